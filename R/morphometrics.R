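#' Segment bright objects in a grayscale image
#'
#' Thresholds the image (Otsu by default), labels connected components with
#' 8-connectivity and removes components smaller than `min_area_px`, then
#' renumbers labels 1..K. Equivalent to the usual Fiji analyze-particles
#' preprocessing for cell or pigmented-lesion masks.
#'
#' @param image Numeric matrix (2D grayscale, any range).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold value for `method = "fixed"` (same scale as
#'   the image).
#' @param min_area_px Minimum object area in pixels.
#' @param pixel_size_um Pixel size carried into the mask, um.
#' @return An object of class `label_mask`: `labels` (integer matrix, 0 =
#'   background, objects 1..K), `n_objects`, `pixel_size_um`. A blank image
#'   yields K = 0, not an error.
#' @export
segment_threshold <- function(image, method = c("otsu", "fixed"),
                              threshold = NULL, min_area_px = 0L,
                              pixel_size_um = 1) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix")
  if (method == "otsu") {
    rng <- range(image)
    if (diff(rng) == 0) {
      lab <- matrix(0L, nrow(image), ncol(image))
      return(structure(list(labels = lab, n_objects = 0L,
                            pixel_size_um = pixel_size_um),
                       class = "label_mask"))
    }
    norm <- (image - rng[1]) / diff(rng)
    threshold <- rng[1] + EBImage::otsu(EBImage::Image(norm)) * diff(rng)
  } else if (is.null(threshold)) {
    stop("`threshold` required for method = \"fixed\"")
  }
  fg <- image > threshold
  lab <- label_components(fg)
  if (min_area_px > 0 && max(lab) > 0) {
    sizes <- tabulate(lab)
    drop <- which(sizes < min_area_px)
    lab[lab %in% drop] <- 0L
  }
  # renumber 1..K
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids)) lab[] <- match(lab, c(0L, ids)) - 1L
  structure(list(labels = lab, n_objects = length(ids),
                 pixel_size_um = pixel_size_um),
            class = "label_mask")
}

# 8-connected component labeling via graph components over foreground pixels
label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  idx <- which(fg)
  if (!length(idx)) return(lab)
  pos <- matrix(0L, nr, nc)
  pos[idx] <- seq_along(idx)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  edges <- integer(0)
  # half of the 8-neighborhood; the other half is implied by undirectedness
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rn <- r + off[1]; cn <- cc + off[2]
    okn <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    nb <- integer(length(idx))
    nb[okn] <- pos[cbind(rn[okn], cn[okn])]
    keep <- nb > 0L
    if (any(keep))
      edges <- c(edges, rbind(seq_along(idx)[keep], nb[keep]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  # keep label order deterministic: renumber by first pixel occurrence
  first <- match(sort(unique(lab[lab > 0])), lab)
  ord <- order(first)
  remap <- integer(max(lab)); remap[sort(unique(lab[lab > 0]))[ord]] <-
    seq_along(ord)
  lab[idx] <- remap[lab[idx]]
  lab
}

# Crofton perimeter, 4-direction approximation: classify every 2x2 pixel
# configuration and weight it by the integral-geometry intercept
# coefficients. Accurate for smooth shapes (disk circularity ~1.00, where
# naive pixel-edge counting would give ~0.78).
perimeter_px <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- (mask != 0) * 1L
  a <- p[2:(nr + 2L), 2:(nc + 2L)]
  b <- p[2:(nr + 2L), 1:(nc + 1L)]
  cc <- p[1:(nr + 1L), 2:(nc + 2L)]
  dd <- p[1:(nr + 1L), 1:(nc + 1L)]
  xf <- a + 4L * b + 2L * cc + 8L * dd
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
             pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
             pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
  sum(coefs[xf + 1L])
}

# convex hull area over pixel corner points (shoelace); corners rather than
# centers keep solidity <= 1 for convex shapes
hull_area_px <- function(rows, cols) {
  pts <- cbind(c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5),
               c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5))
  pts <- unique(pts)
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Shape descriptors of labeled objects
#'
#' For each object: area, perimeter (weighted boundary-configuration
#' estimator), aspect ratio (major/minor axis of the second-moment matched
#' ellipse, the ImageJ fit-ellipse convention), circularity
#' (4 pi A / P^2) and solidity (area / convex hull area). Holes are filled
#' before measuring, so circularity and solidity describe the external
#' margin.
#'
#' @param mask A `label_mask` from [segment_threshold()] (or a compatible
#'   list with `labels` and `pixel_size_um`).
#' @return A data.frame with one row per label: `label`, `area_um2`,
#'   `perimeter_um`, `aspect_ratio`, `circularity`, `solidity`, `flags`
#'   (`""` or `"degenerate"` for sub-2D objects, whose ellipse and hull are
#'   undefined).
#' @export
shape_descriptors <- function(mask) {
  lab <- mask$labels
  K <- max(lab)
  if (K < 1) stop("mask contains no objects")
  px <- mask$pixel_size_um
  filled <- EBImage::fillHull(lab)
  out <- lapply(seq_len(K), function(k) {
    idx <- which(filled == k)
    rows <- (idx - 1L) %% nrow(lab) + 1L
    cols <- (idx - 1L) %/% nrow(lab) + 1L
    area <- length(idx)
    mu_r <- mean(rows); mu_c <- mean(cols)
    # second central moments with the 1/12 pixel-variance term (a single
    # pixel is a unit square, not a point)
    crr <- mean((rows - mu_r)^2) + 1 / 12
    ccc <- mean((cols - mu_c)^2) + 1 / 12
    crc <- mean((rows - mu_r) * (cols - mu_c))
    tr <- crr + ccc
    det <- crr * ccc - crc^2
    disc <- sqrt(max(tr^2 / 4 - det, 0))
    l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
    # sub-2D objects (single pixels, 1-px lines) have no meaningful
    # moment ellipse or hull
    degenerate <- area < 3 || l2 <= 1e-9 ||
      diff(range(rows)) == 0 || diff(range(cols)) == 0
    ar <- if (degenerate) NA_real_ else sqrt(l1 / l2)
    sub <- matrix(FALSE, max(rows) - min(rows) + 3L,
                  max(cols) - min(cols) + 3L)
    sub[cbind(rows - min(rows) + 2L, cols - min(cols) + 2L)] <- TRUE
    per <- perimeter_px(sub)
    circ <- if (per > 0) 4 * pi * area / per^2 else NA_real_
    ha <- hull_area_px(rows, cols)
    sol <- if (ha > 0) area / ha else NA_real_
    data.frame(label = k, area_um2 = area * px^2,
               perimeter_um = per * px,
               aspect_ratio = ar, circularity = circ, solidity = sol,
               flags = if (degenerate) "degenerate" else "")
  })
  do.call(rbind, out)
}

#' Tumoral / body area ratio
#'
#' Fraction of the body covered by pigmented (tumoral) area:
#' `|pigment AND body| / |body|`, used to grade lesion progression.
#'
#' @param pigment_mask,body_mask Logical (or 0/1) matrices of equal size.
#' @return Fraction in `[0, 1]`.
#' @export
tumor_area_ratio <- function(pigment_mask, body_mask) {
  if (!all(dim(pigment_mask) == dim(body_mask)))
    stop("masks must be congruent")
  body <- body_mask != 0
  if (!any(body)) stop("body mask is empty")
  sum((pigment_mask != 0) & body) / sum(body)
}

#' Read a grayscale image file
#'
#' Reads PNG or TIFF into a plain numeric matrix in `[0, 1]`, averaging
#' color channels when present.
#'
#' @param path Image path (extension decides the reader).
#' @return Numeric matrix.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(arr)) == 3) arr <- apply(arr[, , 1:min(3, dim(arr)[3]),
                                              drop = FALSE], c(1, 2), mean)
  arr
}
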