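#' Fit every curve of a force volume into a stiffness map
#'
#' Runs [fit_modulus()] on each pixel's curve. Pixels whose fit fails
#' (`poor_fit`) are marked invalid in the map's `valid` grid — they are
#' never silently dropped, so valid + invalid always equals rows x cols.
#'
#' @param volume A [force_volume()].
#' @param settings A [sample_class_settings()] compatible with the volume's
#'   tip.
#' @param precontact_fraction Passed to [fit_modulus()].
#' @param keep_fits If `TRUE`, attach the per-pixel `elastic_fit` list.
#' @return An object of class `stiffness_map`: `moduli_pa` (rows x cols,
#'   `NA` where invalid), `valid` (logical grid), `pixel_pitch_m`, `flags`
#'   (list grid of per-pixel flags).
#' @export
fit_volume <- function(volume, settings, precontact_fraction = 0.2,
                       keep_fits = FALSE) {
  rows <- volume$rows; cols <- volume$cols
  moduli <- matrix(NA_real_, rows, cols)
  valid <- matrix(FALSE, rows, cols)
  flags <- vector("list", rows * cols)
  fits <- if (keep_fits) vector("list", rows * cols) else NULL
  idx <- 1L
  for (rr in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      ft <- fit_modulus(volume$curves[[idx]], settings, precontact_fraction)
      good <- !("poor_fit" %in% ft$flags) && is.finite(ft$modulus_pa) &&
        ft$modulus_pa > 0
      if (good) { moduli[rr, cc] <- ft$modulus_pa; valid[rr, cc] <- TRUE }
      flags[[idx]] <- ft$flags
      if (keep_fits) fits[[idx]] <- ft
      idx <- idx + 1L
    }
  }
  structure(list(moduli_pa = moduli, valid = valid,
                 pixel_pitch_m = volume$pixel_pitch_m,
                 flags = flags, fits = fits,
                 labels = volume$labels),
            class = "stiffness_map")
}

#' @export
print.stiffness_map <- function(x, ...) {
  cat(sprintf("<stiffness_map> %dx%d, %d/%d valid, median %.4g kPa\n",
              nrow(x$moduli_pa), ncol(x$moduli_pa), sum(x$valid),
              length(x$valid),
              stats::median(x$moduli_pa[x$valid]) / 1e3))
  invisible(x)
}

#' Summarize a region of a stiffness map
#'
#' Median (the headline statistic — robust to residual fit failures), mean
#' and SD of the valid moduli inside a mask. The even-count median is the
#' mean of the two central values (the R convention).
#'
#' @param map A `stiffness_map` from [fit_volume()].
#' @param mask Logical matrix congruent with the map (`NULL` = whole map).
#' @param label Region label carried into the summary.
#' @return An object of class `region_summary`: `n_valid`, `median_pa`,
#'   `mean_pa`, `sd_pa`, `region_label`.
#' @export
summarize_region <- function(map, mask = NULL, label = "region") {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(map$moduli_pa),
                                    ncol(map$moduli_pa))
  if (!all(dim(mask) == dim(map$moduli_pa)))
    stop("mask dimensions must match the map")
  sel <- map$valid & mask
  if (!any(sel)) stop("region has no valid pixels")
  vals <- map$moduli_pa[sel]
  structure(list(n_valid = sum(sel),
                 median_pa = stats::median(vals),
                 mean_pa = mean(vals),
                 sd_pa = stats::sd(vals),
                 region_label = label),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("<region_summary> %s: n = %d, median %.4g kPa, mean %.4g kPa, sd %.3g kPa\n",
              x$region_label, x$n_valid, x$median_pa / 1e3, x$mean_pa / 1e3,
              x$sd_pa / 1e3))
  invisible(x)
}

#' Render a stiffness map as a PNG
#'
#' Linear color scale from the map minimum (default blue, the softest
#' pixels) to the maximum (default red, the stiffest), invalid pixels gray,
#' with a scale bar derived from the pixel pitch drawn in the bottom-right
#' corner. The per-image min-max scale matches how stiffness projections of
#' lesions are usually displayed; pass `fixed_range_pa` for cross-image
#' comparability.
#'
#' @param map A `stiffness_map`.
#' @param out_path Output PNG path.
#' @param color_low,color_high Colors for the scale endpoints.
#' @param upscale Integer pixel replication factor. Default 16.
#' @param fixed_range_pa Optional `c(lo, hi)` in Pa overriding the
#'   per-image range.
#' @return `out_path`, invisibly. The written image is
#'   `(rows*upscale) x (cols*upscale)`.
#' @export
render_map <- function(map, out_path, color_low = "blue",
                       color_high = "red", upscale = 16L,
                       fixed_range_pa = NULL) {
  if (!any(map$valid)) stop("cannot render a map with no valid pixels")
  vals <- map$moduli_pa
  rng <- if (is.null(fixed_range_pa))
    range(vals[map$valid]) else fixed_range_pa
  span <- if (diff(rng) > 0) diff(rng) else 1
  t01 <- pmin(pmax((vals - rng[1]) / span, 0), 1)
  t01[!map$valid | is.na(t01)] <- 0
  ramp <- grDevices::colorRamp(c(color_low, color_high))
  rgb01 <- ramp(as.vector(t01)) / 255
  rgb01[!as.vector(map$valid), ] <- 0.5  # invalid pixels gray
  rows <- nrow(vals); cols <- ncol(vals)
  img <- array(0, dim = c(rows, cols, 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgb01[, ch], rows, cols)
  up <- matrix(1, upscale, upscale)
  big <- array(0, dim = c(rows * upscale, cols * upscale, 3))
  for (ch in 1:3) big[, , ch] <- kronecker(img[, , ch], up)
  # scale bar: a round fraction of the scan width, white, bottom-right
  width_m <- cols * map$pixel_pitch_m
  bar_m <- 10^floor(log10(width_m / 3))
  bar_px <- max(1L, round(bar_m / map$pixel_pitch_m * upscale))
  h <- dim(big)[1]; w <- dim(big)[2]
  bh <- max(2L, round(upscale / 4))
  big[(h - 2 * bh):(h - bh), (w - bar_px - bh):(w - bh), ] <- 1
  png::writePNG(big, out_path)
  invisible(out_path)
}
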