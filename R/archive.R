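#' Read and write force-curve archives
#'
#' The archive is a plain-text directory format: one `metadata.json` document
#' (tip, calibration, grid geometry, units, labels, and the list of curve
#' files) plus one two-column whitespace-separated text file per curve
#' (`z_m`, `deflection`), written with 17 significant digits so a
#' write-then-read round trip preserves every value to better than 1e-12
#' relative. Native instrument formats (Bruker/JPK/Asylum binaries) are out
#' of scope.
#'
#' @param path Archive directory.
#' @return `read_archive()` returns a [force_volume()] when the metadata
#'   declares a grid, otherwise a list of [raw_force_curve()].
#'   `write_archive()` returns `path` invisibly.
#' @examples
#' tip <- default_tip("cell_2d"); cal <- default_calibration("cell_2d")
#' cu <- simulate_curve(4000, sample_class_settings("cell_2d"), tip, cal,
#'                      noise_force_frac = 0, n_samples = 256, seed = 1)
#' p <- file.path(tempdir(), "demo-archive")
#' write_archive(list(cu), p)
#' curves <- read_archive(p)
#' @export
read_archive <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path))
    stop("not an archive: missing ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (key in c("n_curves", "tip", "calibration", "deflection_unit",
                "direction", "curve_files"))
    if (is.null(meta[[key]]))
      stop("archive metadata missing required key: ", key)
  tip <- do.call(tip_geometry, meta$tip[!vapply(meta$tip, is.null, logical(1))])
  cal_args <- meta$calibration
  sens <- cal_args$deflection_sensitivity_m_per_v
  if (!length(sens) || !is.numeric(sens) || !is.finite(sens))
    cal_args$deflection_sensitivity_m_per_v <- NA_real_
  cal <- do.call(cantilever_calibration, cal_args)
  labels <- if (is.null(meta$labels)) list() else meta$labels
  files <- meta$curve_files
  if (length(files) != meta$n_curves)
    stop(sprintf("archive declares %d curves but lists %d files",
                 meta$n_curves, length(files)))
  curves <- lapply(files, function(f) {
    fp <- file.path(path, f)
    tab <- tryCatch(utils::read.table(fp, header = TRUE),
                    error = function(e) stop("cannot parse curve file ", f,
                                             ": ", conditionMessage(e)))
    if (!all(c("z_m", "deflection") %in% names(tab)))
      stop("curve file ", f, " lacks z_m/deflection columns")
    cu <- structure(list(z_m = tab$z_m, deflection = tab$deflection,
                         deflection_unit = meta$deflection_unit,
                         direction = meta$direction,
                         tip = tip, calibration = cal, labels = list()),
                    class = "raw_force_curve")
    bad <- validate_curve(cu)
    if (length(bad))
      stop("invalid curve in file ", f, ": ", paste(bad, collapse = "; "))
    cu
  })
  if (!is.null(meta$rows) && !is.null(meta$cols)) {
    if (!is.null(labels$truth_map_pa) && !is.matrix(labels$truth_map_pa))
      labels$truth_map_pa <- matrix(unlist(labels$truth_map_pa),
                                    nrow = meta$rows, byrow = TRUE)
    force_volume(curves, meta$rows, meta$cols,
                 pixel_pitch_m = meta$pixel_pitch_m,
                 scan_area_m2 = meta$scan_area_m2, labels = labels)
  } else {
    for (i in seq_along(curves))
      curves[[i]]$labels <- if (length(labels)) labels else list()
    curves
  }
}

#' @param x A [force_volume()] or a (possibly length-one) list of
#'   [raw_force_curve()].
#' @rdname read_archive
#' @export
write_archive <- function(x, path) {
  if (inherits(x, "raw_force_curve")) x <- list(x)
  is_volume <- inherits(x, "force_volume")
  curves <- if (is_volume) x$curves else x
  if (!length(curves)) stop("nothing to write: empty curve list")
  dir.create(file.path(path, "curves"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create archive directory ", path)
  files <- sprintf("curves/curve_%04d.tsv", seq_along(curves))
  for (i in seq_along(curves)) {
    cu <- curves[[i]]
    con <- file(file.path(path, files[i]), "w")
    writeLines("z_m deflection", con)
    writeLines(sprintf("%.17g %.17g", cu$z_m, cu$deflection), con)
    close(con)
  }
  first <- curves[[1]]
  meta <- list(format = "nanomech-archive", version = 1L,
               n_curves = length(curves),
               deflection_unit = first$deflection_unit,
               direction = first$direction,
               tip = first$tip[!vapply(first$tip, is.null, logical(1))],
               calibration = unclass(first$calibration),
               curve_files = files)
  if (is_volume) {
    meta$rows <- x$rows; meta$cols <- x$cols
    meta$pixel_pitch_m <- x$pixel_pitch_m
    meta$scan_area_m2 <- x$scan_area_m2
    labels <- x$labels
    if (!is.null(labels$truth_map_pa))
      labels$truth_map_pa <- apply(labels$truth_map_pa, 1, identity,
                                   simplify = FALSE)
    meta$labels <- labels
  } else if (length(first$labels)) {
    meta$labels <- first$labels
  }
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}
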