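#' Tip geometry
#'
#' Describes the indenter at the end of the cantilever. Pyramidal tips are
#' characterized by their face half-angle (the Sneddon model applies),
#' spherical tips by their radius (the Hertz model applies). The nominal apex
#' radius quoted by probe manufacturers (8--12 nm for sharp pyramidal probes)
#' is carried as information only; it enters no computation.
#'
#' @param kind `"pyramidal"` or `"spherical"`.
#' @param half_angle_deg Pyramid face half-angle in degrees (pyramidal only),
#'   in (0, 90).
#' @param radius_m Sphere radius in meters (spherical only), positive.
#' @param nominal_apex_radius_m Optional manufacturer apex radius, meters.
#' @return An object of class `tip_geometry`.
#' @examples
#' tip_geometry("pyramidal", half_angle_deg = 18)
#' tip_geometry("spherical", radius_m = 500e-9)
#' @export
tip_geometry <- function(kind = c("pyramidal", "spherical"),
                         half_angle_deg = NULL, radius_m = NULL,
                         nominal_apex_radius_m = NULL) {
  kind <- match.arg(kind)
  if (kind == "pyramidal") {
    if (is.null(half_angle_deg) || !is.null(radius_m))
      stop("pyramidal tips require `half_angle_deg` and must not set `radius_m`")
    if (!is.finite(half_angle_deg) || half_angle_deg <= 0 || half_angle_deg >= 90)
      stop("`half_angle_deg` must lie in (0, 90)")
  } else {
    if (is.null(radius_m) || !is.null(half_angle_deg))
      stop("spherical tips require `radius_m` and must not set `half_angle_deg`")
    if (!is.finite(radius_m) || radius_m <= 0)
      stop("`radius_m` must be positive")
  }
  structure(list(kind = kind,
                 half_angle_deg = half_angle_deg,
                 radius_m = radius_m,
                 nominal_apex_radius_m = nominal_apex_radius_m),
            class = "tip_geometry")
}

#' Cantilever calibration
#'
#' Spring constant and optical-lever deflection sensitivity of a cantilever.
#' The sensitivity converts photodiode volts to meters of deflection and is
#' required whenever a curve stores deflection in volts.
#'
#' @param spring_constant_n_per_m Spring constant k, N/m, positive.
#' @param deflection_sensitivity_m_per_v Deflection sensitivity, m/V,
#'   positive, or `NA` when curves carry deflection in meters already.
#' @param method How the spring constant was obtained: `"thermal_tune"`,
#'   `"precalibrated"` (manufacturer/stiff levers) or `"synthetic"`.
#' @return An object of class `cantilever_calibration`.
#' @export
cantilever_calibration <- function(spring_constant_n_per_m,
                                   deflection_sensitivity_m_per_v = NA_real_,
                                   method = c("thermal_tune", "precalibrated",
                                              "synthetic")) {
  method <- match.arg(method)
  if (!is.finite(spring_constant_n_per_m) || spring_constant_n_per_m <= 0)
    stop("`spring_constant_n_per_m` must be positive")
  if (!is.na(deflection_sensitivity_m_per_v) &&
      (!is.finite(deflection_sensitivity_m_per_v) ||
       deflection_sensitivity_m_per_v <= 0))
    stop("`deflection_sensitivity_m_per_v` must be positive or NA")
  structure(list(spring_constant_n_per_m = spring_constant_n_per_m,
                 deflection_sensitivity_m_per_v = deflection_sensitivity_m_per_v,
                 method = method),
            class = "cantilever_calibration")
}

#' Per-sample-class analysis settings
#'
#' Bundles the contact model and the indentation window used for modulus
#' extraction. Class defaults follow the measurement design: 2 um on 2D
#' cultured cells and 5 um on whole skin reconstructs (both thick samples),
#' 700 nm on cryosections (thin samples, where staying within one third of
#' the section thickness keeps the substrate out of the measurement).
#'
#' @param sample_class `"cell_2d"`, `"hsr_whole"` or `"cryosection"`.
#' @param model Contact model, `"sneddon"` (pyramidal tips) or `"hertz"`
#'   (spherical tips); defaults to the class convention.
#' @param max_indentation_m Fit window upper bound on indentation, meters.
#'   Defaults: 2e-6 (cell_2d), 5e-6 (hsr_whole), 700e-9 (cryosection).
#' @param poisson_ratio Poisson's ratio of the sample, in `[0, 0.5)`.
#'   Default 0.3.
#' @param thickness_m Sample thickness, meters, if known; enables the
#'   one-third depth rule check. `NULL` when unknown (whole tissues).
#' @param sneddon_prefactor `"canonical"` uses the 2/pi conical-indenter
#'   prefactor; `"typeset"` uses 2*pi and exists only for sensitivity
#'   analyses against sources that print the pyramidal force law that way.
#' @return An object of class `sample_class_settings`.
#' @examples
#' sample_class_settings("cryosection", thickness_m = 5e-6)
#' @export
sample_class_settings <- function(sample_class = c("cell_2d", "hsr_whole",
                                                   "cryosection"),
                                  model = NULL, max_indentation_m = NULL,
                                  poisson_ratio = 0.3, thickness_m = NULL,
                                  sneddon_prefactor = c("canonical", "typeset")) {
  sample_class <- match.arg(sample_class)
  sneddon_prefactor <- match.arg(sneddon_prefactor)
  defaults <- list(cell_2d     = list(model = "sneddon", max_ind = 2e-6),
                   hsr_whole   = list(model = "hertz",   max_ind = 5e-6),
                   cryosection = list(model = "sneddon", max_ind = 700e-9))
  def <- defaults[[sample_class]]
  if (is.null(model)) model <- def$model
  model <- match.arg(model, c("sneddon", "hertz"))
  if (is.null(max_indentation_m)) max_indentation_m <- def$max_ind
  if (!is.finite(max_indentation_m) || max_indentation_m <= 0)
    stop("`max_indentation_m` must be positive")
  if (!is.finite(poisson_ratio) || poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("`poisson_ratio` must lie in [0, 0.5)")
  if (!is.null(thickness_m) && (!is.finite(thickness_m) || thickness_m <= 0))
    stop("`thickness_m` must be positive or NULL")
  structure(list(sample_class = sample_class, model = model,
                 max_indentation_m = max_indentation_m,
                 poisson_ratio = poisson_ratio, thickness_m = thickness_m,
                 sneddon_prefactor = sneddon_prefactor),
            class = "sample_class_settings")
}

#' Default tip and calibration for a sample class
#'
#' Convenience constructors reproducing the probe configurations of the
#' study design: sharp pyramidal probes (18 degree half-angle, ~10 nm apex)
#' on 0.4 N/m levers for cells and cryosections, and 500 nm spheres on
#' precalibrated 40 N/m levers for whole skin reconstructs.
#'
#' @param sample_class One of `"cell_2d"`, `"hsr_whole"`, `"cryosection"`.
#' @return `default_tip()` a [tip_geometry()], `default_calibration()` a
#'   [cantilever_calibration()].
#' @export
default_tip <- function(sample_class = c("cell_2d", "hsr_whole",
                                         "cryosection")) {
  sample_class <- match.arg(sample_class)
  if (sample_class == "hsr_whole")
    tip_geometry("spherical", radius_m = 500e-9)
  else
    tip_geometry("pyramidal", half_angle_deg = 18,
                 nominal_apex_radius_m = 10e-9)
}

#' @rdname default_tip
#' @export
default_calibration <- function(sample_class = c("cell_2d", "hsr_whole",
                                                 "cryosection")) {
  sample_class <- match.arg(sample_class)
  if (sample_class == "hsr_whole")
    cantilever_calibration(40, method = "precalibrated")
  else
    cantilever_calibration(0.4, method = "synthetic")
}

#' Raw force curve
#'
#' One piezo ramp: ordered piezo positions and the cantilever deflection read
#' at each position, plus the tip and calibration needed to interpret them.
#' Deflection may be stored in photodiode volts (requires a deflection
#' sensitivity in the calibration) or directly in meters; the unit flag is
#' mandatory and never guessed.
#'
#' @param z_m Piezo positions, meters, strictly monotone (increasing on
#'   approach, decreasing on retract).
#' @param deflection Deflection samples, same length as `z_m`.
#' @param deflection_unit `"m"` or `"V"`.
#' @param direction `"approach"` or `"retract"`. Approach curves are the
#'   substrate for modulus fitting.
#' @param tip A [tip_geometry()].
#' @param calibration A [cantilever_calibration()].
#' @param labels Free-form named list of group/condition metadata (and, for
#'   synthetic curves, the generating ground truth).
#' @return An object of class `raw_force_curve`.
#' @seealso [validate_curve()] for the non-throwing invariant check.
#' @export
raw_force_curve <- function(z_m, deflection, deflection_unit = c("m", "V"),
                            direction = c("approach", "retract"),
                            tip, calibration, labels = list()) {
  deflection_unit <- match.arg(deflection_unit)
  direction <- match.arg(direction)
  curve <- structure(list(z_m = as.numeric(z_m),
                          deflection = as.numeric(deflection),
                          deflection_unit = deflection_unit,
                          direction = direction,
                          tip = tip, calibration = calibration,
                          labels = labels),
                     class = "raw_force_curve")
  bad <- validate_curve(curve)
  if (length(bad)) stop("invalid force curve: ", paste(bad, collapse = "; "))
  curve
}

#' Validate a force curve
#'
#' Checks every invariant of a [raw_force_curve()] and reports violations as
#' strings instead of raising, so batch readers can collect problems.
#'
#' @param curve A putative `raw_force_curve` (list with the same fields).
#' @return Character vector of violations; empty when the curve is valid.
#' @export
validate_curve <- function(curve) {
  out <- character()
  z <- curve$z_m; d <- curve$deflection
  if (!is.numeric(z) || !is.numeric(d)) return("z and deflection must be numeric")
  if (length(z) != length(d))
    out <- c(out, sprintf("length mismatch: %d z values vs %d deflection values",
                          length(z), length(d)))
  if (length(z) < 64)
    out <- c(out, sprintf("too few samples: %d < 64", length(z)))
  if (anyNA(z) || anyNA(d)) out <- c(out, "non-finite samples present")
  dz <- diff(z)
  if (length(dz)) {
    if (identical(curve$direction, "approach") && any(dz <= 0))
      out <- c(out, "z not strictly increasing (monotonicity violated on approach)")
    if (identical(curve$direction, "retract") && any(dz >= 0))
      out <- c(out, "z not strictly decreasing (monotonicity violated on retract)")
  }
  if (!inherits(curve$tip, "tip_geometry"))
    out <- c(out, "missing or invalid tip geometry")
  if (!inherits(curve$calibration, "cantilever_calibration"))
    out <- c(out, "missing or invalid calibration")
  else if (identical(curve$deflection_unit, "V") &&
           is.na(curve$calibration$deflection_sensitivity_m_per_v))
    out <- c(out, "deflection in volts but no deflection sensitivity")
  out
}

#' Force volume
#'
#' A rectangular grid of force curves acquired one per pixel over a scan
#' area, all sharing tip and calibration. Curves are stored row-major.
#'
#' @param curves List of [raw_force_curve()], length `rows * cols`, row-major.
#' @param rows,cols Grid dimensions.
#' @param pixel_pitch_m Center-to-center pixel spacing, meters.
#' @param scan_area_m2 Scanned area, m^2; default `(rows*pixel_pitch) *
#'   (cols*pixel_pitch)`.
#' @param labels Named list of volume-level metadata (e.g. a ground-truth
#'   modulus map for synthetic volumes).
#' @return An object of class `force_volume`.
#' @export
force_volume <- function(curves, rows, cols, pixel_pitch_m,
                         scan_area_m2 = NULL, labels = list()) {
  if (length(curves) != rows * cols)
    stop(sprintf("grid mismatch: %d curves for a %dx%d grid",
                 length(curves), rows, cols))
  if (!all(vapply(curves, inherits, logical(1), "raw_force_curve")))
    stop("all grid entries must be raw_force_curve objects")
  tip0 <- curves[[1]]$tip; cal0 <- curves[[1]]$calibration
  shared <- vapply(curves, function(cu) {
    identical(unclass(cu$tip), unclass(tip0)) &&
      identical(unclass(cu$calibration), unclass(cal0))
  }, logical(1))
  if (!all(shared)) stop("all curves in a volume must share tip and calibration")
  if (!is.finite(pixel_pitch_m) || pixel_pitch_m <= 0)
    stop("`pixel_pitch_m` must be positive")
  if (is.null(scan_area_m2))
    scan_area_m2 <- rows * cols * pixel_pitch_m^2
  structure(list(curves = curves, rows = as.integer(rows),
                 cols = as.integer(cols), pixel_pitch_m = pixel_pitch_m,
                 scan_area_m2 = scan_area_m2, labels = labels),
            class = "force_volume")
}

#' @export
print.raw_force_curve <- function(x, ...) {
  cat(sprintf("<raw_force_curve> %d samples, %s, deflection in %s, %s tip, k = %g N/m\n",
              length(x$z_m), x$direction, x$deflection_unit, x$tip$kind,
              x$calibration$spring_constant_n_per_m))
  invisible(x)
}

#' @export
print.force_volume <- function(x, ...) {
  cat(sprintf("<force_volume> %dx%d curves (%d samples each), pixel pitch %.3g um\n",
              x$rows, x$cols, length(x$curves[[1]]$z_m), x$pixel_pitch_m * 1e6))
  invisible(x)
}

# deflection in meters regardless of stored unit; errors when volts arrive
# without a sensitivity
deflection_m <- function(curve) {
  if (identical(curve$deflection_unit, "m")) return(curve$deflection)
  s <- curve$calibration$deflection_sensitivity_m_per_v
  if (is.na(s)) stop("deflection in volts but calibration has no sensitivity")
  curve$deflection * s
}
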