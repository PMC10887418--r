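#' Simulate a raw force curve with known ground truth
#'
#' Constructs the piecewise physical curve — flat baseline before contact,
#' contact-model force after contact — and maps it back to raw piezo and
#' deflection samples through the cantilever relations F = k d and
#' delta = (z - z0) - d. Within the contact region the deflection at each
#' piezo position solves k d = F(z - z0 - d) by a vectorized Newton
#' iteration (machine-precision, so the fit/simulate round trip is exact up
#' to floating point). Gaussian force noise (expressed as a fraction of the
#' peak force) and a linear baseline force tilt can be added on top; the
#' generating parameters are recorded in `labels` so the ground truth never
#' has to be reconstructed.
#'
#' @param true_modulus_pa Generating Young's modulus, Pa.
#' @param settings A [sample_class_settings()]; the ramp is sized to exceed
#'   the class indentation window by `delta_overshoot`.
#' @param tip,calibration Tip geometry and calibration consistent with the
#'   settings model.
#' @param noise_force_frac SD of added Gaussian force noise as a fraction of
#'   peak force. Default 0.02; must be >= 0.
#' @param baseline_slope_n_per_m Linear force drift per meter of z across
#'   the whole ramp (emulates optical interference / thermal drift).
#' @param contact_index Sample index at which the tip touches the surface.
#' @param n_samples Samples per curve; default 2048.
#' @param seed Optional RNG seed (only the noise consumes randomness).
#' @param delta_overshoot Ramp depth as a multiple of the indentation
#'   window. Default 1.15.
#' @return A [raw_force_curve()] (deflection in meters) whose
#'   `labels$truth` records modulus, contact index, model and noise level.
#' @export
simulate_curve <- function(true_modulus_pa, settings, tip, calibration,
                           noise_force_frac = 0.02,
                           baseline_slope_n_per_m = 0,
                           contact_index = 700L, n_samples = 2048L,
                           seed = NULL, delta_overshoot = 1.15) {
  if (noise_force_frac < 0) stop("`noise_force_frac` must be >= 0")
  if (true_modulus_pa <= 0) stop("`true_modulus_pa` must be positive")
  if (contact_index < 2 || contact_index > n_samples - 16)
    stop("`contact_index` leaves no room for baseline or contact region")
  if (!is.null(seed)) set.seed(seed)
  k <- calibration$spring_constant_n_per_m
  delta_end <- delta_overshoot * settings$max_indentation_m
  zr_end <- delta_end +
    model_force(true_modulus_pa, delta_end, settings, tip) / k
  i0 <- as.integer(contact_index)
  z0 <- zr_end * (i0 - 1) / (n_samples - i0)
  z <- seq(0, z0 + zr_end, length.out = n_samples)
  d <- numeric(n_samples)
  post <- which(z > z0)
  di <- solve_deflection(z[post] - z0, true_modulus_pa, settings, tip, k)
  d[post] <- di
  f_peak <- k * max(di)
  if (noise_force_frac > 0)
    d <- d + stats::rnorm(n_samples, sd = noise_force_frac * f_peak) / k
  if (baseline_slope_n_per_m != 0)
    d <- d + baseline_slope_n_per_m * (z - z[1]) / k
  raw_force_curve(z, d, deflection_unit = "m", direction = "approach",
                  tip = tip, calibration = calibration,
                  labels = list(truth = list(
                    true_modulus_pa = true_modulus_pa,
                    contact_index = i0, contact_z_m = z[i0],
                    model = settings$model,
                    sample_class = settings$sample_class,
                    noise_force_frac = noise_force_frac,
                    baseline_slope_n_per_m = baseline_slope_n_per_m,
                    seed = seed)))
}

#' Scene specification for synthetic force volumes
#'
#' Describes a spatial stiffness scene: a grid, a set of labeled regions
#' with their true moduli (e.g. a soft pigmented lesion inside stiffer
#' healthy tissue), the force-noise level, baseline tilt and per-pixel
#' contact jitter.
#'
#' @param rows,cols Grid dimensions.
#' @param regions List of regions, each a list with `mask` (rows x cols
#'   logical matrix), `modulus_pa` (> 0) and `label`. Masks must partition
#'   the grid.
#' @param noise_force_frac,baseline_slope_n_per_m Per-curve noise
#'   parameters, see [simulate_curve()].
#' @param contact_jitter_samples Per-pixel contact index jitter, uniform on
#'   `[-j, j]` samples around `contact_index`.
#' @param contact_index,n_samples Base curve geometry.
#' @param seed RNG seed for the whole scene.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(rows, cols, regions, noise_force_frac = 0.02,
                       baseline_slope_n_per_m = 0,
                       contact_jitter_samples = 0L, contact_index = 700L,
                       n_samples = 2048L, seed = 1L) {
  cover <- matrix(0L, rows, cols)
  for (r in regions) {
    if (!is.matrix(r$mask) || !all(dim(r$mask) == c(rows, cols)))
      stop("region mask dimensions must match the grid")
    if (!is.finite(r$modulus_pa) || r$modulus_pa <= 0)
      stop("region moduli must be positive")
    cover <- cover + (r$mask != 0)
  }
  if (any(cover != 1L)) stop("region masks must partition the grid")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 regions = regions, noise_force_frac = noise_force_frac,
                 baseline_slope_n_per_m = baseline_slope_n_per_m,
                 contact_jitter_samples = as.integer(contact_jitter_samples),
                 contact_index = as.integer(contact_index),
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "scene_spec")
}

#' @param modulus_pa Single modulus for the whole grid.
#' @param label Region label.
#' @param ... Passed on to [scene_spec()].
#' @rdname scene_spec
#' @export
uniform_scene <- function(rows, cols, modulus_pa, label = "sample", ...) {
  scene_spec(rows, cols,
             regions = list(list(mask = matrix(TRUE, rows, cols),
                                 modulus_pa = modulus_pa, label = label)),
             ...)
}

#' @param moduli_pa Length-2 moduli for the left/right halves.
#' @param labels Length-2 region labels.
#' @rdname scene_spec
#' @export
two_region_scene <- function(rows, cols, moduli_pa,
                             labels = c("lesion", "healthy"), ...) {
  split <- floor(cols / 2)
  left <- matrix(FALSE, rows, cols); left[, seq_len(split)] <- TRUE
  scene_spec(rows, cols,
             regions = list(
               list(mask = left, modulus_pa = moduli_pa[1], label = labels[1]),
               list(mask = !left, modulus_pa = moduli_pa[2], label = labels[2])),
             ...)
}

#' Simulate a force volume from a stiffness scene
#'
#' One [simulate_curve()] per pixel, with the pixel's region modulus and
#' (optionally) jittered contact index. The ground-truth modulus map and the
#' region masks are stored in the volume labels.
#'
#' @param scene A [scene_spec()].
#' @param settings,tip,calibration As for [simulate_curve()].
#' @param pixel_pitch_m Grid pixel pitch; default sizes a 10 x 10 um scan.
#' @return A [force_volume()] with `labels$truth_map_pa` (rows x cols) and
#'   `labels$region_labels`.
#' @export
simulate_volume <- function(scene, settings, tip, calibration,
                            pixel_pitch_m = 10e-6 / max(scene$rows, scene$cols)) {
  set.seed(scene$seed)
  truth <- matrix(NA_real_, scene$rows, scene$cols)
  region_of <- matrix(NA_character_, scene$rows, scene$cols)
  for (r in scene$regions) {
    truth[r$mask] <- r$modulus_pa
    region_of[r$mask] <- r$label
  }
  j <- scene$contact_jitter_samples
  curves <- vector("list", scene$rows * scene$cols)
  idx <- 1L
  for (rr in seq_len(scene$rows)) {
    for (cc in seq_len(scene$cols)) {
      ci <- scene$contact_index +
        if (j > 0) sample.int(2L * j + 1L, 1L) - j - 1L else 0L
      curves[[idx]] <- simulate_curve(
        truth[rr, cc], settings, tip, calibration,
        noise_force_frac = scene$noise_force_frac,
        baseline_slope_n_per_m = scene$baseline_slope_n_per_m,
        contact_index = ci, n_samples = scene$n_samples, seed = NULL)
      idx <- idx + 1L
    }
  }
  force_volume(curves, scene$rows, scene$cols, pixel_pitch_m,
               labels = list(truth_map_pa = truth,
                             region_labels = region_of,
                             scene_seed = scene$seed))
}

#' Simulate a thermal-noise cantilever trace
#'
#' Gaussian deflection noise whose variance beta * k_B * T / k is the
#' first-mode share of the equipartition energy, so that the beta-corrected
#' thermal-tune estimate ([spring_constant_thermal()]) recovers k without
#' bias.
#'
#' @param spring_constant_n_per_m True spring constant k, N/m.
#' @param temperature_k Temperature, kelvin. Default 298.
#' @param n_samples Trace length; default 65536.
#' @param seed Optional RNG seed.
#' @param sample_rate_hz Nominal sampling rate stored in the trace.
#' @param beta First-mode correction, matching the calibrator's default.
#' @return A [thermal_trace()].
#' @export
simulate_thermal_trace <- function(spring_constant_n_per_m,
                                   temperature_k = 298, n_samples = 65536L,
                                   seed = NULL, sample_rate_hz = 100e3,
                                   beta = 0.971) {
  if (spring_constant_n_per_m <= 0 || temperature_k <= 0)
    stop("spring constant and temperature must be positive")
  if (!is.null(seed)) set.seed(seed)
  sd_m <- sqrt(beta * .kB * temperature_k / spring_constant_n_per_m)
  thermal_trace(stats::rnorm(n_samples, sd = sd_m), sample_rate_hz,
                temperature_k)
}

#' Cell population specification
#'
#' Parameters of a synthetic population of elliptical cells for
#' morphometrics testing: aspect-ratio and size distributions, boundary
#' roughness (0 = smooth ellipses, larger values add low-order radial
#' harmonics that undulate the margin and depress solidity), image geometry
#' and pixel size.
#'
#' @param n_cells Number of cells, >= 1.
#' @param aspect_ratio_mean,aspect_ratio_sd Normal distribution of aspect
#'   ratios, truncated at 1.
#' @param area_mean_um2,area_sd_um2 Normal distribution of cell areas
#'   (um^2), truncated at a small positive floor.
#' @param boundary_roughness In `[0, 1]`.
#' @param image_size_px Square image side, pixels.
#' @param pixel_size_um Pixel size, um.
#' @param seed RNG seed.
#' @return An object of class `cell_population_spec`.
#' @export
cell_population_spec <- function(n_cells, aspect_ratio_mean = 1.6,
                                 aspect_ratio_sd = 0.3,
                                 area_mean_um2 = 400, area_sd_um2 = 80,
                                 boundary_roughness = 0,
                                 image_size_px = 512L, pixel_size_um = 0.5,
                                 seed = 1L) {
  if (n_cells < 1) stop("`n_cells` must be >= 1")
  if (boundary_roughness < 0 || boundary_roughness > 1)
    stop("`boundary_roughness` must lie in [0, 1]")
  structure(list(n_cells = as.integer(n_cells),
                 aspect_ratio_mean = aspect_ratio_mean,
                 aspect_ratio_sd = aspect_ratio_sd,
                 area_mean_um2 = area_mean_um2, area_sd_um2 = area_sd_um2,
                 boundary_roughness = boundary_roughness,
                 image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "cell_population_spec")
}

#' Simulate an image of elliptical cells
#'
#' Places non-overlapping ellipses (optionally with a rough margin) on a
#' dim noisy background and rasterizes them as bright objects, returning
#' both the grayscale image and a per-cell ground-truth table.
#'
#' @param spec A [cell_population_spec()].
#' @param max_tries Placement attempts per cell before giving up.
#' @return A list with `image` (numeric matrix in `[0, 1]`) and `truth`
#'   (data.frame: cell, center_row, center_col, area_um2, aspect_ratio,
#'   orientation_rad).
#' @export
simulate_cell_image <- function(spec, max_tries = 200L) {
  set.seed(spec$seed)
  n <- spec$image_size_px
  px <- spec$pixel_size_um
  img <- matrix(stats::rnorm(n * n, mean = 0.10, sd = 0.02), n, n)
  truth <- data.frame(cell = integer(), center_row = numeric(),
                      center_col = numeric(), area_um2 = numeric(),
                      aspect_ratio = numeric(), orientation_rad = numeric())
  placed <- list()
  rough_margin <- 1 + 0.45 * spec$boundary_roughness
  for (ci in seq_len(spec$n_cells)) {
    ar <- max(1, stats::rnorm(1, spec$aspect_ratio_mean, spec$aspect_ratio_sd))
    area_um2 <- max(25, stats::rnorm(1, spec$area_mean_um2, spec$area_sd_um2))
    area_px <- area_um2 / px^2
    a <- sqrt(area_px * ar / pi)   # semi-major, px
    b <- a / ar
    theta <- stats::runif(1, 0, pi)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ctr <- stats::runif(2, a * rough_margin + 2, n - a * rough_margin - 2)
      clear <- all(vapply(placed, function(p) {
        sqrt(sum((ctr - p$ctr)^2)) > (a + p$a) * rough_margin + 2
      }, logical(1)))
      if (clear) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not place ", spec$n_cells, " cells without overlap; ",
           "use a larger `image_size_px` or fewer cells")
    # radial margin modulation: smooth low-order harmonics
    kh <- 3:7
    amp <- stats::rnorm(length(kh), 0, 0.06 * spec$boundary_roughness)
    phase <- stats::runif(length(kh), 0, 2 * pi)
    win <- ceiling(a * rough_margin) + 1
    rows <- max(1, floor(ctr[1] - win)):min(n, ceiling(ctr[1] + win))
    cols <- max(1, floor(ctr[2] - win)):min(n, ceiling(ctr[2] + win))
    gx <- outer(rows - ctr[1], rep(1, length(cols)))
    gy <- outer(rep(1, length(rows)), cols - ctr[2])
    xr <- (gx * cos(theta) + gy * sin(theta)) / a
    yr <- (-gx * sin(theta) + gy * cos(theta)) / b
    rho <- sqrt(xr^2 + yr^2)
    ang <- atan2(yr, xr)
    scale <- 1 + Reduce(`+`, Map(function(k, A, ph) A * cos(k * ang + ph),
                                 kh, amp, phase))
    inside <- rho <= scale
    img[rows, cols][inside] <- 0.85 + stats::rnorm(sum(inside), 0, 0.03)
    placed[[length(placed) + 1]] <- list(ctr = ctr, a = a)
    truth <- rbind(truth, data.frame(
      cell = ci, center_row = ctr[1], center_col = ctr[2],
      area_um2 = area_um2, aspect_ratio = ar, orientation_rad = theta))
  }
  list(image = pmin(pmax(img, 0), 1), truth = truth)
}

#' Simulate two samples for group-comparison testing
#'
#' Reproducible draws from named distributions, with the generating truth
#' attached, for exercising the test-selection procedure.
#'
#' @param dist_a,dist_b Distribution specs: `list("normal", mean=, sd=)`,
#'   `list("lognormal", meanlog=, sdlog=)` or `list("exponential", rate=)`.
#' @param n_a,n_b Sample sizes, >= 3.
#' @param seed RNG seed.
#' @return List with numeric vectors `a`, `b` and `meta` recording the
#'   generating distributions.
#' @export
simulate_two_groups <- function(dist_a, dist_b, n_a, n_b, seed = 1L) {
  if (n_a < 3 || n_b < 3) stop("group sizes must be >= 3")
  draw <- function(spec, n) {
    name <- spec[[1]]
    switch(name,
           normal = stats::rnorm(n, spec$mean %||% 0, spec$sd %||% 1),
           lognormal = stats::rlnorm(n, spec$meanlog %||% 0,
                                     spec$sdlog %||% 1),
           exponential = stats::rexp(n, spec$rate %||% 1),
           stop("unknown distribution: ", name))
  }
  set.seed(seed)
  a <- draw(dist_a, n_a)
  b <- draw(dist_b, n_b)
  list(a = a, b = b, meta = list(dist_a = dist_a, dist_b = dist_b,
                                 seed = seed))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Published reference stiffness values
#'
#' Young's moduli (kPa) reported for the melanocyte/melanoma systems this
#' pipeline targets, shipped as a YAML fixture and used to seed the
#' parameter-recovery scenes: normal human melanocytes in 2D culture
#' (`nhm_2d`), skin-reconstruct cryosections grown with non-invasive IC8
#' (`ic8_hsr_section`) and invasive T1C3 (`t1c3_hsr_section`) melanoma
#' cells, and the two-fold IC8:T1C3 stiffness contrast in 2D culture
#' (`ic8_t1c3_2d_ratio`, dimensionless).
#'
#' @return Named list of values in kPa (the ratio is dimensionless).
#' @export
reference_moduli <- function() {
  yaml::read_yaml(system.file("extdata", "reference_moduli.yaml",
                              package = "nanomech", mustWork = TRUE))
}
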