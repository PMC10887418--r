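#' Sneddon force law for a pyramidal/conical indenter
#'
#' Force on a rigid conical (pyramidal) indenter pressed a depth delta into a
#' flat elastic half-space:
#' \deqn{F = \frac{2}{\pi}\,\frac{E}{1-\nu^2}\,\tan(\alpha)\,\delta^2}
#' with E the Young's modulus, nu the Poisson ratio and alpha the face
#' half-angle. The force is linear in E and quadratic in depth.
#'
#' @param modulus_pa Young's modulus E, Pa, positive.
#' @param poisson_ratio Poisson's ratio nu, in `[0, 0.5)`.
#' @param half_angle_deg Indenter half-angle alpha, degrees, in (0, 90).
#' @param delta_m Indentation depth(s) delta, meters, non-negative
#'   (vectorized).
#' @param prefactor `"canonical"` (2/pi, the Sneddon cone result) or
#'   `"typeset"` (2*pi), the latter only for sensitivity checks against
#'   sources that print the law with the constant on the wrong side of the
#'   fraction bar.
#' @return Force in newtons, same length as `delta_m`.
#' @examples
#' sneddon_force(1000, 0.3, 20, 1e-6) # 2.546e-10 N
#' @export
sneddon_force <- function(modulus_pa, poisson_ratio, half_angle_deg, delta_m,
                          prefactor = c("canonical", "typeset")) {
  prefactor <- match.arg(prefactor)
  if (any(delta_m < 0)) stop("indentation `delta_m` must be non-negative")
  if (modulus_pa <= 0) stop("`modulus_pa` must be positive")
  pf <- if (prefactor == "canonical") 2 / pi else 2 * pi
  pf * modulus_pa / (1 - poisson_ratio^2) *
    tan(half_angle_deg * pi / 180) * delta_m^2
}

#' Hertz force law for a spherical indenter
#'
#' Force on a rigid sphere of radius R pressed a depth delta into a flat
#' elastic half-space:
#' \deqn{F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}}
#'
#' @inheritParams sneddon_force
#' @param radius_m Sphere radius R, meters, positive.
#' @return Force in newtons, same length as `delta_m`.
#' @examples
#' hertz_force(1000, 0.3, 500e-9, 100e-9) # 3.276e-11 N
#' @export
hertz_force <- function(modulus_pa, poisson_ratio, radius_m, delta_m) {
  if (any(delta_m < 0)) stop("indentation `delta_m` must be non-negative")
  if (radius_m <= 0) stop("`radius_m` must be positive")
  if (modulus_pa <= 0) stop("`modulus_pa` must be positive")
  (4 / 3) * modulus_pa / (1 - poisson_ratio^2) * sqrt(radius_m) * delta_m^1.5
}

# geometry term g(delta) with F = E * g(delta); linearity in E is what makes
# the per-contact-point modulus a closed-form least-squares solution
geometry_term <- function(delta_m, settings, tip) {
  d <- pmax(delta_m, 0)
  if (settings$model == "sneddon") {
    if (tip$kind != "pyramidal")
      stop("sneddon model requires a pyramidal tip")
    pf <- if (settings$sneddon_prefactor == "canonical") 2 / pi else 2 * pi
    pf / (1 - settings$poisson_ratio^2) *
      tan(tip$half_angle_deg * pi / 180) * d^2
  } else {
    if (tip$kind != "spherical")
      stop("hertz model requires a spherical tip")
    (4 / 3) / (1 - settings$poisson_ratio^2) * sqrt(tip$radius_m) * d^1.5
  }
}

model_force <- function(modulus_pa, delta_m, settings, tip) {
  modulus_pa * geometry_term(delta_m, settings, tip)
}

# derivative dF/ddelta, used by the synthetic generator's Newton solve
model_force_deriv <- function(modulus_pa, delta_m, settings, tip) {
  d <- pmax(delta_m, 0)
  if (settings$model == "sneddon") {
    pf <- if (settings$sneddon_prefactor == "canonical") 2 / pi else 2 * pi
    2 * pf * modulus_pa / (1 - settings$poisson_ratio^2) *
      tan(tip$half_angle_deg * pi / 180) * d
  } else {
    2 * modulus_pa / (1 - settings$poisson_ratio^2) * sqrt(tip$radius_m * d)
  }
}

#' Remove the pre-contact baseline from a force curve
#'
#' Fits a straight line to the off-contact (low-z on approach) portion of the
#' deflection signal and subtracts it from the whole curve, so that the free
#' cantilever reads zero deflection with zero tilt. Required before contact
#' detection and fitting; optical interference and drift otherwise bias the
#' contact point.
#'
#' @param curve A [raw_force_curve()].
#' @param precontact_fraction Fraction of samples at the start of the
#'   approach assumed off-contact. Default 0.2.
#' @return The curve with baseline-corrected deflection; the fitted
#'   `(intercept, slope)` (deflection units, and per meter of z) is recorded
#'   in `labels$baseline`.
#' @export
correct_baseline <- function(curve, precontact_fraction = 0.2) {
  n <- length(curve$z_m)
  m <- max(8L, floor(n * precontact_fraction))
  idx <- if (curve$direction == "approach") seq_len(m) else seq(n - m + 1L, n)
  z0 <- curve$z_m[idx]; d0 <- curve$deflection[idx]
  fit <- stats::lm.fit(cbind(1, z0), d0)
  co <- fit$coefficients
  curve$deflection <- curve$deflection - (co[1] + co[2] * curve$z_m)
  curve$labels$baseline <- list(intercept = unname(co[1]),
                                slope_per_m = unname(co[2]),
                                n_precontact = m)
  curve
}

#' Build a force-indentation curve from a raw curve and a contact point
#'
#' Applies the cantilever relations F = k d and delta = (z - z0) - d beyond
#' the contact point, with d the deflection in meters (converted from volts
#' via the deflection sensitivity when needed) measured relative to its
#' value at contact.
#'
#' @param curve A baseline-corrected [raw_force_curve()] (approach).
#' @param contact_index Sample index of tip-sample contact.
#' @return An object of class `indentation_curve`: `delta_m` (ascending,
#'   starting at 0), `force_n`, `contact_index`, `contact_z_m` and the
#'   recorded `baseline`.
#' @export
build_indentation <- function(curve, contact_index) {
  n <- length(curve$z_m)
  if (contact_index < 1 || contact_index > n - 1)
    stop("`contact_index` out of range")
  d <- deflection_m(curve)
  k <- curve$calibration$spring_constant_n_per_m
  j <- contact_index:n
  dz <- curve$z_m[j] - curve$z_m[contact_index]
  drel <- d[j] - d[contact_index]
  structure(list(delta_m = dz - drel,
                 force_n = k * d[j],
                 contact_index = as.integer(contact_index),
                 contact_z_m = curve$z_m[contact_index],
                 baseline = curve$labels$baseline),
            class = "indentation_curve")
}

# Score every candidate contact index in `cand`: the modulus is the
# closed-form least squares E = sum(F g)/sum(g^2) over post-contact samples
# inside the indentation window, and the candidate's score is the total
# squared residual of the piecewise model {zero force before contact,
# E g(delta) after contact} over the WHOLE curve, so a candidate cannot
# look good by excluding the data that contradicts it. delta is anchored on
# the piezo position alone (the baseline-corrected pre-contact deflection
# averages zero); anchoring on the candidate's own deflection sample would
# inject that sample's noise into every delta. Shared by the production
# coarse-to-fine search and by fit reporting.
score_contact_candidates <- function(z, d, k, settings, tip, cand,
                                     min_fit_points = 10L) {
  FF <- k * d
  n <- length(z)
  idx <- seq_len(n)
  lapply(cand, function(i) {
    delta <- (z - z[i]) - d
    post <- delta > 0 & idx > i
    g <- numeric(n)
    g[post] <- geometry_term(delta[post], settings, tip)
    win <- post & delta <= settings$max_indentation_m
    n_fit <- sum(win)
    if (n_fit < min_fit_points) return(list(ok = FALSE, ss = Inf))
    sg2 <- sum(g[win]^2)
    if (sg2 == 0) return(list(ok = FALSE, ss = Inf))
    E <- sum(FF[win] * g[win]) / sg2
    if (!is.finite(E) || E <= 0) return(list(ok = FALSE, ss = Inf))
    res <- FF - E * g
    ss <- sum(res^2)
    ss_tot <- sum((FF - mean(FF))^2)
    list(ok = TRUE, ss = ss, modulus_pa = E, n_fit = n_fit,
         rmse_n = sqrt(mean(res[win]^2)),
         rsq = if (ss_tot > 0) 1 - ss / ss_tot else NA_real_,
         delta_max_m = max(delta[win]), delta_reach_m = max(delta))
  })
}

# linearization constants: the contact laws can be written
# z = z0 + d + (k d / (c E))^(1/expo), i.e. z - d is LINEAR in
# x = (k d)^(1/expo) with slope s = (c E)^(-1/expo) and intercept z0.
# Sneddon: expo = 2 (x = sqrt(F)); Hertz: expo = 3/2 (x = F^(2/3)).
linearization_constants <- function(settings, tip) {
  nu2 <- 1 - settings$poisson_ratio^2
  if (settings$model == "sneddon") {
    pf <- if (settings$sneddon_prefactor == "canonical") 2 / pi else 2 * pi
    list(c = pf * tan(tip$half_angle_deg * pi / 180) / nu2, expo = 2)
  } else {
    list(c = (4 / 3) * sqrt(tip$radius_m) / nu2, expo = 1.5)
  }
}

# Refine (E, z0) by the linearized contact regression. The piezo position
# is noise-free, so regressing y = z - d on x = (k d)^(1/expo) puts all the
# measurement noise in the response except for what leaks into x; the
# remaining errors-in-variables terms are removed by moment corrections
# computed from the pre-contact noise variance, and the fit subset is
# chosen on a smoothed deflection (and above a 5-sigma deflection floor) so
# that no point selects itself in or out through its own noise. Exact on
# noiseless curves; a few fixed-point iterations settle the subset.
linearized_contact_fit <- function(z, d, k, settings, tip, z0_init,
                                   noise_floor_sd = 5, smooth_window = 31L,
                                   iters = 6L, min_fit_points = 10L) {
  lc <- linearization_constants(settings, tip)
  n <- length(z)
  npre <- max(8L, floor(0.2 * n))
  sig2 <- stats::var(d[seq_len(npre)])
  sig <- sqrt(sig2)
  dsm <- stats::filter(d, rep(1 / smooth_window, smooth_window), sides = 2)
  dsm <- as.numeric(dsm)
  dsm[is.na(dsm)] <- d[is.na(dsm)]
  z0 <- z0_init
  out <- NULL
  for (it in seq_len(iters)) {
    delta_sm <- (z - z0) - dsm
    sel <- which(dsm > noise_floor_sd * sig & d > 0 & delta_sm > 0 &
                   delta_sm <= settings$max_indentation_m)
    if (length(sel) < min_fit_points) return(out)
    ds <- d[sel]
    x <- (k * ds)^(1 / lc$expo)
    hp <- (k / lc$expo) * (k * ds)^(1 / lc$expo - 1)  # dx/dd
    y <- z[sel] - ds
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    sxx <- sum((x - mean(x))^2)
    s_hat <- (sxy + sig2 * sum(hp)) / (sxx - sig2 * sum(hp^2))
    if (!is.finite(s_hat) || s_hat <= 0) return(out)
    z0 <- mean(y) - s_hat * mean(x)
    out <- list(modulus_pa = s_hat^(-lc$expo) / lc$c, z0 = z0,
                sel = sel, sigma_d = sig)
  }
  out
}

# deflection at piezo extension u = z - z0 past contact: solves
# k d = F_model(u - d) by vectorized Newton iteration
solve_deflection <- function(u, modulus_pa, settings, tip, k) {
  di <- pmin(u, model_force(modulus_pa, u, settings, tip) / k)
  for (it in 1:60) {
    delta <- pmax(u - di, 0)
    f <- model_force(modulus_pa, delta, settings, tip)
    fp <- model_force_deriv(modulus_pa, delta, settings, tip)
    step <- (k * di - f) / (k + fp)
    di <- pmin(pmax(di - step, 0), u)
    if (max(abs(step)) < 1e-22) break
  }
  di
}

#' Locate the tip-sample contact point
#'
#' Finds the contact index that minimizes the total squared residual of a
#' piecewise model: zero force before contact, the configured contact model
#' (with its closed-form least-squares modulus) after contact, evaluated
#' over samples within the indentation window. The search is coarse-to-fine
#' (every 8th sample, then exhaustive within +/- 8 of the coarse optimum)
#' and deterministic; ties break toward the smaller index.
#'
#' @param curve A baseline-corrected [raw_force_curve()] (approach,
#'   deflection convertible to meters).
#' @param settings A [sample_class_settings()].
#' @param tip Tip geometry; defaults to the curve's own tip.
#' @param details If `TRUE` return the full candidate record (index, modulus,
#'   residuals, R^2) instead of just the index.
#' @return The contact sample index (integer), or the detail list. When no
#'   candidate reaches R^2 >= 0.8 the result carries `poor_fit = TRUE`
#'   (index is still the best found; `NA` if nothing was fittable).
#' @export
find_contact_point <- function(curve, settings, tip = curve$tip,
                               details = FALSE) {
  z <- curve$z_m; d <- deflection_m(curve)
  k <- curve$calibration$spring_constant_n_per_m
  n <- length(z)
  best <- contact_search(z, d, k, settings, tip)
  if (details) return(best)
  best$contact_index
}

contact_search <- function(z, d, k, settings, tip, min_fit_points = 10L) {
  n <- length(z)
  i_max <- n - min_fit_points
  if (i_max < 1)
    return(list(contact_index = NA_integer_, poor_fit = TRUE))
  coarse <- unique(pmin(seq(1L, i_max, by = 8L), i_max))
  pick_best <- function(cand) {
    sc <- score_contact_candidates(z, d, k, settings, tip, cand,
                                   min_fit_points)
    ss <- vapply(sc, `[[`, numeric(1), "ss")
    if (all(!is.finite(ss))) return(NULL)
    j <- which.min(ss)  # which.min takes the first (smallest index) on ties
    c(list(contact_index = as.integer(cand[j])), sc[[j]])
  }
  top <- pick_best(coarse)
  if (is.null(top))
    return(list(contact_index = NA_integer_, poor_fit = TRUE))
  fine <- max(1L, top$contact_index - 8L):min(i_max, top$contact_index + 8L)
  top <- pick_best(fine)
  top$poor_fit <- !is.finite(top$rsq) || top$rsq < 0.8
  top
}

#' Fit a Young's modulus to a raw force curve
#'
#' Full single-curve pipeline: baseline correction, the discrete
#' contact-point search ([find_contact_point()]), then a refinement of
#' (E, contact) by the linearized contact regression: both contact laws can
#' be rewritten as z - d linear in (k d)^(1/2) (Sneddon) or (k d)^(2/3)
#' (Hertz), with slope determined by E and intercept equal to the contact
#' position, so a single error-corrected linear fit over the indentation
#' window (2 um cells, 5 um whole skin reconstructs, 700 nm cryosections)
#' extracts both without the attenuation bias a naive force-vs-indentation
#' regression suffers when deflection noise leaks into the indentation.
#' When the sample thickness is known and the fitted depth exceeds one
#' third of it, the fit is flagged `thickness_rule_violated` and
#' `apparent_modulus_Ea`: the number is then a realistic stiffness
#' approximation rather than a strict elastic modulus, because the
#' substrate contributes to the measured force.
#'
#' @param curve A [raw_force_curve()] (approach; deflection in meters or in
#'   volts with a sensitivity).
#' @param settings A [sample_class_settings()]; its model must match the tip
#'   (sneddon-pyramidal, hertz-spherical).
#' @param precontact_fraction Passed to [correct_baseline()].
#' @return An object of class `elastic_fit`: `modulus_pa`, `contact_index`,
#'   `rmse_n`, `delta_max_m`, `n_points_fit`, `rsq` and a character vector
#'   `flags` drawn from `depth_truncated`, `thickness_rule_violated`,
#'   `apparent_modulus_Ea`, `thickness_unknown`, `poor_fit`.
#' @examples
#' st <- sample_class_settings("cell_2d")
#' cu <- simulate_curve(4000, st, default_tip("cell_2d"),
#'                      default_calibration("cell_2d"),
#'                      noise_force_frac = 0, n_samples = 512, seed = 1)
#' fit_modulus(cu, st)
#' @export
fit_modulus <- function(curve, settings, precontact_fraction = 0.2) {
  tip <- curve$tip
  if (settings$model == "sneddon" && tip$kind != "pyramidal")
    stop("sneddon settings require a pyramidal tip (curve has ", tip$kind, ")")
  if (settings$model == "hertz" && tip$kind != "spherical")
    stop("hertz settings require a spherical tip (curve has ", tip$kind, ")")
  if (curve$direction != "approach")
    stop("modulus fitting uses approach curves")
  corrected <- correct_baseline(curve, precontact_fraction)
  res <- find_contact_point(corrected, settings, tip, details = TRUE)
  if (is.null(res$ok) || !isTRUE(res$ok)) {
    return(structure(list(modulus_pa = NA_real_,
                          contact_index = res$contact_index,
                          rmse_n = NA_real_, delta_max_m = NA_real_,
                          n_points_fit = 0L, rsq = NA_real_,
                          flags = "poor_fit"),
                     class = "elastic_fit"))
  }
  z <- corrected$z_m
  d <- deflection_m(corrected)
  k <- corrected$calibration$spring_constant_n_per_m
  # the search fixes the starting point; the refinement re-decides contact
  # and modulus, so a mediocre search fit is not disqualifying by itself
  ref <- linearized_contact_fit(z, d, k, settings, tip,
                                z0_init = z[res$contact_index])
  poor <- FALSE
  if (is.null(ref)) {
    # refinement infeasible (e.g. noise floor swallows the curve):
    # report the search-stage estimate
    ref <- list(modulus_pa = res$modulus_pa, z0 = z[res$contact_index],
                sel = integer(0), sigma_d = NA_real_)
    rmse_n <- res$rmse_n
    n_fit <- res$n_fit
    delta_max <- res$delta_max_m
    delta_reach <- res$delta_reach_m
    rsq <- res$rsq
    poor <- isTRUE(res$poor_fit)
  } else {
    u <- pmax(z - ref$z0, 0)
    dm <- numeric(length(z))
    pos <- u > 0
    dm[pos] <- solve_deflection(u[pos], ref$modulus_pa, settings, tip, k)
    sel <- ref$sel
    rmse_n <- k * sqrt(mean((d[sel] - dm[sel])^2))
    n_fit <- length(sel)
    delta_model <- u - dm
    delta_max <- min(max(delta_model[sel]), settings$max_indentation_m)
    delta_reach <- max(delta_model)
    sstot <- sum((d - mean(d))^2)
    rsq <- if (sstot > 0) 1 - sum((d - dm)^2) / sstot else NA_real_
    poor <- !is.finite(rsq) || rsq < 0.8
  }
  flags <- if (poor) "poor_fit" else character()
  if (delta_reach < settings$max_indentation_m)
    flags <- c(flags, "depth_truncated")
  if (is.null(settings$thickness_m)) {
    if (settings$sample_class != "cell_2d")
      flags <- c(flags, "thickness_unknown")
  } else if (delta_max > settings$thickness_m / 3) {
    flags <- c(flags, "thickness_rule_violated", "apparent_modulus_Ea")
  }
  structure(list(modulus_pa = ref$modulus_pa,
                 contact_index = which.min(abs(z - ref$z0)),
                 rmse_n = rmse_n,
                 delta_max_m = delta_max,
                 n_points_fit = n_fit,
                 rsq = rsq,
                 flags = flags),
            class = "elastic_fit")
}

#' @export
print.elastic_fit <- function(x, ...) {
  cat(sprintf("<elastic_fit> E = %.4g kPa, contact @ %s, rmse %.3g nN, %d pts%s\n",
              x$modulus_pa / 1e3,
              ifelse(is.na(x$contact_index), "NA", x$contact_index),
              x$rmse_n * 1e9, x$n_points_fit,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
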