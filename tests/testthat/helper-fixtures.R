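# shared fixtures: class settings + matching probes, built in code

cell_setup <- function(...) {
  list(settings = sample_class_settings("cell_2d", ...),
       tip = default_tip("cell_2d"),
       cal = default_calibration("cell_2d"))
}

cryo_setup <- function(...) {
  list(settings = sample_class_settings("cryosection", ...),
       tip = default_tip("cryosection"),
       cal = default_calibration("cryosection"))
}

hsr_setup <- function(...) {
  list(settings = sample_class_settings("hsr_whole", ...),
       tip = default_tip("hsr_whole"),
       cal = default_calibration("hsr_whole"))
}

# rasterized shapes for morphometrics tests
raster_disk <- function(radius_px, pad = 14L) {
  n <- 2L * radius_px + 2L * pad
  img <- matrix(0, n, n)
  c0 <- (n + 1) / 2
  img[(row(img) - c0)^2 + (col(img) - c0)^2 <= radius_px^2] <- 1
  img
}

raster_ellipse <- function(a_px, b_px, pad = 14L) {
  n <- 2L * max(a_px, b_px) + 2L * pad
  img <- matrix(0, n, n)
  c0 <- (n + 1) / 2
  img[((row(img) - c0) / a_px)^2 + ((col(img) - c0) / b_px)^2 <= 1] <- 1
  img
}

# independent brute-force contact search: every admissible index, explicit
# through-origin least squares, whole-curve piecewise residual
brute_force_contact <- function(curve, settings, tip = curve$tip,
                                min_fit_points = 10L) {
  z <- curve$z_m
  d <- curve$deflection
  k <- curve$calibration$spring_constant_n_per_m
  n <- length(z)
  stopifnot(curve$deflection_unit == "m")
  geom <- function(delta) {
    if (settings$model == "sneddon")
      (2 / pi) * tan(tip$half_angle_deg * pi / 180) /
        (1 - settings$poisson_ratio^2) * delta^2
    else
      (4 / 3) * sqrt(tip$radius_m) / (1 - settings$poisson_ratio^2) *
        delta^1.5
  }
  FF <- k * d
  best_i <- NA_integer_; best_E <- NA_real_; best_ss <- Inf
  for (i in seq_len(n - min_fit_points)) {
    delta <- (z - z[i]) - d
    post <- delta > 0 & seq_len(n) > i
    g <- numeric(n)
    g[post] <- geom(delta[post])
    win <- post & delta <= settings$max_indentation_m
    if (sum(win) < min_fit_points) next
    E <- sum(FF[win] * g[win]) / sum(g[win]^2)
    if (!is.finite(E) || E <= 0) next
    ss <- sum((FF - E * g)^2)
    if (ss < best_ss) { best_ss <- ss; best_i <- i; best_E <- E }
  }
  list(contact_index = best_i, modulus_pa = best_E)
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
perm_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combs <- utils::combn(length(pooled), n_a)
  w_all <- apply(combs, 2, function(ix) sum(ranks[ix]) - n_a * (n_a + 1) / 2)
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(1, p)
}
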