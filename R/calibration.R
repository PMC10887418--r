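#' Thermal-noise deflection trace
#'
#' Time series of cantilever deflection recorded away from the surface, used
#' for the thermal-tune spring-constant calibration.
#'
#' @param deflection_m Deflection samples, meters.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param temperature_k Temperature, kelvin, in (250, 350).
#' @return An object of class `thermal_trace`.
#' @export
thermal_trace <- function(deflection_m, sample_rate_hz, temperature_k) {
  if (length(deflection_m) < 4096)
    stop("thermal traces need at least 4096 samples")
  if (!is.finite(temperature_k) || temperature_k <= 250 || temperature_k >= 350)
    stop("`temperature_k` must lie in (250, 350)")
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("`sample_rate_hz` must be positive")
  structure(list(deflection_m = as.numeric(deflection_m),
                 sample_rate_hz = sample_rate_hz,
                 temperature_k = temperature_k),
            class = "thermal_trace")
}

#' Deflection sensitivity from a rigid-substrate contact curve
#'
#' On an effectively rigid substrate (sapphire) the tip cannot indent, so in
#' contact the photodiode voltage rises linearly with piezo position and the
#' inverse slope is the optical-lever sensitivity (meters of deflection per
#' volt). The contact segment is found deterministically: linear fits over
#' every window of the curve (anchored scan from the high-z end first), and
#' the longest window achieving R^2 >= 0.99 with positive slope wins. The
#' slope is then refit on the upper 75% of the deflection range of that
#' window, which excises the curvature left around the contact kink and
#' removes the bias it would otherwise put on the sensitivity.
#'
#' @param curve A [raw_force_curve()] with deflection in volts, acquired on
#'   a rigid substrate.
#' @param min_window Smallest admissible contact window, samples.
#' @param rsq_min Linearity requirement for the contact segment.
#' @return Deflection sensitivity, m/V (positive).
#' @examples
#' # a 0.05 V/nm contact slope corresponds to 20 nm/V
#' @export
deflection_sensitivity_from_contact <- function(curve, min_window = 16L,
                                                rsq_min = 0.99) {
  if (!identical(curve$deflection_unit, "V"))
    stop("sensitivity calibration needs deflection in volts")
  z <- curve$z_m; v <- curve$deflection
  n <- length(z)
  # cumulative sums make every (start, length) window fit O(1)
  cz <- cumsum(z); cv <- cumsum(v)
  czz <- cumsum(z * z); cvv <- cumsum(v * v); czv <- cumsum(z * v)
  wsum <- function(cs, a, b) cs[b] - ifelse(a > 1, cs[pmax(a - 1, 1)], 0)
  for (len in seq(n, min_window)) {
    starts <- seq_len(n - len + 1L)
    ends <- starts + len - 1L
    sz <- wsum(cz, starts, ends); sv <- wsum(cv, starts, ends)
    szz <- wsum(czz, starts, ends); svv <- wsum(cvv, starts, ends)
    szv <- wsum(czv, starts, ends)
    sxx <- szz - sz^2 / len
    syy <- svv - sv^2 / len
    sxy <- szv - sz * sv / len
    slope <- sxy / sxx
    rsq <- ifelse(syy > 0, sxy^2 / (sxx * syy), NA_real_)
    ok <- which(is.finite(rsq) & rsq >= rsq_min & slope > 0)
    if (length(ok)) {
      # prefer the window nearest the high-z (contact) end
      j <- ok[which.max(ends[ok])]
      win <- starts[j]:ends[j]
      vw <- v[win]
      sel <- win[vw >= min(vw) + 0.25 * (max(vw) - min(vw))]
      if (length(sel) >= 8) {
        co <- stats::lm.fit(cbind(1, z[sel]), v[sel])$coefficients
        if (is.finite(co[2]) && co[2] > 0) return(unname(1 / co[2]))
      }
      return(1 / slope[j])
    }
  }
  stop("calibration failure: no linear contact region with R^2 >= ", rsq_min)
}

# Boltzmann constant, J/K
.kB <- 1.380649e-23

#' Spring constant by the thermal-tune (equipartition) method
#'
#' Equipartition assigns k_B T / 2 of energy to the cantilever's fundamental
#' bending mode, so k = beta * k_B * T / var(d), where the factor
#' beta = 0.971 corrects for the fact that the optical lever reads the
#' end-slope-calibrated deflection of the first mode of a rectangular
#' cantilever rather than an ideal point mass.
#'
#' @param trace A [thermal_trace()]; the mean is removed internally.
#' @param beta First-mode correction factor; default 0.971.
#' @return Spring constant, N/m.
#' @export
spring_constant_thermal <- function(trace, beta = 0.971) {
  if (!inherits(trace, "thermal_trace")) stop("`trace` must be a thermal_trace")
  d <- trace$deflection_m - mean(trace$deflection_m)
  v <- mean(d^2)
  if (v <= 0) stop("calibration failure: thermal trace has zero variance")
  beta * .kB * trace$temperature_k / v
}
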