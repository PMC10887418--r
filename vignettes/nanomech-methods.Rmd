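---
title: "Methods: contact-model stiffness extraction and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-model stiffness extraction and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and numerical choices behind
`nanomech`, and what the synthetic-data validation does and does not
demonstrate about real instrument data.

## The measurement model

An AFM force curve is a ramp of piezo positions `z` (strictly monotone,
2048 samples per curve by default) with the cantilever deflection `d` read
at each position. With the cantilever spring constant `k` (N/m), force is
`F = k d`; past the tip–sample contact at `z0`, the indentation is
`delta = (z − z0) − d`. Two rigid-indenter contact laws connect force to
indentation on an elastic half-space:

* Sneddon, for pyramidal/conical tips with face half-angle `alpha`:
  `F = (2/pi) * E/(1 − nu^2) * tan(alpha) * delta^2`
* Hertz, for spherical tips of radius `R`:
  `F = (4/3) * E/(1 − nu^2) * sqrt(R) * delta^(3/2)`

`E` is the Young's modulus (Pa; reported in kPa) and `nu` the Poisson
ratio, 0.3 by default for all sample classes, overridable per run. Both
laws assume a flat, homogeneous, purely elastic sample and a rigid
indenter; biological samples violate all of these to some degree, which is
why measured values are interpreted in relative terms across conditions
rather than as absolute material constants.

Some sources typeset the pyramidal prefactor ambiguously; the canonical
Sneddon cone result `2/pi` is the default, and
`sample_class_settings(..., sneddon_prefactor = "typeset")` switches to
`2*pi` purely for sensitivity analyses (the two differ by a constant factor
`pi^2/... ≈ 9.87`, so the choice rescales every modulus identically and
cancels from ratios).

## Sample classes and their windows

| class | model | tip | window | rationale |
|---|---|---|---|---|
| `cell_2d` | Sneddon | pyramidal, 18°, k = 0.4 N/m | 2 µm | thick adherent cells |
| `hsr_whole` | Hertz | spherical, R = 500 nm, k = 40 N/m | 5 µm | bulk skin reconstruct |
| `cryosection` | Sneddon | pyramidal, 18°, k = 0.4 N/m | 700 nm | thin sections |

The fit uses indentations up to the class window only. When the sample
thickness is known, indenting beyond one third of it means the substrate
contributes to the measured force; such fits are flagged
`thickness_rule_violated` and `apparent_modulus_Ea` (a usable stiffness
approximation, not a strict elastic modulus) rather than discarded. For
whole tissues of unknown thickness the rule cannot be checked and the fit
carries a `thickness_unknown` note. The pyramid half-angle is not a
quantity probe vendors always publish for sharp silicon-nitride tips; 18°
is the package default and is exposed as an explicit, mandatory part of
`tip_geometry()`.

Approach curves are the analysis substrate; retract curves (adhesion
hysteresis) are stored but not fitted.

## Contact-point search

`find_contact_point()` scans candidate contact indices (every 8th sample,
then exhaustively within ±8 of the coarse optimum; ties break toward the
smaller index, so the result is deterministic). Each candidate `i` is
scored by the total squared residual, over the whole curve, of the
piecewise model {zero force before `i`, `E·g(delta)` after `i`}, where the
geometry term `g` makes force linear in `E` and the per-candidate modulus
is therefore the closed-form least squares `E = sum(F g)/sum(g^2)` over
window points. Scoring the whole curve (not just the candidate's own
window) is essential: a candidate that excluded the contact region from
its residual could otherwise "win" by fitting near-zero force to the
baseline. `delta` is anchored on the piezo position alone — anchoring on
the candidate's own deflection sample would inject that single sample's
noise into every `delta` of the candidate.

On noiseless synthetic curves this search recovers the generating contact
index exactly and the search is provably equivalent to exhaustive
enumeration on short curves (the test suite checks 100 random 64-sample
instances against an independent brute-force implementation).

## Why the modulus is refined after the search

The closed-form estimator regresses `F` on `g(delta)` with
`delta = (z − z0) − d`. Deflection noise therefore contaminates the
regressor, and its effect on the residual is amplified by
`(1 + F'(delta)/k)` — a factor of ~14 at the window edge for a 16 MPa
cryosection on a 0.4 N/m lever. This correlated errors-in-variables
structure attenuates `E` severely on stiff samples (we measure roughly
−50% at 2% peak-force noise) while leaving soft samples almost unaffected.

`fit_modulus()` therefore refines `(E, z0)` with a linearized contact
regression. Both laws invert to

```
z  =  z0 + d + (k d / (c E))^(1/p)      p = 2 (Sneddon), 3/2 (Hertz)
```

so `y = z − d` is linear in `x = (k d)^(1/p)`, with slope
`(cE)^(−1/p)` and intercept `z0`. The piezo position `z` is noise-free, so
this orientation puts nearly all the noise into the response. Three
measures remove the remaining errors-in-variables effects, each computed
from the data with no tuning:

1. **Moment correction.** The pre-contact segment gives the deflection
   noise variance `sigma^2`; the cross- and self-contamination of the
   regression moments by the shared noise is subtracted
   (`Sxy + sigma^2*sum(h')`, `Sxx − sigma^2*sum(h'^2)` with `h' = dx/dd`).
2. **Noise floor.** Points with smoothed deflection below `5 sigma` carry
   no usable signal (their `x = (k d)^(1/p)` is dominated by noise through
   a strongly nonlinear map) and are excluded.
3. **Selection on smoothed deflection.** The fit subset (floor and
   indentation window) is chosen on a 31-sample moving average of `d`, so
   no point can select itself in or out of the fit through its own noise —
   selection on the raw values is itself a bias mechanism.

The subset and intercept are iterated to a fixed point (6 iterations,
initialized from the discrete search). On noiseless curves the refinement
is exact to machine precision, so the generator/fitter round-trip identity
(relative error < 1e-6, all classes, moduli from 0.5 kPa to 16 MPa) is
preserved. Under 2% force noise the test suite checks that the median
recovered modulus over a 16×16 volume stays within 10% of the generating
value for every acceptance scene, and within 3% for the cryosection class
at 10 kPa.

A fit is `poor_fit` when the refined model explains less than 80% of the
deflection variance, when fewer than 10 points fall in the window, or when
no candidate supports a positive modulus (e.g. an all-zero curve). Failed
pixels stay in stiffness maps as invalid entries; they are never silently
dropped.

## Calibration

The thermal-tune spring constant uses time-domain equipartition,
`k = beta * kB * T / var(d)`, with `beta = 0.971` the first-bending-mode
correction for a rectangular cantilever read by an optical lever. A PSD
fit would need spectral details the archive format does not carry;
equipartition is the minimal faithful implementation, and the generator
draws traces with variance `beta*kB*T/k` so the two compose to the
identity. Deflection sensitivity comes from a contact curve on a rigid
substrate: the longest window with `R^2 ≥ 0.99` and positive slope is
located (cumulative-sum sliding fits, longest window first, preferring the
high-z end), then the slope is refit on the upper 75% of that window's
deflection range to excise curvature around the contact kink; the
sensitivity is the inverse slope. A curve with no such window is a
calibration failure, by design.

## Morphometrics

Segmentation is Otsu (or fixed) thresholding followed by 8-connected
component labeling and small-object removal. Holes are filled before
measuring, because circularity and solidity describe the external margin.
Descriptors follow the Fiji conventions: area and perimeter in physical
units via the pixel size; aspect ratio from the second-moment matched
ellipse (with the 1/12 per-pixel variance term); circularity
`4*pi*A/P^2`; solidity as area over the convex hull of the pixel corner
points (corners, not centers — otherwise digitized convex shapes exceed
solidity 1). The perimeter uses the 4-direction Crofton estimator over
2×2 pixel configurations: naive boundary-pixel counting would bias the
circularity of a digitized disk to ~0.78, while the Crofton estimate
converges to 1 (checked at radii 10/30/100 px). One-pixel-wide objects
have no meaningful ellipse or hull and are returned flagged `degenerate`
instead of erroring.

## Group comparison

`compare_groups()` implements the fixed decision tree used for every
two-group panel: Shapiro–Wilk on each group at `alpha = 0.05`; if both
pass, Levene's test (classical form, centered on group means — the
median-centered variant is Brown–Forsythe, a different named test)
selects the pooled-variance Student t-test, or Welch's t-test when
variances differ; if either group fails normality, the two-sided Wilcoxon
rank-sum test. What happens when Levene rejects under normality is not
prescribed by the procedure's usual one-line description; Welch is the
standard remedy and keeps the branch t-based. All tests are two-sided and
unpaired. Wilcoxon uses exact enumeration when the smaller group has ≤ 12
observations and no ties, otherwise the normal approximation with
continuity correction and midranks. Stars follow the strict thresholds
`*** < 0.001 ≤ ** < 0.01 ≤ * < 0.05 ≤ ns`. The suite verifies the
procedure's type-I error on null normal data (0.05 ± 0.01 over 2000
replicates), its argument symmetry, and exact agreement of the Wilcoxon
branch with full permutation enumeration for small samples.

## What the synthetic generator does and does not emulate

The generator inverts the exact contact models: baseline, contact point,
then deflection solved from `k d = F(z − z0 − d)` by vectorized Newton
iteration to machine precision, with Gaussian force noise (expressed as a
fraction of peak force, default 0.02 — instruments report no universal
noise floor, so this is a documented free parameter of every recovery
claim), optional linear baseline tilt, and per-pixel contact jitter in
volumes. Scenes are partitions of a grid into labeled regions with fixed
true moduli; cell images are non-overlapping rasterized ellipses with
low-order radial harmonics for margin roughness.

Passing the recovery suites therefore demonstrates that the estimators
invert the stated models under additive Gaussian force noise — it does not
demonstrate robustness to what real curves additionally contain:
viscoelastic rate dependence, adhesion on retract, substrate effects
beyond the 1/3-rule flag, drift between pixels of a volume, optical
interference fringes, or segmentation over touching cells. Those are
documented non-goals; the package reports flags rather than attempting
corrections.

## Reference values and problem sizes

`inst/extdata/reference_moduli.yaml` carries the published reference
stiffnesses that seed the acceptance scenes: 4 kPa for normal melanocytes
in 2D, 16,000 and 12,000 kPa for skin-reconstruct sections grown with
non-invasive (IC8) and invasive (T1C3) melanoma cells, and the two-fold
IC8:T1C3 contrast in 2D culture. Absolute 2D moduli for the two clones
were not published, so only their ratio is pinned; the acceptance scene
uses 2 and 1 kPa (softer than the 4 kPa melanocyte anchor, as melanoma
cells are) and reports the recovered ratio, which is scale-free.

Validation problem sizes are chosen to exercise the full acquisition
geometry where it matters — acceptance scenes are 16×16 volumes of
2048-sample curves, the instrument's native format — while unit tests use
smaller grids and shorter curves (the per-pixel code path is identical at
any size). The statistics suite uses 2000 null replicates, sized so the
binomial standard error (~0.005) resolves the ±0.01 acceptance band.

## Known limitations

* The contact point of a soft sample is intrinsically weakly identified:
  the quadratic force onset stays below a 2% peak-force noise floor for
  tens of samples, so per-curve contact indices scatter by roughly ±15
  samples there. The modulus is insensitive to this (the linearized fit's
  slope does not depend on the intercept), which is why recovery holds at
  the few-percent level regardless.
* On very stiff samples a few-percent positive residual bias remains after
  the moment corrections (higher-order noise terms in `(k d)^(1/2)` near
  the noise floor); it is well inside the 10% acceptance band.
* Only the documented archive format is read; proprietary instrument
  formats are out of scope, as are viscoelastic and adhesive contact
  models and substrate-correction schemes.
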