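---
title: "Methods: optical proxies of DOM aromaticity and DOC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical proxies of DOM aromaticity and DOC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domoptics)
```

This vignette documents the models implemented in domoptics, their
assumptions, the numerical choices made where the underlying methods leave
room, and what the synthetic-data generator does and does not emulate. It
states no empirical result that the package's tests and acceptance script
do not themselves compute.

## Fluorescence indices

All indices are intensity ratios taken from a fully corrected EEM — the
package assumes instrument spectral correction, inner-filter correction and
scatter removal happened upstream (an optional `mask_scatter()` utility can
excise and interpolate residual Rayleigh/Raman ridges, off by default).
Ratios are invariant to any positive rescaling of the EEM, so the
intensity units never matter.

ARIX is the emission ratio 520/390 nm at excitation 320 nm. The two
wavelengths sit on the *shoulders* of the long-emission (humic-like, peak
above 500 nm) and short-emission (peak near 400 nm) fluorophore groups
rather than on their peaks, to avoid overlapping non-target fluorophores
and the water Raman line (at 320 nm excitation the ~3500 cm⁻¹ Raman shift
lands near 359 nm emission, safely below 390).

**Interpolation.** Off-grid wavelengths are evaluated by bilinear
interpolation: linear in excitation between the two adjacent slices, then
linear in emission. Exact grid hits return stored values. Extrapolation is
never performed — the index wavelengths were chosen to sit in clean
spectral regions, and fabricating data beyond the measured grids would
defeat that; out-of-range requests are errors, and an index whose
wavelengths the grids cannot support is reported `NA`, never silently
zero. Whether reference implementations use nearest-neighbour or
interpolated lookup is not standardized; bilinear interpolation is this
package's documented choice.

**Band integrals.** HIX-type band sums (300–345, 435–480 nm) and the
freshness maximum (420–435 nm) are simple sums/maxima over a 1 nm linearly
interpolated emission grid with inclusive endpoints. The constant grid
factor cancels in every ratio; tests verify 1% agreement between the HIX
ratios and a trapezoid-integral oracle for native grids at 1–2 nm spacing.
By construction `HIX = HIX1999 / (1 + HIX1999)` (shared numerator; HIX
adds it to the denominator), which holds to machine precision.

**Detection floor.** At very low signal the ARIX denominator approaches
zero and the ratio degenerates to noise. A configurable floor
(`arix(eem, floor = )`) flags such values `NA`; the default is 0
(disabled) because no universal numeric limit exists — it depends on the
instrument.

## CDOM absorbance

Spectra store the dimensionless decadic cell reading plus the path length
in meters. Conversions are explicit and never implicit:
`absorbance_per_meter()` gives the decadic m⁻¹ convention in which A254
enters SUVA (a 1 cm cell reading × 100), and `napierian_coefficient()`
gives `a(λ) = ln(10)·A(λ)/l` used by the DOC literature models. `ln(10)`
is used at full precision, not 2.303, so round trips are bit-stable.

`spectral_slope()` fits `a(λ) = a(λ_ref)·exp(S(λ_ref − λ))` over a band
(default 275–295 nm) by two methods, because the two literature lineages
that consume S275–295 estimate it differently:

* **loglinear** — OLS of `ln a(λ)` on λ; `S = −slope`. Requires strictly
  positive absorbance in the band.
* **nonlinear** — unweighted Levenberg–Marquardt least squares of the
  exponential itself (via minpack.lm), reference wavelength fixed at the
  band's upper edge, initialized from the log-linear estimate. If the
  optimizer fails, the error carries the log-linear fallback.

Both are exact (and equal) on noise-free exponentials and invariant to
amplitude scaling. Internally S is stored in nm⁻¹; the interaction-model
proxy uses 1/S with S in µm⁻¹, while the UV-slope model formulas consume
nm⁻¹ (their constants 0.078 and 0.0084 only make sense there). The
conversion happens once, at the model boundary. The S380–443 band defaults
to the same method choice as whichever model consumes it.

## Regression engines

`ols_fit()` is ordinary least squares, optionally through the origin.
`robust = TRUE` switches to iteratively reweighted least squares with
Tukey bisquare weights, tuning constant 4.685 and a
median-absolute-deviation residual scale (`s = median|r|/0.6745`),
iterating to a 1e-8 maximum coefficient change or 50 iterations. These are
the conventional defaults behind common statistics toolboxes'
automatic-outlier-exclusion option; they are a documented convention here,
not a requirement of the science. If the MAD scale collapses to zero (an
exact fit on the majority), iteration stops.

`gm_fit()` is the geometric-mean (reduced major axis) model II regression:
`slope = sign(r)·s_y/s_x`, intercept through the means, slope SE
`≈ |slope|·sqrt((1 − r²)/n)`. It is the right tool when both variables
carry error — e.g. a calibration pooled across instruments — and
coincides with model I only at perfect correlation. Zero correlation
leaves the slope sign undefined and is an error rather than an arbitrary
tie-break. Note the geometric slope is not a consistent estimator of a
structural slope under arbitrary error ratios; it equals it only when the
error-variance ratio matches the slope, which is why the package reports
it as a calibration convention rather than an errors-in-variables MLE
(explicitly out of scope).

`fit_metrics()` defines `R² = 1 − RSS/TSS` about the observed mean — this
can be negative, flagging a model that predicts worse than a horizontal
line — and RMSE on the `n − k` degrees-of-freedom denominator.

## Published proxy registry

`published_models()` is an immutable table of the printed calibrations;
tests assert its coefficients digit for digit. Two choices worth noting:

* The global whole-water relation `SUVA = 6.1·ARIX − 0.7` predicts
  negative SUVA below ARIX ≈ 0.115. The package returns the negative value
  with a warning instead of clamping: observed whole-water ARIX spans
  roughly 0.15–1.1, so a negative prediction is a signal that the input is
  outside the calibrated domain, which the caller should see.
* The percent-aromaticity relation is exposed in both printed forms (via
  SUVA and via ARIX). Composing the through-origin extract calibration
  (slope 4.5) into the ¹³C-NMR relation (slope 6.52) gives 29.34 per unit
  ARIX versus the printed 29.3 — rounding at print time; tests check the
  composition to 0.05. The ARIX form carries the caveat that it assumes
  extract fluorescence trends carry over to bulk DOM.

## The DOC model family

Units are fixed per model and never converted silently: base/interaction
fits use mg/L DOC and decadic A254 m⁻¹; the Pan-Arctic model uses
Napierian a350 and S in µm⁻¹ (the scale on which its printed coefficients
are of order 0.04–0.07 against S ≈ 15–25); the UV-slope models use
Napierian a275, slopes in nm⁻¹ and µmol/L DOC, converted to mg/L through
12.011 g/mol. Each fit object records its proxy kind and refuses
prediction with any other.

The interaction model includes aromaticity *only* through the interaction
term, never as a main effect: fluorescence and slope proxies are undefined
at zero absorbance, so a main effect could take on meaningless values. A
constant proxy makes `A254` and `A254·P` collinear; the fit detects the
rank deficiency and errors rather than returning an arbitrary solution.
Rearranged, the model reads `A254 = (DOC − b0)/(b1 + b2·P)`: colored DOC
`cDOC = DOC − b0` absorbs with apparent absorptivity `∝ 1/(b1 + b2·P)`, a
Beer–Lambert form. `invert_a254()` implements exactly this inversion, so
`invert_a254 ∘ predict_doc` is the identity to 1e-10; the diagnostics
report `cDOC`, the absorptivity proxy (flagged `NA` where `b1 + b2·P ≤ 0`,
outside the physical regime) and the interaction ratio `b2·P/b1`.

**Standard errors.** The concentration-space fits (base, interaction)
report HC3 heteroscedasticity-consistent standard errors: DOC measurement
error typically scales with concentration, and across a realistically wide
(log-normal) DOC distribution homoscedastic OLS variances are
anti-conservative — simulation under 5% relative DOC noise shows 3-SE
intervals covering the truth at their nominal rate with HC3 but not with
classical SEs. The Pan-Arctic fit works in log space and the UV-slope fit
in variance-stabilized µM space, where classical SEs are kept.

**Pan-Arctic fitting** is OLS of `log10(DOC/a350)` on S275–295; the source
model's own fitting procedure is not fully specified, so OLS in log space
is the documented choice, and Napierian a350 is assumed as in the source.

**Information criteria** use the Gaussian profile log likelihood
`logL = −(n/2)(ln 2π + ln(RSS/n) + 1)` and
AIC/AICc/BIC/CAIC with `k` counting estimated model coefficients only:
0 for the fixed global UV-slope preset, 2 for base, Pan-Arctic and the
locally fitted UV-slope model, 3 for the interaction model. A
`count_sigma` flag adds one uniformly for the residual variance; the rank
order is unchanged. A perfect fit (RSS = 0) makes the likelihood
unbounded and is reported as a degenerate comparison rather than a
number. `compare_doc_models()` fits all feasible models on one shared
complete-case subset so every criterion sees the same `n`, reports each
model's percent RMSE change against the base model, and names the model
lowest on a majority of the four criteria, listing ties explicitly.

## Measurement-error simulation

The simulation asks how much scatter in a SUVA-vs-ARIX calibration pure
random measurement error could produce. `build_error_free()` keeps DOC and
ARIX as observed and replaces A254 with `(β1·ARIX + β0)·DOC` so every
sample lies exactly on the reference line (defaults 6.1, −0.7); a sample
whose ARIX implies negative A254 cannot lie on the line and is reported by
id. Each of the (default 100) runs adds independent Gaussian errors to
DOC, ARIX and A254 — each either absolute or relative — recomputes
SUVA = A254/DOC, refits the model I regression, and records its RMSE; the
summary is the median RMSE and its percentage of a supplied observed RMSE.

Two design points:

* **Refit versus fixed line.** The package refits per run by default,
  because prediction error is conventionally reported from fitted models;
  scoring against the fixed generating line is available via
  `refit = FALSE` and is slightly larger on average (the refit absorbs
  part of the noise).
* **Non-positive DOC.** Perturbed DOC ≤ 0 is resampled (bounded retries,
  counted in the result) rather than truncated, which preserves the
  zero-mean error assumption approximately. Truncation would bias SUVA
  upward.

The default noise magnitudes (DOC 5% relative, ARIX 0.05 absolute, A254 2%
relative) are placeholders at the scale of routine laboratory precision —
the true inter-laboratory error table behind published ratios is not
reproduced here — so the simulation's ratio output is only as meaningful
as the noise model supplied; calibrate it to your instruments.

## What the synthetic generator emulates — and what it does not

`synth_eem()` sums separable Gaussian × Gaussian fluorophore profiles.
Real EEM landscapes are *not* separable and contain scatter ridges,
inner-filter curvature and instrument bias; the separable form is a test
fixture chosen because every index then has a closed form
(`true_arix()`), making exact estimator verification possible. Passing
tests on this generator demonstrate correctness of the index arithmetic,
not robustness to real-world EEM artifacts. The default two-component
palette (long emission 510/60 nm, short 400/40 nm) sweeps ARIX over about
0.15–1.1 — the natural whole-water range — as the amplitude ratio varies.

`synth_absorbance()` is a single exponential; real CDOM spectra deviate
from one exponential across wide bands (which is exactly why slopes are
fitted on narrow bands).

`synth_dataset()` generates in the forward direction of the interaction
model: proxy P uniform on [0.2, 1.0] (where most natural whole-water ARIX
values fall), colored DOC log-normal (meanlog log 5, sdlog 0.5 — a
right-skewed few-to-tens mg/L range typical of inland waters),
`DOC = b0 + cDOC`, `A254 = cDOC/(b1 + b2·P)`, `SUVA = A254/DOC`, then
noise. Defaults `b0 = 0.8`, `b1 = 0.8`, `b2 = −0.5` keep `b1 + b2·P`
within [0.3, 0.7], SUVA within the natural 1–6 m² g⁻¹ band, the
interaction ratio within roughly −0.1 to −0.6, and `b1 > 0 > b2` — the
regime the models describe. A truth spec with `b1 + b2·P ≤ 0` anywhere in
the proxy support is rejected before generation. `synth_suva_table()`
generates the calibration regime directly on a SUVA-vs-ARIX line (default
slope 6.07, intercept −0.67, SUVA scatter 0.3 m² g⁻¹ — the magnitude
reported across DOC analysers).

All generators are deterministic under a fixed seed via R's default
Mersenne-Twister stream; seeded runs reproduce byte-identically.

## Problem sizes and tolerances in the test suite

Exact claims (parsing round trips, closed-form index values, noiseless
coefficient recovery, algebraic inversions) are tested at 1e-6 to 1e-12.
Stochastic claims use fixed seeds and pre-stated sizes chosen to make the
checks sharp but quick: slope unbiasedness at 50 replicates; coefficient
coverage at n = 200 with 100 seeds (3-SE intervals must cover the truth in
at least 95 runs); the delta-method check of the error simulation at
n = 200 and 100 runs within 15%; monotonicity of simulated scatter over
5–10 seed replicates. The acceptance script refits the global calibration
at n = 876 and the extract calibration at n = 34, the scales of the
pooled data sets those calibrations describe.

## Known limitations

* No inner-filter or Raman-normalization corrections: inputs must be fully
  corrected EEMs.
* The geometric model II SE is an approximation; exact reproduction of
  published ± values is best-effort.
* pH and iron interference with absorbance-based proxies is real but has
  no algorithmic correction here.
* PARAFAC decomposition is out of scope: PARIX consumes user-supplied
  component scores (ARIX exists precisely to avoid requiring PARAFAC).
* The registry's extract-based relations assume extract fluorescence
  behaves like bulk DOM; the caveat travels with the registry entries.
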