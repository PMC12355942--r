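# domoptics

Optical proxies of dissolved organic matter (DOM) aromaticity and dissolved
organic carbon (DOC), for aquatic biogeochemists and water-treatment
chemists who characterize DOM from UV–visible absorbance and fluorescence
rather than from slower, costlier reference methods (FT-ICR-MS, LC-OCD,
¹³C-NMR, TOC analysis).

## What it computes

**Fluorescence indices from excitation–emission matrices (EEMs).** The
central quantity is the aromaticity index

```
ARIX = F(ex 320, em 520) / F(ex 320, em 390)
```

the ratio of emission intensities on the shoulders of the long-emission
(humic-like, peak > 500 nm) and short-emission (peak ≈ 400 nm) fluorophore
groups whose balance tracks DOM aromaticity. Alongside it: FI, HIX (and its
1999 predecessor), BIX, the freshness ratio β/α, and PARIX (the analogous
ratio of two PARAFAC component Fmax scores, long/short).

**CDOM absorbance quantities.** A254 (decadic, m⁻¹), Napierian absorption
coefficients a275/a350, spectral slopes S275–295 and S380–443 by log-linear
and nonlinear exponential fits of `a(λ) = a(λ_ref)·exp(S(λ_ref − λ))`, and
SUVA254 = A254/DOC (m² g_C⁻¹).

**Published proxy calibrations** (a fixed registry): percent polycyclic
aromatic + polyphenolic formulas `= 30.28·PARIX`; LC-OCD HS/BB
`= 6.1·ARIX`; `SUVA = 6.1·ARIX − 0.7` (global whole-water) and
`SUVA = 4.5·ARIX` (DOM extracts); percent aromaticity
`= 6.52·SUVA + 3.63 = 29.3·ARIX + 3.63`.

**DOC prediction models.** The aromaticity-interaction (ARINT) model

```
DOC = b0 + b1·A254 + b2·A254·P      (P = ARIX, 1/S275–295, or SUVA)
```

where the proxy enters only through the interaction, `b0` is uncolored DOC
and the model inverts to `A254 = (DOC − b0)/(b1 + b2·P)` — a Beer–Lambert
form in which chromophoric DOC absorbs with apparent absorptivity
`∝ 1/(b1 + b2·P)`. Competitors: the base model `DOC = b0 + b1·A254`, the
Pan-Arctic model `log10(DOC/a350) = C + M·S275–295`, and the UV-slope
models `DOC_µM = Φ·a275·(S275–295 + 0.078·S380–443 − 0.0084) + DOC_cor`
(global constants Φ = 1507, DOC_cor = 32.2, or locally fitted). Models are
compared on identical samples by AIC/AICc/BIC/CAIC from the Gaussian log
likelihood.

**Measurement-error sensitivity.** A Monte Carlo simulation builds an
error-free table lying exactly on a SUVA-vs-ARIX reference line, perturbs
DOC, ARIX and A254 with Gaussian errors, refits, and reports the median
RMSE across runs as a share of the observed RMSE.

**Model I / model II regression.** Ordinary, robust (bisquare IRLS) and
geometric-mean (reduced major axis) fits back all calibrations.

**Synthetic data with closed-form truth.** Separable Gaussian fluorophores,
exponential CDOM spectra, and interaction-model sample tables make every
estimator testable without any data download.

## Worked example

```r
library(domoptics)

# indices from a synthetic EEM with a known component mixture
se <- synth_eem(default_components(long_amplitude = 0.9), seed = 1)
fluor_indices(se$eem)
#> # A tibble: 1 × 7
#>   sample_id  arix    fi   hix hix1999   bix freshness
#>   <chr>     <dbl> <dbl> <dbl>   <dbl> <dbl>     <dbl>
#> 1 synthetic 0.838 0.971 0.844    5.43  1.16     0.826

# DOC from absorbance x aromaticity on a generated data set
ds  <- synth_dataset(150, noise = noise_model(
         doc = list(mode = "relative", sd = 0.03),
         arix = list(mode = "absolute", sd = 0),
         a254 = list(mode = "relative", sd = 0)), seed = 2)
fit <- fit_doc_model(ds$table, "arint", proxy = "arix")
tidy(fit)
#> # A tibble: 3 × 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 b0       0.778   0.0434
#> 2 b1       0.803   0.00809
#> 3 b2      -0.495   0.00956

compare_doc_models(ds$table, proxies = "arix")
#> <doc_model_comparison> n = 150
#>       model k r_squared   rmse pct_rmse_change   aic   aicc    bic    caic
#>        base 2    0.7901 1.5042            0.00 550.2 550.23 556.17 558.172
#>  arint_arix 3    0.9954 0.2235          -85.14 -20.9 -20.74 -11.87  -8.868
#> preferred: arint_arix (lowest on 4 of 4 criteria)
```

ARIX 0.838 sits in the upper half of the natural whole-water range
(0.15–1.1): the long-emission humic fraction dominates. The interaction fit
recovers the generator's coefficients (b0 = 0.8 mg/L uncolored DOC,
b1 = 0.8 g m⁻², b2 = −0.5) within one standard error, with a positive
absorbance slope and a negative interaction — more aromatic DOM yields less
DOC per unit absorbance — and cuts the base model's prediction error by
85%, so all four information criteria select it despite its extra
parameter.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "domoptics", package = "domoptics")`, with subcommands
`indices`, `slopes`, `predict-suva`, `fit-doc`, `compare-models`,
`simulate-noise` and `synth`.

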