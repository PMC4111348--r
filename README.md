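# ramanbone

Non-destructive prescreening of archaeological bone for collagen survival
from FT-Raman spectra.

Stable-isotope paleodiet analysis (δ¹³C, δ¹⁵N) is only reliable when enough
bone protein — collagen — has survived burial. The conventional indicators
(% collagen yield, weight %C and %N, atomic C:N) all require the bone to be
demineralised and destroyed first. FT-Raman spectroscopy offers a way to
rank bones *before* destructive chemistry: the ratio of the C-H stretch band
area (3060–2800 cm⁻¹, organic content) to the phosphate ν₁ band area
(983–930 cm⁻¹, the mineral internal standard),

```
R = ∫ I_corr dν̃ (2800–3060) / ∫ I_corr dν̃ (930–983)
```

tracks the remaining organic fraction and is invariant to laser power and
focus. This package is for bioarchaeologists and archaeological chemists
who want that prescreen as a tested, reproducible pipeline rather than an
ad-hoc spreadsheet.

## What it does

* **Spectrum I/O** — two-column text and JCAMP-DX (AFFN) readers/writers,
  validation, resampling (`read_spectrum()`, `resample_spectrum()`).
* **Band analysis** — trapezoidal band areas over the fixed windows with
  exact affine-invariant chord baseline correction, the organic-phosphate
  ratio, triplicate aggregation with a surface-heterogeneity flag,
  fluorescence rejection, and a qualitative prominent/weak/absent C-H score
  (`band_areas()`, `organic_phosphate_ratio()`, `analyze_sample()`).
* **Wet-chemistry QC** — atomic C:N = (%C/%N) × 1.1666 with the 2.9–3.6
  protein range, δ-notation, collagen-yield and nitrogen-mass flags
  (`atomic_cn()`, `delta_ratio()`, `qc_flags()`).
* **Comparison statistics** — Pearson correlation with Fisher-z CI,
  leverage/studentized-residual influence diagnostics, composable
  sensitivity re-analysis after point removal, and Steiger's z (or
  Williams' t) for dependent overlapping correlations
  (`pearson_cor()`, `sensitivity_reanalysis()`,
  `compare_dependent_correlations()`).
* **Screening** — viable/suspect/unusable decisions and Youden-J threshold
  selection against wet-chemistry truth (`classify_sample()`,
  `choose_threshold()`).
* **Reference data** — the published paired Raman/chemistry tables for a
  41-burial cohort from a tropical site ship as fixtures
  (`bnw_dataset()`).
* **Synthetic cohorts** — a spectrum/cohort generator with known ground
  truth (band inventory at 960, 431, 1071, 1425, 1667, 2880, 2935,
  3010 cm⁻¹, fluorescence baseline, noise, co-simulated %C/%N/% collagen
  with a controllable ratio–collagen correlation) so every stage is
  testable without excavated material (`simulate_cohort()`).

## Worked example

```r
library(ramanbone)

bnw <- bnw_dataset()            # 41 samples, both reference tables
ref <- complete_cases(bnw)      # the 31 with ratio, %N, %C and yield

pearson_cor(ref$raman_ratio, ref$pct_collagen)
#> r = 0.715 (R2 = 51.2%), n = 31, p = 6.07e-06, 95% CI [0.484, 0.853]
```

Half the variance in collagen yield is explained by the ratio. How fragile
is that? Remove the two highest-leverage points (the two largest ratios)
and then the largest studentized residual among the rest:

```r
sens <- sensitivity_reanalysis(ref$raman_ratio, ref$pct_collagen,
                               ids = ref$sample_id,
                               leverage_k = 2, residual_m = 1)
sens$removed_ids
#> [1] "33" "24" "41"
sens$result_after
#> r = 0.422 (R2 = 17.8%), n = 28, p = 0.0252, 95% CI [0.058, 0.687]
```

The association survives (p ≈ 0.025) but most of the R² was carried by the
three best-preserved bones — exactly the caveat a prescreening user needs.
Is the ratio a better predictor of %C than of yield? The two correlations
share the ratio, so an ordinary comparison is invalid:

```r
compare_dependent_correlations(
  pearson_cor(ref$raman_ratio, ref$pct_collagen)$r,
  pearson_cor(ref$raman_ratio, ref$pct_c)$r,
  pearson_cor(ref$pct_collagen, ref$pct_c)$r, n = 31)
#> H0: rho_jk = rho_jh (steiger): r_jk = 0.715 vs r_jh = 0.649 (r_kh = 0.515, n = 31)
#>   statistic = 0.555, two-sided p = 0.579
```

No evidence either chemistry measure is the stronger correlate. Finally, a
screening threshold against the 1% collagen-yield floor:

```r
thr <- choose_threshold(ref, collagen_threshold = 1)
#> threshold 0.2085, Youden J = 0.652
thr$evaluation$confusion
#> tp fp tn fn
#>  8  8 15  0
```

At a ratio cut of ≈ 0.21 no viable bone is discarded (fn = 0); the 8 false
positives are what the subsequent chemistry would still weed out — the
right asymmetry for a prescreen. Synthetic cohorts with known truth work
the same way:

```r
sim <- simulate_cohort(cohort_config(n = 4, seed = 1, n_fluor_fail = 1))
sim$dataset
#>   sample_id burial_no  phase pct_n pct_c cn_atomic pct_collagen raman_ratio
#> 1    syn001         1 Bronze  1.47  7.50       6.0       0.3400 0.026673928
#> 2    syn002         2 Bronze  1.12  8.79       9.2       0.7281 0.008994813
#> 3    syn003         3   Iron  3.02  9.29       3.6       0.2793 0.042202363
#> 4    syn004         4   Iron  9.74 28.67       3.4       2.7444          NA
```

(the `NA` is the fluorescence-failed sample; its spectra saturated the
simulated detector and were rejected, as happens with real burials).

See `vignette("raman-collagen-screening")` for the model, parameter
defaults, and the design decisions behind the baseline, aggregation and
threshold rules.

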