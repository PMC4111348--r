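---
title: "Prescreening archaeological bone for collagen survival with FT-Raman spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prescreening archaeological bone for collagen survival with FT-Raman spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanbone)
```

## The problem

Paleodiet inference from stable isotopes (δ¹³C, δ¹⁵N) needs surviving bone
protein. In hot, seasonally wet burial environments collagen leaches out of
bone, and the conventional indicators of protein survival — % collagen yield
(gelatin mass relative to undemineralised bone weight), weight %C and %N, and
the atomic C:N ratio — are only available *after* the bone has been
demineralised and destroyed. FT-Raman spectroscopy (1064 nm excitation, which
suppresses fluorescence) is non-destructive, and its spectrum of bone carries
both a mineral signature (the phosphate ν₁ symmetric stretch at ~960 cm⁻¹,
the most intense band, and the ν₂ O-P-O bend at ~431 cm⁻¹) and an organic one
(three C-H stretches in 3060–2800 cm⁻¹, the δC-H bend at ~1425 cm⁻¹, amide I
at ~1667 cm⁻¹).

The quantity at the centre of this package is the **organic-phosphate
ratio**:

$$
R \;=\; \frac{\int_{2800}^{3060} I_{\mathrm{corr}}(\tilde\nu)\, d\tilde\nu}
             {\int_{930}^{983} I_{\mathrm{corr}}(\tilde\nu)\, d\tilde\nu},
$$

the baseline-corrected C-H stretch band area over the phosphate ν₁ band area.
Because the mineral matrix is always present, the denominator acts as an
internal standard, making $R$ invariant to overall intensity scaling (laser
power, focus, integration time). The package's pipeline computes $R$ per
replicate spectrum, aggregates triplicates, rejects fluorescence-swamped
spectra, correlates $R$ with the wet-chemistry yields, and turns $R$ into a
screening decision.

## Band integration and baseline handling

Integration is trapezoidal on the spectrum's native grid over three fixed
windows (`band_windows()`): C-H 3060–2800, phosphate ν₁ 983–930 and ν₂
566–300 cm⁻¹. The default baseline correction (`local_linear`) subtracts the
chord through the window's endpoint intensities, each endpoint estimated as
the median of the 5 nearest grid points. This is the minimal correction that:

* leaves every corrected band area **exactly** unchanged under addition of
  any affine background $a + b\tilde\nu$ (verified to 1e-8 in the tests), and
* tames the smooth, slowly varying fluorescence backgrounds that dominate
  poorly preserved bone.

`baseline_mode = "none"` reproduces raw integrals. Negative corrected areas
arise legitimately in degraded bone (pure noise in the C-H window); they are
clipped to zero and flagged rather than raised as errors. The ratio errors
only when the *phosphate* area is zero or near-zero — a bone spectrum without
its mineral band is not a bone spectrum.

The ν₁-only denominator is the default because that is the conventional form
of the published ratio; a ν₁+ν₂ variant is exposed
(`organic_phosphate_ratio(..., denominator = "v1_plus_v2")`) since both
mineral bands carry apatite signal. The published per-sample ratio values in
the packaged tables are treated as given data, not as recomputable outputs —
the original integration and baseline settings behind them are not on record.

## Replicates, fluorescence, and qualitative scoring

Triplicate spectra are taken on different spots of compact bone, so the
per-replicate ratios are combined by the **mean of ratios** (not the ratio of
mean areas): the spots are independent observations of a heterogeneous
surface. A coefficient of variation above 0.25 (configurable) sets a
heterogeneity flag, mirroring the handful of bones in the reference cohort
whose spots disagreed.

`detect_fluorescence()` flags a spectrum as unusable when the chord-corrected
ν₁ area falls below 5% of the raw intensity integral over the same window
(i.e. the band has drowned in background), when the detector saturates, or
when there is no signal at all.

`ch_presence()` reproduces the qualitative call an analyst makes by eye —
`prominent` / `weak` / `absent` organic bands — as a signal-to-noise ratio:
the peak of the chord-corrected C-H region over a robust noise sd (MAD of the
detrended 1900–2200 cm⁻¹ region, which carries no bone bands). One numerical
subtlety: the maximum of ~260 points of pure noise is itself about 2.7 noise
sd, so a naive peak/noise score can never fall much below 3 and would rate
empty spectra "weak". The corrected region is therefore smoothed with a
15-point moving average before the peak is taken — the C-H bands are broad
(σ ≈ 20 cm⁻¹) and pass through essentially unchanged while the noise maximum
drops by √15 — after which the default thresholds (prominent ≥ 10, weak ≥ 3)
behave as intended. The score is scale-invariant and monotone in the true
organic amplitude (both property-tested).

## Wet-chemistry QC

The chemistry side carries three conventional screens, implemented exactly:

* atomic C:N $= (\%C/\%N) \times 1.1666$, acceptable in the inclusive range
  2.9–3.6 (bone protein); endpoints configurable;
* % collagen yield below 1% w/w is suspect. The literature convention is
  "1–2%"; the default floor is 1% because that is the operative cut in the
  reference study's own screening narrative, and the floor is a parameter;
* analytical nitrogen mass of 7 µg or less is insufficient for a reliable
  δ¹⁵N (flag is `NA` when the mass is unrecorded).

δ-notation is provided as
$\delta = (R_{\mathrm{sample}}/R_{\mathrm{standard}} - 1) \times 1000$ ‰.

## The comparison stage

`pearson_cor()` reports $r$, $R^2$, the two-sided p from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df, and a Fisher-z 95% CI.
`influence_diagnostics()` gives simple-regression leverages
$h_i = 1/n + (x_i-\bar x)^2/\sum(x-\bar x)^2$ (they always sum to 2) and
externally studentized residuals. `sensitivity_reanalysis()` composes
removal rules — top-k leverage first, then top-m |studentized residual|
refitted on what remains, or an explicit id list — and recomputes the
correlation.

The reference analysis removes "one clear outlier and two leverage points to
the right" of the collagen scatter. The identities were never printed; the
reconstruction `leverage_k = 2, residual_m = 1` lands on the two
highest-ratio samples plus the high-collagen outlier and reproduces the
published post-removal $R^2$ of 17.8% exactly — and an exhaustive search over
all $\binom{31}{3}$ removals shows this is the *only* 3-point removal that
does, which is as close to identification as the printed record permits.

For "is the ratio more strongly correlated with %C than with % collagen?"
the correlations share a variable and are measured on the same samples, so
an ordinary two-sample z is invalid. `compare_dependent_correlations()`
implements Steiger's (1980) z for overlapping dependent correlations using
the back-transformed average correlation (default), with Williams' t as an
alternative; the method used is recorded in the result. The test behind the
published comparison p-values was never named: the default Steiger method
gives p = 0.579 for the collagen-vs-carbon comparison against a printed
0.555, agreement at the level such method ambiguity allows (both tests agree
there is no evidence either yield correlates more strongly). These p-values
are treated as consistency references, not as recomputable outputs.

## Screening decisions

`classify_sample()` formalises the prescreening call: `unusable` when
fluorescence defeated the measurement, `viable` when the mean ratio clears a
threshold **or** the C-H bands are prominent, `suspect` otherwise.
`evaluate_screen()` scores a ratio threshold against wet-chemistry truth
(positive = collagen yield strictly greater than the floor; predicted
positive = ratio ≥ threshold — the strict/non-strict split matches the
"greater than 1% yield" phrasing and makes the confusion counts
reproducible), and `choose_threshold()` sweeps every observed ratio,
maximises Youden's J (ties toward sensitivity), and returns the midpoint of
the bracketing gap. On the packaged cohort at a 1% collagen floor the sweep
selects a threshold near 0.21 with J ≈ 0.65.

## The synthetic cohort generator

Real excavated bone cannot ship with a package, so every stage is testable
against `simulate_cohort()`, whose ground truth is known by construction.
The model, with defaults chosen once to emulate the reference cohort:

* **% collagen**: lognormal, meanlog −0.49, sdlog 0.94 (fit to the 41
  published yields: median ≈ 0.6%, range ≈ 0.1–6%).
* **Spectrum**: Gaussian bands at 960/8, 431/12, 1071/8, 1425/20, 1667/25,
  2880/20, 2935/20, 3010/20 (centre/σ, cm⁻¹) with fixed relative
  amplitudes; mineral amplitudes are collagen-independent
  (`mineral_amp = 100`), organic amplitudes are
  `organic_gain × collagen × (1 + replicate jitter)` with
  `organic_gain = 1.7`, giving a noise-free ratio slope of ≈ 0.098 per
  % collagen — the regression slope of the reference table. Polynomial
  baseline (in wavenumber/1000), optional exponentially decaying
  fluorescence hump, i.i.d. Gaussian noise (sd 0.5 counts), optional
  detector saturation. Grid 0–3200 cm⁻¹ at 1 cm⁻¹.
* **Surface heterogeneity**: Raman probes a few hundred µm of surface while
  the chemistry digests whole bone, so the organic amplitude is driven by
  `collagen × M` with `M` lognormal, mean 1. The default sdlog 0.67 makes
  the true ratio–collagen correlation ≈ 0.72, the level observed in the
  reference cohort; `hetero_sd_for_rho()` solves the lognormal moment
  equation for any target ρ.
* **%C, %N**: linear in collagen (3.0 + 9.0·coll ± 2.5; 1.0 + 3.2·coll ±
  1.0, truncated at 0) — a crude fit to the spread of the reference table,
  configurable, and not a claim about the real samples.
* **Fluorescence failures**: `n_fluor_fail` samples get a baseline far above
  the bands and a saturating detector, reproducing the two reference samples
  whose ratio could not be measured.

`closed_form_areas()` / `closed_form_ratio()` give the exact erf-based
integrals of the band model over the three windows; on noiseless spectra the
numerically measured ratio agrees with the closed form to better than 1e-3
relative at the 1 cm⁻¹ grid.

`simulate_cohort()` has two modes. The spectral mode generates three
replicate spectra per sample and *measures* the ratio through the band
analysis pipeline — this is the mode that validates the pipeline itself. The
summary mode (`spectra = FALSE`) draws the aggregated ratio directly from the
statistical reduction of the same model
(`mean over 3 replicates of slope × collagen × M × (1 + jitter) + ε`,
ε ~ N(0, `ratio_noise_sd`)); it exists because simulation studies (2000 null
cohorts for the type-I-error check, 200 cohorts for parameter recovery) would
be needlessly slow through full spectra. Null cohorts for the calibration
check use `organic_gain = 0` with additive ratio noise, under which the
correlation p-value is exactly uniform (Gaussian noise independent of
collagen), and the observed rejection rate at α = 0.05 over 2000 cohorts
falls inside the binomial 95% band.

What the generator does **not** emulate: photon/shot noise statistics,
instrument response, collagen-fibril orientation effects (mitigated in
practice by a 1 mm spot), secondary mineralisation bands (calcite, barite),
and any nonzero intercept in the ratio–collagen relation (the reference
cohort shows one, ≈ 0.13; the generator's ratio is proportional to surface
collagen). Passing tests on synthetic cohorts therefore demonstrate the
pipeline's internal correctness and statistical calibration, not that real
diagenetic bone behaves this simply.

## Problem sizes and numerical choices

The test-suite simulation studies use 2000 summary-mode cohorts of n = 20
for the type-I check, 200 cohorts of n = 31 (the reference-study size)
against a 2000-replicate independently coded oracle for parameter recovery,
one n = 1000 cohort for the ρ = 0.7 recovery band, and a 10,000-replicate
bootstrap at n = 80 as the oracle for the dependent-correlation test —
chosen at n = 80 because the asymptotic z and the bootstrap only converge
once n is comfortably past the small-sample regime; at n = 20 the bootstrap
SE of a correlation difference is unstable and neither method can arbitrate
the other. All stochastic tests run under fixed seeds.

Other numerical choices: duplicate wavenumbers within 1e-9 cm⁻¹ merge by
mean; chord endpoints use the median of 5 grid points; ratios with a
phosphate area ≤ 1e-8 raise an undefined-ratio error; `choose_threshold()`
breaks Youden ties toward the lower cut (higher sensitivity — the
prescreening context prefers false positives, which the chemistry will
catch, over discarding viable bone).

## Known limitations

* The screening threshold learned from one site's taphonomy does not
  transfer: burial chemistry, consolidants and soil organics shift both the
  ratio scale and the fluorescence regime.
* The ratio cannot *quantify* collagen yield; roughly half the variance in
  yield is explained by the ratio in the reference cohort, and the method is
  a prescreen, not a substitute for C:N and yield QC.
* JCAMP-DX support covers uncompressed AFFN XYDATA/XYPOINTS only; vendor
  binary formats (SPC, OPUS) and compressed JCAMP encodings are out of
  scope.
* Peak fitting/deconvolution of overlapping bands, and diagenesis metrics
  based on phosphate band position/width (apatite recrystallisation), are
  deliberately not implemented.
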