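#' Default band inventory for synthetic FT-Raman bone spectra
#'
#' Gaussian band models for the vibrations seen in FT-Raman spectra of bone:
#' the phosphate \eqn{\nu_1} symmetric stretch at 960 cm\eqn{^{-1}} (the most
#' intense band), the \eqn{\nu_2} O-P-O bend at 431, the carbonate symmetric
#' stretch at 1071, the broad C-H bend at 1425, amide I at 1667, and three C-H
#' stretches at 2880/2935/3010. Widths (Gaussian sigma) and relative
#' amplitudes are chosen to resemble FT-Raman bone and are configurable;
#' `organic` marks bands whose amplitude scales with collagen content.
#'
#' @return A `data.frame` with columns `center`, `sigma` (both cm^-1),
#'   `rel_amp` (relative amplitude, unitless) and `organic` (logical).
#' @export
default_bands <- function() {
  data.frame(
    center  = c(960, 431, 1071, 1425, 1667, 2880, 2935, 3010),
    sigma   = c(8, 12, 8, 20, 25, 20, 20, 20),
    rel_amp = c(1.00, 0.35, 0.12, 0.25, 0.30, 0.85, 1.00, 0.45),
    organic = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
}

#' Configuration for a synthetic bone cohort
#'
#' Defines the joint model for % collagen yield, %C, %N and the Raman
#' spectrum of each simulated sample. Collagen yields are lognormal
#' (defaults fit the spread of the packaged reference cohort: median about
#' 0.6% w/w, range roughly 0.1-6%). Organic band amplitudes are
#' `organic_gain * collagen * M`, where `M` is a per-sample lognormal
#' surface-heterogeneity multiplier (mean 1) capturing the fact that Raman
#' probes only a few hundred micrometres of surface while the chemistry
#' digests the whole bone; mineral band amplitudes are independent of
#' collagen. %C and %N follow linear models in collagen, truncated at zero.
#'
#' @param n cohort size (>= 1).
#' @param seed integer RNG seed for reproducibility.
#' @param collagen_meanlog,collagen_sdlog lognormal parameters for % collagen.
#' @param organic_gain counts of organic band amplitude per % collagen
#'   (default 1.7 gives a noise-free ratio slope of about 0.098 per
#'   % collagen, matching the reference cohort's regression slope).
#' @param mineral_amp phosphate nu1 amplitude, counts (collagen-independent).
#' @param sample_hetero_sd sdlog of the surface-heterogeneity multiplier `M`
#'   (default 0.67 yields a ratio/collagen correlation near 0.72 at the
#'   default collagen distribution, the level seen in the reference cohort).
#' @param baseline polynomial baseline coefficients (ascending powers),
#'   evaluated in `wavenumber / 1000`, counts.
#' @param fluor_amp amplitude of an exponentially decaying fluorescence hump
#'   `fluor_amp * exp(-wavenumber / 1500)`, counts.
#' @param noise_sd i.i.d. Gaussian detector noise sd per point, counts.
#' @param pct_c_intercept,pct_c_slope,pct_c_sd %C = intercept + slope *
#'   collagen + N(0, sd), truncated at 0.
#' @param pct_n_intercept,pct_n_slope,pct_n_sd same for %N.
#' @param replicate_jitter_sd relative sd of organic amplitude across the
#'   three replicate scan spots.
#' @param ratio_noise_sd additive per-replicate measurement noise on the
#'   ratio, used only by the summary (spectra-free) mode of
#'   [simulate_cohort()].
#' @param n_fluor_fail number of samples rendered unusable by overwhelming
#'   fluorescence (their spectra get a baseline far above the bands and the
#'   detector saturates; their ratio is missing, as for the two fluorescent
#'   samples of the reference cohort).
#' @param detector_max saturation ceiling, counts (`Inf` = none). Set finite
#'   automatically for fluorescence-failed samples.
#' @param bands band inventory as from [default_bands()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 31, seed = 1L,
                          collagen_meanlog = -0.49, collagen_sdlog = 0.94,
                          organic_gain = 1.7, mineral_amp = 100,
                          sample_hetero_sd = 0.67,
                          baseline = 0, fluor_amp = 0, noise_sd = 0.5,
                          pct_c_intercept = 3.0, pct_c_slope = 9.0, pct_c_sd = 2.5,
                          pct_n_intercept = 1.0, pct_n_slope = 3.2, pct_n_sd = 1.0,
                          replicate_jitter_sd = 0.05, ratio_noise_sd = 0.01,
                          n_fluor_fail = 0, detector_max = Inf,
                          bands = default_bands()) {
  cfg <- list(n = as.integer(n), seed = as.integer(seed),
              collagen_meanlog = collagen_meanlog, collagen_sdlog = collagen_sdlog,
              organic_gain = organic_gain, mineral_amp = mineral_amp,
              sample_hetero_sd = sample_hetero_sd,
              baseline = baseline, fluor_amp = fluor_amp, noise_sd = noise_sd,
              pct_c_intercept = pct_c_intercept, pct_c_slope = pct_c_slope,
              pct_c_sd = pct_c_sd,
              pct_n_intercept = pct_n_intercept, pct_n_slope = pct_n_slope,
              pct_n_sd = pct_n_sd,
              replicate_jitter_sd = replicate_jitter_sd,
              ratio_noise_sd = ratio_noise_sd,
              n_fluor_fail = as.integer(n_fluor_fail),
              detector_max = detector_max, bands = bands)
  if (cfg$n < 1L) stop("n must be >= 1")
  if (cfg$organic_gain < 0) stop("organic_gain must be >= 0")
  sds <- c(cfg$collagen_sdlog, cfg$sample_hetero_sd, cfg$noise_sd, cfg$pct_c_sd,
           cfg$pct_n_sd, cfg$replicate_jitter_sd, cfg$ratio_noise_sd)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  if (any(cfg$bands$sigma <= 0) || any(cfg$bands$rel_amp < 0))
    stop("band widths must be > 0 and amplitudes >= 0")
  if (cfg$n_fluor_fail < 0 || cfg$n_fluor_fail > cfg$n)
    stop("n_fluor_fail must be in [0, n]")
  class(cfg) <- "cohort_config"
  cfg
}

# Exact band-model integrals over [lo, hi] for given organic amplitude scale
.gauss_window_area <- function(amp, center, sigma, lo, hi) {
  amp * sigma * sqrt(2 * pi) *
    (pnorm((hi - center) / sigma) - pnorm((lo - center) / sigma))
}

#' Closed-form noise-free band areas of the synthetic model
#'
#' Exact Gaussian-integral areas of the band model over the three analysis
#' windows (C-H 3060-2800, phosphate nu1 983-930, nu2 566-300 cm^-1), with no
#' baseline and no noise. Used as the analytic oracle for the numerical
#' integration pipeline and to express the generator's ground-truth ratio.
#'
#' @param config a [cohort_config()].
#' @param collagen_pct % collagen driving the organic bands.
#' @return Named list `ch_area`, `po4_v1_area`, `po4_v2_area`.
#' @export
closed_form_areas <- function(config, collagen_pct) {
  b <- config$bands
  amps <- ifelse(b$organic, config$organic_gain * collagen_pct,
                 config$mineral_amp) * b$rel_amp
  area_in <- function(win) sum(.gauss_window_area(amps, b$center, b$sigma,
                                                  win[1], win[2]))
  list(ch_area = area_in(.WINDOW_CH),
       po4_v1_area = area_in(.WINDOW_PO4_V1),
       po4_v2_area = area_in(.WINDOW_PO4_V2))
}

#' Ground-truth organic-phosphate ratio of the synthetic model
#'
#' `closed_form_ratio(config, collagen)` is linear in collagen; the slope
#' (ratio units per % collagen) is returned by `closed_form_slope(config)`.
#'
#' @inheritParams closed_form_areas
#' @param denominator `"v1"` (default) or `"v1_plus_v2"`.
#' @return Unitless ratio (or slope).
#' @export
closed_form_ratio <- function(config, collagen_pct, denominator = c("v1", "v1_plus_v2")) {
  denominator <- match.arg(denominator)
  a <- closed_form_areas(config, collagen_pct)
  den <- if (denominator == "v1") a$po4_v1_area else a$po4_v1_area + a$po4_v2_area
  a$ch_area / den
}

#' @rdname closed_form_ratio
#' @export
closed_form_slope <- function(config, denominator = c("v1", "v1_plus_v2")) {
  closed_form_ratio(config, 1, denominator)
}

#' Heterogeneity sdlog giving a target ratio-collagen correlation
#'
#' Solves, from lognormal moments, for the `sample_hetero_sd` under which the
#' noise-free per-sample ratio `slope * collagen * M` has Pearson correlation
#' `rho` with collagen (replicate jitter and measurement noise assumed
#' negligible). Useful for constructing cohorts with known true correlation.
#'
#' @param config a [cohort_config()] supplying the collagen distribution.
#' @param rho target Pearson correlation, 0 < rho <= 1.
#' @return sdlog of the heterogeneity multiplier.
#' @export
hetero_sd_for_rho <- function(config, rho) {
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  m <- config$collagen_meanlog; s <- config$collagen_sdlog
  e1 <- exp(m + s^2 / 2); e2 <- exp(2 * m + 2 * s^2)
  v <- e2 - e1^2
  arg <- (v / rho^2 + e1^2) / e2
  if (arg < 1) stop("target rho not attainable for this collagen distribution")
  sqrt(log(arg))
}

#' Simulate one replicate FT-Raman bone spectrum
#'
#' Generates a spectrum on 0-3200 cm\eqn{^{-1}} at 1 cm\eqn{^{-1}}: Gaussian
#' bands from the config's inventory (organic amplitudes
#' `organic_gain * collagen_pct * (1 + jitter)`, mineral amplitudes fixed),
#' plus polynomial baseline, optional fluorescence hump, i.i.d. Gaussian
#' noise, and saturation clipping at `detector_max`.
#'
#' @param config a [cohort_config()].
#' @param collagen_pct % collagen (>= 0) driving the organic bands.
#' @param replicate_index replicate number (>= 1).
#' @param seed optional integer; when given the draw is reproducible and the
#'   global RNG state is untouched. `NULL` uses (and advances) the current
#'   RNG stream.
#' @param sample_id id stored in the spectrum.
#' @return A [raman_spectrum()].
#' @export
simulate_spectrum <- function(config, collagen_pct, replicate_index = 1L,
                              seed = NULL, sample_id = "synthetic") {
  if (collagen_pct < 0) stop("collagen_pct must be >= 0")
  draw <- function() {
    jitter <- if (config$replicate_jitter_sd > 0)
      rnorm(1, 0, config$replicate_jitter_sd) else 0
    w <- seq(0, 3200, by = 1)
    b <- config$bands
    amps <- ifelse(b$organic,
                   config$organic_gain * collagen_pct * (1 + jitter),
                   config$mineral_amp) * b$rel_amp
    y <- numeric(length(w))
    for (i in seq_len(nrow(b)))
      y <- y + amps[i] * exp(-(w - b$center[i])^2 / (2 * b$sigma[i]^2))
    # baseline: polynomial in w/1000 plus optional fluorescence hump
    y <- y + .polyval_asc(config$baseline, w / 1000)
    if (config$fluor_amp != 0) y <- y + config$fluor_amp * exp(-w / 1500)
    if (config$noise_sd > 0) y <- y + rnorm(length(w), 0, config$noise_sd)
    if (is.finite(config$detector_max)) y <- pmin(y, config$detector_max)
    raman_spectrum(w, y, sample_id = sample_id, replicate = replicate_index)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# evaluate polynomial with ascending coefficients
.polyval_asc <- function(coefs, x) {
  out <- 0
  for (k in seq_along(coefs)) out <- out + coefs[k] * x^(k - 1)
  out
}

#' Simulate a bone cohort with known ground truth
#'
#' Draws % collagen, surface-heterogeneity multipliers, %C and %N for `n`
#' samples and produces the paired Raman/chemistry table that the downstream
#' correlation and screening stages consume, together with the ground truth.
#'
#' Two modes:
#' \describe{
#'   \item{`spectra = TRUE`}{Each sample gets three replicate spectra from
#'     [simulate_spectrum()]; its ratio is then *measured* by the band
#'     analysis pipeline (chord baseline, nu1 denominator, mean over usable
#'     replicates). Fluorescence-failed samples get a missing ratio.}
#'   \item{`spectra = FALSE`}{The aggregated ratio is drawn directly from the
#'     statistical reduction of the same model
#'     (`mean_j[slope * collagen * M * (1 + jitter_j) + noise_j]` over 3
#'     replicates, noise sd `ratio_noise_sd`), which is orders of magnitude
#'     faster for simulation studies with many cohorts.}
#' }
#'
#' @param config a [cohort_config()]; `config$seed` makes the cohort
#'   bit-reproducible.
#' @param spectra logical; generate and analyse full spectra (default) or use
#'   the summary model.
#' @param keep_spectra logical; also return the list of spectra (spectral
#'   mode only).
#' @return A list with elements `dataset` (a `paired_dataset` data frame),
#'   `truth` (per-sample drawn values and noise-free ratios) and, when
#'   requested, `spectra` (list of lists of [raman_spectrum()]).
#' @export
simulate_cohort <- function(config, spectra = TRUE, keep_spectra = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    n <- config$n
    collagen <- rlnorm(n, config$collagen_meanlog, config$collagen_sdlog)
    m_het <- if (config$sample_hetero_sd > 0)
      rlnorm(n, -config$sample_hetero_sd^2 / 2, config$sample_hetero_sd)
    else rep(1, n)
    surface_collagen <- collagen * m_het
    pct_c <- pmax(0, config$pct_c_intercept + config$pct_c_slope * collagen +
                    rnorm(n, 0, config$pct_c_sd))
    pct_n <- pmax(0, config$pct_n_intercept + config$pct_n_slope * collagen +
                    rnorm(n, 0, config$pct_n_sd))
    phase <- sample(.PHASES, n, replace = TRUE, prob = c(5, 23, 13) / 41)
    fluor_fail <- rep(FALSE, n)
    if (config$n_fluor_fail > 0)
      fluor_fail[sample.int(n, config$n_fluor_fail)] <- TRUE
    slope <- closed_form_slope(config)
    true_ratio <- slope * surface_collagen

    ratio <- rep(NA_real_, n)
    spec_list <- if (keep_spectra) vector("list", n) else NULL
    if (spectra) {
      spec_seeds <- sample.int(.Machine$integer.max - 1L, n * 3L)
      for (i in seq_len(n)) {
        cfg_i <- config
        if (fluor_fail[i]) {
          # fluorescence far above the usable range; detector saturates
          cfg_i$fluor_amp <- config$mineral_amp * 2000
          cfg_i$detector_max <- config$mineral_amp * 500
        }
        reps <- lapply(1:3, function(j)
          simulate_spectrum(cfg_i, surface_collagen[i], replicate_index = j,
                            seed = spec_seeds[(i - 1L) * 3L + j],
                            sample_id = sprintf("syn%03d", i)))
        res <- analyze_sample(reps)
        ratio[i] <- res$ratio_mean
        if (keep_spectra) spec_list[[i]] <- reps
      }
    } else {
      for (i in seq_len(n)) {
        if (fluor_fail[i]) next
        jit <- rnorm(3, 0, config$replicate_jitter_sd)
        eps <- rnorm(3, 0, config$ratio_noise_sd)
        ratio[i] <- mean(true_ratio[i] * (1 + jit) + eps)
      }
    }

    dataset <- data.frame(
      sample_id = sprintf("syn%03d", seq_len(n)),
      burial_no = seq_len(n), phase = phase,
      pct_n = round(pct_n, 2), pct_c = round(pct_c, 2),
      cn_atomic = ifelse(pct_n > 0, round(atomic_cn(pct_c, pmax(pct_n, 1e-12)), 1),
                         NA_real_),
      pct_collagen = round(collagen, 4), raman_ratio = ratio,
      stringsAsFactors = FALSE)
    class(dataset) <- c("paired_dataset", class(dataset))

    truth <- data.frame(
      sample_id = dataset$sample_id, collagen = collagen,
      surface_multiplier = m_het, surface_collagen = surface_collagen,
      true_ratio = true_ratio, pct_c = pct_c, pct_n = pct_n,
      fluorescence_failed = fluor_fail, stringsAsFactors = FALSE)

    out <- list(dataset = dataset, truth = truth)
    if (keep_spectra) out$spectra <- spec_list
    out
  })
}
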