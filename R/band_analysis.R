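#' Integration windows of the bone prescreening analysis
#'
#' The three fixed windows over which band areas are integrated: the C-H
#' symmetric/asymmetric stretch region 3060-2800 cm\eqn{^{-1}} (organic
#' content), the phosphate \eqn{\nu_1} symmetric stretch 983-930
#' cm\eqn{^{-1}} and the \eqn{\nu_2} O-P-O bend 566-300 cm\eqn{^{-1}}
#' (mineral content).
#'
#' @return A `data.frame` with columns `label`, `lo`, `hi` (cm^-1).
#' @export
band_windows <- function() {
  data.frame(label = c("ch", "po4_v1", "po4_v2"),
             lo = c(.WINDOW_CH[1], .WINDOW_PO4_V1[1], .WINDOW_PO4_V2[1]),
             hi = c(.WINDOW_CH[2], .WINDOW_PO4_V1[2], .WINDOW_PO4_V2[2]))
}

# chord endpoint: median intensity of the 5 grid points nearest `at`
.chord_endpoint <- function(spectrum, at) {
  d <- abs(spectrum$wavenumbers - at)
  idx <- order(d)[seq_len(min(5L, length(d)))]
  median(spectrum$intensities[idx])
}

#' Integrate a band area over a window
#'
#' Trapezoidal integration of (intensity - baseline) over `[lo, hi]` on the
#' spectrum's native grid. With `baseline_mode = "local_linear"` the baseline
#' is the chord through the window's endpoint intensities, each endpoint
#' taken as the median of the 5 grid points nearest it; this removes any
#' affine background exactly and makes the area robust to fluorescence
#' slopes. `"none"` integrates the raw signal. The returned value may be
#' negative for noisy near-zero bands; clipping is applied at the
#' [band_areas()] level.
#'
#' @param spectrum a [raman_spectrum()].
#' @param window length-2 numeric `c(lo, hi)` in cm^-1, or a row label from
#'   [band_windows()] (`"ch"`, `"po4_v1"`, `"po4_v2"`).
#' @param baseline_mode `"local_linear"` (default) or `"none"`.
#' @return Band area (counts * cm^-1), possibly negative.
#' @export
integrate_band <- function(spectrum, window,
                           baseline_mode = c("local_linear", "none")) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  baseline_mode <- match.arg(baseline_mode)
  if (is.character(window)) {
    wins <- band_windows()
    row <- wins[wins$label == window, ]
    if (!nrow(row)) stop("unknown window label: ", window)
    window <- c(row$lo, row$hi)
  }
  lo <- window[1]; hi <- window[2]
  if (!(lo < hi)) stop("window must satisfy lo < hi")
  rng <- range(spectrum$wavenumbers)
  if (lo < rng[1] || hi > rng[2])
    stop(sprintf("window [%g, %g] outside spectrum range [%g, %g]",
                 lo, hi, rng[1], rng[2]))
  keep <- spectrum$wavenumbers >= lo & spectrum$wavenumbers <= hi
  if (sum(keep) < 2L) stop("fewer than two grid points inside window")
  w <- spectrum$wavenumbers[keep]
  y <- spectrum$intensities[keep]
  if (baseline_mode == "local_linear") {
    y_lo <- .chord_endpoint(spectrum, lo)
    y_hi <- .chord_endpoint(spectrum, hi)
    y <- y - (y_lo + (y_hi - y_lo) * (w - lo) / (hi - lo))
  }
  pracma::trapz(w, y)
}

#' Band areas over the three analysis windows
#'
#' Applies [integrate_band()] to the C-H, phosphate nu1 and nu2 windows.
#' Negative corrected areas (pure-noise bands in heavily degraded bone) are
#' clipped to 0 and flagged rather than treated as errors.
#'
#' @inheritParams integrate_band
#' @return A list of class `band_areas`: `ch_area`, `po4_v1_area`,
#'   `po4_v2_area`, `baseline_mode`, `clipped` (named logical vector).
#' @export
band_areas <- function(spectrum, baseline_mode = c("local_linear", "none")) {
  baseline_mode <- match.arg(baseline_mode)
  raw <- c(ch = integrate_band(spectrum, "ch", baseline_mode),
           po4_v1 = integrate_band(spectrum, "po4_v1", baseline_mode),
           po4_v2 = integrate_band(spectrum, "po4_v2", baseline_mode))
  clipped <- raw < 0
  vals <- pmax(raw, 0)
  structure(list(ch_area = vals[["ch"]], po4_v1_area = vals[["po4_v1"]],
                 po4_v2_area = vals[["po4_v2"]],
                 baseline_mode = baseline_mode, clipped = clipped),
            class = "band_areas")
}

#' Organic-phosphate ratio
#'
#' The C-H band area divided by the phosphate band area: the spectroscopic
#' proxy for surviving organic (protein) content. The conventional
#' denominator is the \eqn{\nu_1} area alone; a \eqn{\nu_1 + \nu_2} variant
#' is provided since both mineral bands carry apatite signal.
#'
#' @param areas a [band_areas()] result.
#' @param denominator `"v1"` (default) or `"v1_plus_v2"`.
#' @param min_denominator areas at or below this are treated as an absent
#'   mineral band, i.e. an unusable spectrum.
#' @return Unitless ratio >= 0.
#' @export
organic_phosphate_ratio <- function(areas, denominator = c("v1", "v1_plus_v2"),
                                    min_denominator = 1e-8) {
  stopifnot(inherits(areas, "band_areas"))
  denominator <- match.arg(denominator)
  den <- if (denominator == "v1") areas$po4_v1_area
         else areas$po4_v1_area + areas$po4_v2_area
  if (!is.finite(den) || den <= min_denominator)
    stop("phosphate denominator area is zero or near-zero: mineral band absent, spectrum unusable")
  areas$ch_area / den
}

#' Aggregate replicate ratios for one sample
#'
#' Replicate spectra are taken on different spots of the bone surface, so the
#' per-replicate ratios are combined by arithmetic mean (not ratio of mean
#' areas). A large relative spread across spots flags surface heterogeneity.
#'
#' @param ratios numeric vector of per-replicate ratios (NAs dropped).
#' @param heterogeneity_threshold flag when `sd/mean` exceeds this (default
#'   0.25).
#' @return List `mean`, `sd`, `n`, `heterogeneity_flag`. With no finite
#'   ratios, `mean` is `NA` (missing result); a single ratio gives `sd = 0`.
#' @export
aggregate_replicates <- function(ratios, heterogeneity_threshold = 0.25) {
  r <- ratios[is.finite(ratios)]
  if (!length(r))
    return(list(mean = NA_real_, sd = NA_real_, n = 0L,
                heterogeneity_flag = FALSE))
  m <- mean(r)
  s <- if (length(r) > 1L) sd(r) else 0
  flag <- if (m != 0) (s / abs(m)) > heterogeneity_threshold else s > 0
  list(mean = m, sd = s, n = length(r), heterogeneity_flag = flag)
}

#' Detect a fluorescence-dominated (unusable) spectrum
#'
#' A strong fluorescence emission swamps the Raman bands: the
#' baseline-corrected phosphate \eqn{\nu_1} area becomes negligible against
#' the raw intensity integrated over the same window. Flags a spectrum as
#' unusable when that contrast falls below `tau`, when the detector
#' saturates, or when there is no signal at all.
#'
#' @param spectrum a [raman_spectrum()].
#' @param tau contrast threshold (default 0.05).
#' @param saturation_level intensity ceiling; any point at or above it counts
#'   as saturation (`Inf` disables the check).
#' @return Logical: `TRUE` when the spectrum should not be used.
#' @export
detect_fluorescence <- function(spectrum, tau = 0.05, saturation_level = Inf) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (is.finite(saturation_level) &&
      any(spectrum$intensities >= saturation_level)) return(TRUE)
  corrected <- integrate_band(spectrum, "po4_v1", "local_linear")
  raw <- integrate_band(spectrum, "po4_v1", "none")
  if (!is.finite(raw) || raw <= 0) return(TRUE)   # no signal at all
  (max(corrected, 0) / raw) < tau
}

#' Qualitative C-H presence score
#'
#' Scores the organic C-H stretch region the way an analyst reading spectra
#' would: `prominent` bands indicate definite proteinaceous content, `weak`
#' bands poorly-defined organics, `absent` none. The score is the C-H
#' signal-to-noise ratio: peak height of the chord-corrected C-H region over
#' a robust noise sd (MAD of the detrended signal-free window, default
#' 1900-2200 cm\eqn{^{-1}}). Scale-invariant by construction. The corrected
#' region is smoothed with a short moving average before the peak is taken:
#' the C-H bands are broad (sigma about 20 cm\eqn{^{-1}}) and pass through
#' nearly unchanged, while the maximum of pure noise -- which otherwise
#' reaches about 2.7 noise sd over a window this wide -- is suppressed by the
#' square root of the smoothing width, so an empty region scores `absent`
#' rather than `weak`.
#'
#' @param spectrum a [raman_spectrum()].
#' @param noise_window length-2 numeric, signal-free region for noise
#'   estimation.
#' @param snr_prominent,snr_weak thresholds: `prominent` when SNR >=
#'   `snr_prominent` (default 10), `weak` when >= `snr_weak` (default 3).
#' @param smooth_points odd width of the moving-average peak filter.
#' @return One of `"prominent"`, `"weak"`, `"absent"`.
#' @export
ch_presence <- function(spectrum, noise_window = c(1900, 2200),
                        snr_prominent = 10, snr_weak = 3, smooth_points = 15L) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  lo <- .WINDOW_CH[1]; hi <- .WINDOW_CH[2]
  keep <- spectrum$wavenumbers >= lo & spectrum$wavenumbers <= hi
  w <- spectrum$wavenumbers[keep]; y <- spectrum$intensities[keep]
  y_lo <- .chord_endpoint(spectrum, lo); y_hi <- .chord_endpoint(spectrum, hi)
  corrected <- y - (y_lo + (y_hi - y_lo) * (w - lo) / (hi - lo))
  k <- min(smooth_points, length(corrected))
  smoothed <- stats::filter(corrected, rep(1 / k, k), sides = 2)
  peak <- max(smoothed, na.rm = TRUE)
  nk <- spectrum$wavenumbers >= noise_window[1] &
        spectrum$wavenumbers <= noise_window[2]
  if (sum(nk) >= 3L) {
    # detrend so a fluorescence slope does not masquerade as noise
    res <- stats::residuals(lm(spectrum$intensities[nk] ~ spectrum$wavenumbers[nk]))
    noise <- mad(res)
  } else noise <- 0
  if (noise <= 0) {
    # noiseless spectrum: any real corrected peak is prominent
    return(if (peak > 1e-9) "prominent" else "absent")
  }
  snr <- peak / noise
  if (snr >= snr_prominent) "prominent" else if (snr >= snr_weak) "weak" else "absent"
}

#' Analyse all replicate spectra of one sample
#'
#' Runs the full per-sample pipeline: fluorescence rejection per replicate,
#' band areas and ratio on the usable replicates, replicate aggregation, and
#' the C-H presence score (best replicate). `ratio_mean` is missing exactly
#' when every replicate is rejected.
#'
#' @param spectra list of [raman_spectrum()] replicates of one sample.
#' @param baseline_mode passed to [band_areas()].
#' @param denominator passed to [organic_phosphate_ratio()].
#' @param heterogeneity_threshold passed to [aggregate_replicates()].
#' @param fluorescence_tau,saturation_level passed to [detect_fluorescence()].
#' @return A list of class `sample_raman_result`: `sample_id`, `ratio_mean`,
#'   `ratio_sd`, `n_replicates` (usable), `fluorescence_failed`,
#'   `heterogeneity_flag`, `ch_presence`.
#' @export
analyze_sample <- function(spectra, baseline_mode = "local_linear",
                           denominator = "v1", heterogeneity_threshold = 0.25,
                           fluorescence_tau = 0.05, saturation_level = Inf) {
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, logical(1), "raman_spectrum")))
  fluor <- vapply(spectra, detect_fluorescence, logical(1),
                  tau = fluorescence_tau, saturation_level = saturation_level)
  ratios <- rep(NA_real_, length(spectra))
  for (i in which(!fluor)) {
    areas <- band_areas(spectra[[i]], baseline_mode)
    ratios[i] <- tryCatch(
      organic_phosphate_ratio(areas, denominator),
      error = function(e) NA_real_)
  }
  agg <- aggregate_replicates(ratios, heterogeneity_threshold)
  presence <- if (all(fluor)) "absent" else {
    scores <- vapply(spectra[!fluor], ch_presence, character(1))
    lv <- c(absent = 0L, weak = 1L, prominent = 2L)
    names(lv)[max(lv[scores]) + 1L]
  }
  structure(list(sample_id = spectra[[1]]$sample_id,
                 ratio_mean = agg$mean, ratio_sd = agg$sd,
                 n_replicates = agg$n,
                 fluorescence_failed = all(fluor) || agg$n == 0L,
                 heterogeneity_flag = agg$heterogeneity_flag,
                 ch_presence = presence),
            class = "sample_raman_result")
}
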