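# Shared helpers: deterministic configurations and analytic oracles.

# noise-free, jitter-free, heterogeneity-free config for exact oracles;
# any field can still be overridden
clean_config <- function(...) {
  defaults <- list(n = 1, seed = 1L, noise_sd = 0, replicate_jitter_sd = 0,
                   sample_hetero_sd = 0, ratio_noise_sd = 0)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# exact Gaussian band area over a window (erf closed form)
gauss_area <- function(amp, center, sigma, lo, hi) {
  amp * sigma * sqrt(2 * pi) *
    (pnorm((hi - center) / sigma) - pnorm((lo - center) / sigma))
}

# a simple flat-baseline bone-like spectrum built directly (no generator)
toy_spectrum <- function(intensity_fun, lo = 0, hi = 3200, by = 1,
                         sample_id = "toy") {
  w <- seq(lo, hi, by = by)
  raman_spectrum(w, intensity_fun(w), sample_id = sample_id)
}
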