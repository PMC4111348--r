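test_that("integrate_band handles degenerate signals exactly", {
  zero <- toy_spectrum(function(w) 0 * w)
  expect_equal(integrate_band(zero, "po4_v1", "none"), 0)
  const <- toy_spectrum(function(w) rep(7, length(w)))
  expect_equal(integrate_band(const, "ch", "local_linear"), 0, tolerance = 1e-12)
  expect_error(integrate_band(zero, c(983, 930)), "lo < hi")
  expect_error(integrate_band(toy_spectrum(function(w) w, lo = 500, hi = 1000),
                              "ch"), "outside")
})

test_that("trapezoidal area matches the erf closed form on a fine grid", {
  # unit-height Gaussian, center 956, sigma 10, 0.1 1/cm grid, window 930-983
  sp <- toy_spectrum(function(w) exp(-(w - 956)^2 / 200),
                     lo = 900, hi = 1010, by = 0.1)
  got <- integrate_band(sp, c(930, 983), "none")
  want <- gauss_area(1, 956, 10, 930, 983)   # = 24.86 to 2 dp
  expect_equal(got, want, tolerance = 1e-5)
  expect_equal(round(want, 1), 24.9)
})

test_that("areas are homogeneous of degree 1 in intensity and the ratio is scale-free", {
  cfg <- clean_config()
  sp <- simulate_spectrum(cfg, 1.2, seed = 6)
  a1 <- band_areas(sp, "local_linear")
  sp5 <- raman_spectrum(sp$wavenumbers, 5 * sp$intensities)
  a5 <- band_areas(sp5, "local_linear")
  expect_equal(a5$ch_area, 5 * a1$ch_area, tolerance = 1e-10)
  expect_equal(a5$po4_v1_area, 5 * a1$po4_v1_area, tolerance = 1e-10)
  expect_equal(a5$po4_v2_area, 5 * a1$po4_v2_area, tolerance = 1e-10)
  expect_equal(organic_phosphate_ratio(a5), organic_phosphate_ratio(a1),
               tolerance = 1e-10)
})

test_that("chord baseline removes any affine background exactly", {
  cfg <- clean_config()
  sp <- simulate_spectrum(cfg, 2, seed = 3)
  for (ab in list(c(10, 0), c(0, 4), c(25, -3))) {
    shifted <- raman_spectrum(sp$wavenumbers,
                              sp$intensities + ab[1] + ab[2] * sp$wavenumbers)
    for (win in band_windows()$label) {
      expect_equal(integrate_band(shifted, win, "local_linear"),
                   integrate_band(sp, win, "local_linear"),
                   tolerance = 1e-8)
    }
  }
})

test_that("zero organic signal clips the C-H area to zero without erroring", {
  cfg <- clean_config(noise_sd = 0.2)
  sp <- simulate_spectrum(cfg, 0, seed = 11)
  a <- band_areas(sp, "local_linear")
  expect_gte(a$ch_area, 0)
  expect_gt(a$po4_v1_area, 0)
})

test_that("ratio arithmetic and denominator variants", {
  mk <- function(ch, v1, v2) structure(
    list(ch_area = ch, po4_v1_area = v1, po4_v2_area = v2,
         baseline_mode = "none", clipped = c(ch = FALSE, po4_v1 = FALSE, po4_v2 = FALSE)),
    class = "band_areas")
  expect_equal(organic_phosphate_ratio(mk(0, 5, 1)), 0)
  expect_equal(organic_phosphate_ratio(mk(5, 5, 1)), 1)
  expect_equal(organic_phosphate_ratio(mk(6, 4, 2), "v1_plus_v2"), 1)
  expect_equal(organic_phosphate_ratio(mk(10, 20, 3)),
               organic_phosphate_ratio(mk(50, 100, 15)))
  expect_error(organic_phosphate_ratio(mk(3, 0, 1)), "unusable")
})

test_that("replicate aggregation follows the mean/sd/flag rule", {
  expect_equal(aggregate_replicates(c(0.3, 0.3, 0.3)),
               list(mean = 0.3, sd = 0, n = 3L, heterogeneity_flag = FALSE))
  a <- aggregate_replicates(c(0.2, 0.3, 0.4))
  expect_equal(a$mean, 0.3)
  expect_equal(a$sd, 0.1)
  expect_true(a$heterogeneity_flag)   # cv = 1/3 > 0.25 default
  expect_false(aggregate_replicates(c(0.2, 0.3, 0.4),
                                    heterogeneity_threshold = 0.5)$heterogeneity_flag)
  single <- aggregate_replicates(0.5)
  expect_equal(single$mean, 0.5)
  expect_equal(single$sd, 0)
  none <- aggregate_replicates(NA_real_)
  expect_true(is.na(none$mean))
  expect_equal(none$n, 0L)
})

test_that("fluorescence detection separates swamped from clean spectra", {
  clean <- simulate_spectrum(clean_config(), 2, seed = 1)
  expect_false(detect_fluorescence(clean))
  swamped <- simulate_spectrum(clean_config(fluor_amp = 2e5, noise_sd = 0.5),
                               0.1, seed = 1)
  expect_true(detect_fluorescence(swamped))
  allzero <- toy_spectrum(function(w) 0 * w)
  expect_true(detect_fluorescence(allzero))
  saturated <- raman_spectrum(clean$wavenumbers, pmin(clean$intensities, 10))
  expect_true(detect_fluorescence(saturated, saturation_level = 10))
})

test_that("C-H presence scoring is SNR-based, scale-invariant and monotone in organic gain", {
  none <- simulate_spectrum(clean_config(noise_sd = 0.5, organic_gain = 0),
                            1, seed = 2)
  expect_equal(ch_presence(none), "absent")

  strong <- simulate_spectrum(clean_config(noise_sd = 0.5), 3.5, seed = 2)
  expect_equal(ch_presence(strong), "prominent")
  scaled <- raman_spectrum(strong$wavenumbers, 10 * strong$intensities)
  expect_equal(ch_presence(scaled), ch_presence(strong))

  gains <- c(0, 0.05, 0.2, 0.8, 1.7, 5)
  lv <- c(absent = 0L, weak = 1L, prominent = 2L)
  scores <- vapply(gains, function(g) {
    sp <- simulate_spectrum(clean_config(noise_sd = 0.5, organic_gain = g),
                            1, seed = 13)
    lv[[ch_presence(sp)]]
  }, integer(1))
  expect_true(all(diff(scores) >= 0))
  expect_equal(scores[1], 0L)
  expect_equal(scores[length(scores)], 2L)
})

test_that("per-sample analysis aggregates replicates and flags failures", {
  cfg <- clean_config(noise_sd = 0.3, replicate_jitter_sd = 0.03)
  reps <- lapply(1:3, function(j)
    simulate_spectrum(cfg, 2.5, replicate_index = j, seed = 100 + j,
                      sample_id = "s1"))
  res <- analyze_sample(reps)
  expect_equal(res$n_replicates, 3L)
  expect_false(res$fluorescence_failed)
  expect_equal(res$ratio_mean, closed_form_ratio(cfg, 2.5), tolerance = 0.1)

  fl <- lapply(1:3, function(j)
    simulate_spectrum(clean_config(fluor_amp = 2e5, noise_sd = 0.5), 0.1,
                      replicate_index = j, seed = j, sample_id = "s2"))
  bad <- analyze_sample(fl)
  expect_true(bad$fluorescence_failed)
  expect_true(is.na(bad$ratio_mean))
})
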