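test_that("pearson_cor matches hand-computed and limiting cases", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6))$r, 1)
  res <- pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  expect_equal(res$r_squared, 0.64)
  expect_error(pearson_cor(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_cor(1:2, 2:3), "at least 3")
})

test_that("pearson_cor agrees with a direct two-pass covariance oracle", {
  withr::with_seed(99, {
    for (k in 1:20) {
      n <- sample(5:60, 1)
      x <- rnorm(n); y <- 0.4 * x + rnorm(n)
      res <- pearson_cor(x, y)
      r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(res$r, r_oracle, tolerance = 1e-12)
      t_stat <- r_oracle * sqrt((n - 2) / (1 - r_oracle^2))
      expect_equal(res$p_two_sided, 2 * pt(-abs(t_stat), n - 2),
                   tolerance = 1e-12)
      expect_true(res$ci95[1] <= res$r && res$r <= res$ci95[2])
    }
  })
})

test_that("r is invariant under positive affine maps and flips sign with negative scale", {
  withr::with_seed(7, {
    x <- rnorm(25); y <- 0.6 * x + rnorm(25)
    r0 <- pearson_cor(x, y)$r
    expect_equal(pearson_cor(3 * x + 2, 0.5 * y - 4)$r, r0, tolerance = 1e-12)
    expect_equal(pearson_cor(-2 * x + 1, y)$r, -r0, tolerance = 1e-12)
  })
})

test_that("leverages follow the closed form and always sum to 2", {
  d <- influence_diagnostics(c(0, 1, 2), c(0.1, 0.9, 2.2))
  expect_equal(d$leverage, c(5 / 6, 1 / 3, 5 / 6))
  withr::with_seed(21, {
    for (k in 1:10) {
      n <- sample(4:50, 1)
      x <- rnorm(n); y <- rnorm(n)
      dd <- influence_diagnostics(x, y)
      expect_equal(sum(dd$leverage), 2, tolerance = 1e-10)
      # closed form h_i = 1/n + (x_i - xbar)^2 / SSx
      expect_equal(dd$leverage, 1 / n + (x - mean(x))^2 / sum((x - mean(x))^2),
                   tolerance = 1e-10)
    }
  })
})

test_that("on the reference table the top-leverage point has the largest ratio", {
  cc <- complete_cases(bnw_dataset())
  d <- influence_diagnostics(cc$raman_ratio, cc$pct_collagen)
  # exhaustive check over all points
  expect_equal(which.max(d$leverage), which.max(cc$raman_ratio))
})

test_that("sensitivity re-analysis rules compose and reduce to identity", {
  cc <- complete_cases(bnw_dataset())
  x <- cc$raman_ratio; y <- cc$pct_collagen

  none <- sensitivity_reanalysis(x, y, ids = cc$sample_id)
  expect_equal(none$result_after$r, pearson_cor(x, y)$r)
  expect_length(none$removed_ids, 0)

  both <- sensitivity_reanalysis(x, y, ids = cc$sample_id,
                                 leverage_k = 2, residual_m = 1)
  expect_equal(both$n_after, 28L)
  # the two leverage removals are the two highest-ratio samples
  top2 <- cc$sample_id[order(x, decreasing = TRUE)[1:2]]
  expect_setequal(both$removed_ids[1:2], top2)

  expl <- sensitivity_reanalysis(x, y, ids = cc$sample_id,
                                 explicit = both$removed_ids)
  expect_equal(expl$result_after$r, both$result_after$r)

  expect_error(sensitivity_reanalysis(x[1:4], y[1:4], leverage_k = 2),
               "fewer than 3")
  expect_error(sensitivity_reanalysis(x, y, explicit = "nope"), "not in dataset")
})

test_that("dependent-correlation comparison: null identity and degenerate input", {
  res <- compare_dependent_correlations(0.5, 0.5, 0.3, 30)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_two_sided, 1)
  expect_error(compare_dependent_correlations(1, 0.5, 0.3, 30), "degenerate")
  expect_error(compare_dependent_correlations(0.5, 0.4, 0.3, 3), "n >= 4")
})

test_that("Steiger and Williams p-values agree with a bootstrap oracle", {
  for (sd_seed in c(21, 41)) {
    dat <- withr::with_seed(sd_seed, {
      n <- 80
      j <- rnorm(n)
      k <- 0.6 * j + rnorm(n, 0, 0.8)
      h <- 0.4 * j + 0.3 * k + rnorm(n, 0, 0.9)
      list(j = j, k = k, h = h, n = n)
    })
    st <- compare_dependent_correlations(cor(dat$j, dat$k), cor(dat$j, dat$h),
                                         cor(dat$k, dat$h), dat$n)
    wi <- compare_dependent_correlations(cor(dat$j, dat$k), cor(dat$j, dat$h),
                                         cor(dat$k, dat$h), dat$n,
                                         method = "williams")
    p_boot <- withr::with_seed(sd_seed + 1, {
      d <- replicate(10000, {
        ix <- sample.int(dat$n, replace = TRUE)
        atanh(cor(dat$j[ix], dat$k[ix])) - atanh(cor(dat$j[ix], dat$h[ix]))
      })
      d_obs <- atanh(cor(dat$j, dat$k)) - atanh(cor(dat$j, dat$h))
      2 * pnorm(-abs(d_obs / sd(d)))
    })
    expect_lt(abs(st$p_two_sided - p_boot), 0.06)
    expect_lt(abs(wi$p_two_sided - st$p_two_sided), 0.02)
  }
})

test_that("correlation p-values are uniform under the null (type-I error)", {
  cfg <- cohort_config(n = 20, seed = 0, organic_gain = 0,
                       ratio_noise_sd = 0.05)
  ps <- vapply(seq_len(2000), function(k) {
    cfg_k <- cfg; cfg_k$seed <- k
    sim <- simulate_cohort(cfg_k, spectra = FALSE)
    pearson_cor(sim$dataset$raman_ratio, sim$dataset$pct_collagen)$p_two_sided
  }, numeric(1))
  rate <- mean(ps < 0.05)
  half <- qnorm(0.975) * sqrt(0.05 * 0.95 / 2000)
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})
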