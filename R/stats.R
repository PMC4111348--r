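#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation, two-sided p-value from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} df, coefficient of
#' determination, and a 95% CI via the Fisher z transform.
#'
#' @param x,y numeric vectors of equal length, n >= 3, both with nonzero
#'   variance. Pairs with a missing value in either are dropped.
#' @return A list of class `correlation_result`: `r`, `r_squared`
#'   (proportion; multiply by 100 for the percentage form), `p_two_sided`,
#'   `n`, `ci95`.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  z <- atanh(r)
  half <- qnorm(0.975) / sqrt(n - 3)
  structure(list(r = r, r_squared = r^2, p_two_sided = ct$p.value, n = n,
                 ci95 = tanh(c(z - half, z + half))),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (R2 = %.1f%%), n = %d, p = %.3g, 95%% CI [%.3f, %.3f]\n",
              x$r, 100 * x$r_squared, x$n, x$p_two_sided,
              x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Influence diagnostics for a simple regression of y on x
#'
#' Per-point leverage \eqn{h_i = 1/n + (x_i - \bar x)^2 / \sum (x - \bar x)^2}
#' and externally studentized residuals from the OLS fit. Leverages always
#' sum to 2 (the number of regression parameters); high-leverage points sit
#' at the extremes of the predictor, large studentized residuals are outliers
#' in the response.
#'
#' @param x,y numeric vectors, complete pairs, n >= 3.
#' @return A `data.frame` with columns `leverage`, `studentized_residual`.
#' @export
influence_diagnostics <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  fit <- lm(y ~ x)
  data.frame(leverage = unname(hatvalues(fit)),
             studentized_residual = unname(rstudent(fit)))
}

#' Correlation sensitivity re-analysis after influential-point removal
#'
#' Removes points by a composable rule and recomputes the correlation:
#' first the `leverage_k` highest-leverage points (the extremes of `x`),
#' then -- with diagnostics refitted on what remains -- the `residual_m`
#' largest absolute externally studentized residuals. Alternatively,
#' `explicit` names the removals outright so a published re-analysis can be
#' reproduced exactly once the removed points are identified.
#'
#' @param x,y numeric vectors (predictor, response); incomplete pairs are
#'   dropped before any removal.
#' @param ids identifiers parallel to `x`; defaults to positional indices.
#' @param leverage_k number of top-leverage points to remove first.
#' @param residual_m number of top-|studentized residual| points to remove
#'   after the leverage removals.
#' @param explicit ids to remove instead of the rule.
#' @return A list of class `sensitivity_result`: `removed_ids`,
#'   `result_after` (a [pearson_cor()] result), `n_after`.
#' @export
sensitivity_reanalysis <- function(x, y, ids = NULL, leverage_k = 0L,
                                   residual_m = 0L, explicit = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(x))
  stopifnot(length(ids) == length(x), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; ids <- as.character(ids[ok])

  removed <- character(0)
  if (!is.null(explicit)) {
    explicit <- as.character(explicit)
    if (!all(explicit %in% ids))
      stop("explicit ids not in dataset: ",
           paste(setdiff(explicit, ids), collapse = ", "))
    removed <- explicit
  } else {
    if (leverage_k > 0L) {
      d <- influence_diagnostics(x, y)
      removed <- ids[order(d$leverage, decreasing = TRUE)[seq_len(leverage_k)]]
    }
    if (residual_m > 0L) {
      keep <- !(ids %in% removed)
      d <- influence_diagnostics(x[keep], y[keep])
      removed <- c(removed,
                   ids[keep][order(abs(d$studentized_residual),
                                   decreasing = TRUE)[seq_len(residual_m)]])
    }
  }
  keep <- !(ids %in% removed)
  if (sum(keep) < 3L) stop("removals leave fewer than 3 points")
  structure(list(removed_ids = removed,
                 result_after = pearson_cor(x[keep], y[keep]),
                 n_after = sum(keep)),
            class = "sensitivity_result")
}

#' Compare two dependent overlapping correlations
#'
#' Tests H0: rho_jk = rho_jh when both correlations share variable j and all
#' three variables are measured on the same n samples (e.g. does the Raman
#' ratio correlate more strongly with %C than with % collagen?). Default is
#' Steiger's z using the back-transformed average correlation; Williams' t
#' is available as an alternative. Two-sided p-values.
#'
#' @param r_jk,r_jh the two correlations sharing variable j.
#' @param r_kh correlation between the two non-shared variables.
#' @param n common sample size (>= 4).
#' @param method `"steiger"` (default) or `"williams"`.
#' @return A list of class `dependent_correlation_comparison`: `r_jk`,
#'   `r_jh`, `r_kh`, `n`, `statistic`, `p_two_sided`, `method`.
#' @export
compare_dependent_correlations <- function(r_jk, r_jh, r_kh, n,
                                           method = c("steiger", "williams")) {
  method <- match.arg(method)
  rs <- c(r_jk, r_jh, r_kh)
  if (any(!is.finite(rs)) || any(abs(rs) > 1))
    stop("correlations must be finite and in [-1, 1]")
  if (any(abs(c(r_jk, r_jh)) == 1))
    stop("degenerate input: |r| = 1")
  if (n < 4) stop("need n >= 4")

  if (method == "steiger") {
    # Steiger (1980): z-test with pooled covariance at the back-transformed
    # average of the two compared correlations
    rbar <- tanh((atanh(r_jk) + atanh(r_jh)) / 2)
    psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
    cov_z <- psi / (1 - rbar^2)^2
    stat <- (atanh(r_jk) - atanh(r_jh)) * sqrt((n - 3) / (2 - 2 * cov_z))
    p <- 2 * pnorm(-abs(stat))
  } else {
    det_r <- 1 - r_jk^2 - r_jh^2 - r_kh^2 + 2 * r_jk * r_jh * r_kh
    rbar <- (r_jk + r_jh) / 2
    denom <- 2 * ((n - 1) / (n - 3)) * det_r + rbar^2 * (1 - r_kh)^3
    stat <- (r_jk - r_jh) * sqrt((n - 1) * (1 + r_kh) / denom)
    p <- 2 * pt(-abs(stat), df = n - 3)
  }
  structure(list(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = as.integer(n),
                 statistic = stat, p_two_sided = min(1, p), method = method),
            class = "dependent_correlation_comparison")
}

#' @export
print.dependent_correlation_comparison <- function(x, ...) {
  cat(sprintf("H0: rho_jk = rho_jh (%s): r_jk = %.3f vs r_jh = %.3f (r_kh = %.3f, n = %d)\n  statistic = %.3f, two-sided p = %.3f\n",
              x$method, x$r_jk, x$r_jh, x$r_kh, x$n, x$statistic,
              x$p_two_sided))
  invisible(x)
}
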