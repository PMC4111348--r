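#' Screening decision for one sample
#'
#' Formalises the prescreening call an analyst makes from the spectra:
#' a sample is `unusable` when fluorescence defeated the measurement (no
#' ratio), `viable` when its mean organic-phosphate ratio reaches the
#' threshold or its C-H bands are prominent, and `suspect` otherwise.
#'
#' @param result a `sample_raman_result` from [analyze_sample()].
#' @param ratio_threshold decision threshold on the mean ratio.
#' @return A list of class `screening_decision`: `sample_id`, `decision`
#'   (`"viable"`, `"suspect"`, `"unusable"`), `basis`.
#' @export
classify_sample <- function(result, ratio_threshold) {
  stopifnot(inherits(result, "sample_raman_result"))
  if (result$fluorescence_failed || !is.finite(result$ratio_mean)) {
    decision <- "unusable"; basis <- "fluorescence"
  } else if (result$ratio_mean >= ratio_threshold) {
    decision <- "viable"; basis <- "ratio_threshold"
  } else if (identical(result$ch_presence, "prominent")) {
    decision <- "viable"; basis <- "ch_presence"
  } else {
    decision <- "suspect"; basis <- "ratio_threshold"
  }
  structure(list(sample_id = result$sample_id, decision = decision,
                 basis = basis),
            class = "screening_decision")
}

#' Evaluate a ratio threshold against wet-chemistry truth
#'
#' Treats `pct_collagen > collagen_threshold` (strict, matching the
#' "greater than 1% yield" convention) as the ground-truth positive and
#' `raman_ratio >= ratio_threshold` as the predicted positive, and tabulates
#' the confusion matrix with sensitivity, specificity and Youden's J.
#' Records missing either value are excluded and counted separately.
#'
#' @param dataset a `paired_dataset` data frame.
#' @param ratio_threshold decision threshold on the Raman ratio.
#' @param collagen_threshold ground-truth collagen cut, % w/w (default 1).
#' @return A list of class `screen_evaluation`: thresholds, `confusion`
#'   (tp/fp/tn/fn), `sensitivity`, `specificity`, `youden_j`, `n_evaluable`,
#'   `n_excluded`.
#' @export
evaluate_screen <- function(dataset, ratio_threshold, collagen_threshold = 1.0) {
  ok <- is.finite(dataset$raman_ratio) & is.finite(dataset$pct_collagen)
  if (!any(ok)) stop("no records with both ratio and collagen present")
  truth <- dataset$pct_collagen[ok] > collagen_threshold
  pred <- dataset$raman_ratio[ok] >= ratio_threshold
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(ratio_threshold = ratio_threshold,
                 collagen_threshold = collagen_threshold,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 sensitivity = sens, specificity = spec,
                 youden_j = sens + spec - 1,
                 n_evaluable = sum(ok), n_excluded = sum(!ok)),
            class = "screen_evaluation")
}

#' Choose the ratio threshold maximising Youden's J
#'
#' Sweeps every observed ratio as a candidate cut, evaluates J for each via
#' [evaluate_screen()], and returns the midpoint between the maximising cut
#' and the largest observed ratio strictly below it (so the returned
#' threshold sits in the gap between classes). Ties in J break toward the
#' lower cut, i.e. toward higher sensitivity. Errors when the truth is
#' single-class (J undefined).
#'
#' @inheritParams evaluate_screen
#' @return A list: `threshold`, `youden_j`, `evaluation` (the
#'   [evaluate_screen()] result at the chosen threshold).
#' @export
choose_threshold <- function(dataset, collagen_threshold = 1.0) {
  ok <- is.finite(dataset$raman_ratio) & is.finite(dataset$pct_collagen)
  if (!any(ok)) stop("no records with both ratio and collagen present")
  truth <- dataset$pct_collagen[ok] > collagen_threshold
  if (all(truth) || !any(truth))
    stop("single-class truth: Youden's J undefined at this collagen threshold")
  ratios <- sort(unique(dataset$raman_ratio[ok]))
  js <- vapply(ratios, function(thr)
    evaluate_screen(dataset, thr, collagen_threshold)$youden_j, numeric(1))
  best <- which(js == max(js))[1]          # ties -> lowest cut
  cut <- ratios[best]
  below <- ratios[ratios < cut]
  thr <- if (length(below)) (cut + max(below)) / 2 else cut
  list(threshold = thr, youden_j = js[best],
       evaluation = evaluate_screen(dataset, thr, collagen_threshold))
}
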