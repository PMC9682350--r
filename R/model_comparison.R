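# Pairwise model comparison with the variance-corrected resampled t-test.
#
# Fold scores from repeated cross-validation are not independent: the
# training sets overlap heavily, so the naive paired t-test is
# anti-conservative. The corrected test inflates the variance by
# (1/n + rho) with rho = n_test/n_train, the standard instantiation for
# k-fold resampling (rho = (1/k)/(1-1/k), i.e. 1/9 for 10-fold).

#' Corrected resampled t-test
#'
#' Tests the mean of the paired fold-score differences `a - b` with the
#' variance correction for overlapping training sets:
#' `t = mean(d) / sqrt((1/n + r/(1-r)) * var(d))` with `r` the test
#' fraction, and a two-sided p-value from Student's t with `n - 1`
#' degrees of freedom. Identical vectors give `t = 0, p = 1`.
#'
#' @param scores_a,scores_b per-fold metric vectors aligned fold-for-fold.
#' @param test_fraction held-out fraction per fold (1/k for k-fold CV).
#' @return list with `t`, `p`, `n`, `correction_factor`.
#' @export
corrected_ttest <- function(scores_a, scores_b, test_fraction) {
  if (length(scores_a) != length(scores_b)) {
    stopf("score vectors must be aligned (lengths %d vs %d)",
          length(scores_a), length(scores_b))
  }
  stopifnot(length(scores_a) >= 2, test_fraction > 0, test_fraction < 1)
  d <- scores_a - scores_b
  n <- length(d)
  corr <- 1 / n + test_fraction / (1 - test_fraction)
  vd <- stats::var(d)
  if (vd == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t_stat <- mean(d) / sqrt(corr * vd)
  }
  p <- 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  list(t = t_stat, p = p, n = n, correction_factor = corr)
}

#' Pairwise comparison of cross-validated models
#'
#' Runs the corrected t-test on the AUROC fold scores of every unordered
#' pair of models, with Bonferroni adjustment over the number of pairs.
#' All results must share the identical fold structure (same folds, same
#' repetitions), which is checked.
#'
#' @param results named list of `cv_result` objects.
#' @param alpha significance level applied to adjusted p-values.
#' @param metric fold metric to compare (default `"auroc"`).
#' @return data.frame with one row per pair: `t_stat`, `p_raw`,
#'   `p_adjusted`, `significant`, `n_scores`, `correction_factor`.
#' @export
pairwise_compare <- function(results, alpha = 0.05, metric = "auroc") {
  stopifnot(is.list(results), length(results) >= 2, !is.null(names(results)))
  ref <- results[[1]]
  for (r in results[-1]) {
    if (!identical(r$folds, ref$folds)) {
      stopf("cv_result objects do not share the same fold structure")
    }
  }
  test_fraction <- 1 / ref$cv$k
  nms <- names(results)
  pairs <- utils::combn(nms, 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tt <- corrected_ttest(results[[a]]$per_fold[[metric]],
                          results[[b]]$per_fold[[metric]], test_fraction)
    data.frame(model_a = a, model_b = b, t_stat = tt$t, p_raw = tt$p,
               p_adjusted = min(1, tt$p * m), n_scores = tt$n,
               correction_factor = tt$correction_factor)
  })
  out <- do.call(rbind, out)
  out$significant <- out$p_adjusted < alpha
  attr(out, "bonferroni_factor") <- m
  attr(out, "alpha") <- alpha
  out
}
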