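# Tile-level evaluation statistics: confusion counts, the standard binary
# classification metrics, AUROC (Mann-Whitney formulation), DeLong's test for
# paired AUROC differences, and McNemar's test on discordant
# classifications. Predictions are data frames with at least `score` (in
# [0, 1]) and `label` (0/1, positive class = cDLBCL-like = 1); paired tests
# additionally require `tile_id`.

assert_predictions <- function(preds, need_id = FALSE) {
  req <- c("score", "label", if (need_id) "tile_id")
  miss <- setdiff(req, names(preds))
  if (length(miss)) abort("predictions lack column(s): ", paste(miss, collapse = ", "))
  if (any(preds$score < 0 | preds$score > 1)) abort("scores must lie in [0, 1]")
  if (!all(preds$label %in% c(0L, 1L))) abort("labels must be 0 or 1")
  invisible(preds)
}

#' Confusion counts at a threshold
#'
#' Scores `>= threshold` are predicted positive (class 1). The four counts
#' partition the records.
#'
#' @param preds Prediction data frame with `score` and `label`.
#' @param threshold Decision threshold (default 0.5, `>=` convention).
#' @return A `confusion_counts` object: list with `tp, fp, tn, fn`.
#' @export
confusion <- function(preds, threshold = 0.5) {
  assert_predictions(preds)
  if (!nrow(preds)) abort("predictions are empty")
  pred <- preds$score >= threshold
  pos <- preds$label == 1L
  structure(
    list(tp = sum(pred & pos), fp = sum(pred & !pos),
         tn = sum(!pred & !pos), fn = sum(!pred & pos)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Binary classification metrics from confusion counts
#'
#' Accuracy, precision, sensitivity (recall), specificity and F1
#' (`2 * precision * sensitivity / (precision + sensitivity)`). A metric
#' whose denominator is zero is reported as `NA` and named in the
#' `undefined` field rather than silently propagated.
#'
#' @param counts A `confusion_counts` object.
#' @return A `metrics_report`: list of the five metrics plus `undefined`
#'   (character vector of metrics with zero denominators).
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fp + tn + fn == 0L) abort("confusion counts sum to zero")
  precision <- safe_ratio(tp, tp + fp)
  sensitivity <- safe_ratio(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(sensitivity) && precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else NA_real_
  out <- list(
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    precision = precision,
    sensitivity = sensitivity,
    specificity = safe_ratio(tn, tn + fp),
    f1 = f1
  )
  out$undefined <- names(out)[vapply(out, function(v) is.na(v[1]), logical(1))]
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  for (m in c("accuracy", "precision", "sensitivity", "specificity", "f1")) {
    v <- x[[m]]
    cat(sprintf("%-12s %s\n", m, if (is.na(v)) "undefined" else sprintf("%.4f", v)))
  }
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a uniformly random positive outscores a uniformly
#' random negative, with ties counted one half; computed from average ranks.
#'
#' @param scores Numeric scores, higher meaning more positive.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  if (is.data.frame(scores)) { labels <- scores$label; scores <- scores$score }
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

pair_predictions <- function(preds_a, preds_b) {
  assert_predictions(preds_a, need_id = TRUE)
  assert_predictions(preds_b, need_id = TRUE)
  only_a <- setdiff(preds_a$tile_id, preds_b$tile_id)
  only_b <- setdiff(preds_b$tile_id, preds_a$tile_id)
  if (length(only_a) || length(only_b))
    abort("predictions are not pairable; unmatched tile_id(s): ",
          paste(head(c(only_a, only_b), 5L), collapse = ", "))
  if (anyDuplicated(preds_a$tile_id) || anyDuplicated(preds_b$tile_id))
    abort("duplicated tile_id(s) in predictions")
  b <- preds_b[match(preds_a$tile_id, preds_b$tile_id), ]
  if (!all(preds_a$label == b$label))
    abort("paired predictions disagree on labels for tile_id(s): ",
          paste(head(preds_a$tile_id[preds_a$label != b$label], 5L), collapse = ", "))
  list(a = preds_a, b = b)
}

new_paired_test <- function(test, statistic, p_value, alpha, extra = list()) {
  structure(c(list(test = test, statistic = statistic, p_value = p_value,
                   alpha = alpha), extra),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
              x$test, x$statistic, x$p_value,
              if (x$p_value < x$alpha) "" else "not ", x$alpha))
  if (!is.null(x$b)) cat(sprintf("  discordant counts: b = %d, c = %d\n", x$b, x$c))
  invisible(x)
}

#' DeLong's test for two correlated AUROCs
#'
#' Fast structural-components estimator of the variance of
#' `AUC_A - AUC_B`, including the covariance induced by evaluating both
#' models on the same tiles; two-sided normal p-value. With zero estimated
#' variance the p-value is 1 when the AUCs are equal (e.g., a model compared
#' against itself) and 0 otherwise.
#'
#' @param preds_a,preds_b Prediction data frames with `tile_id, score,
#'   label`, paired by `tile_id` and agreeing on labels.
#' @param alpha Significance level recorded in the result.
#' @return A `paired_test_result` with the z statistic, p-value, and both
#'   AUCs (`auc_a`, `auc_b`).
#' @export
delong_test <- function(preds_a, preds_b, alpha = 0.05) {
  pr <- pair_predictions(preds_a, preds_b)
  labels <- pr$a$label
  pos <- labels == 1L
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) abort("both classes must be present")
  comp <- function(scores) {
    x <- scores[pos]; y <- scores[!pos]
    # placements: V10[i] = mean_j psi(x_i, y_j), V01[j] = mean_i psi(x_i, y_j)
    rx <- rank(c(x, y), ties.method = "average")
    v10 <- (rx[seq_len(m)] - rank(x, ties.method = "average")) / n
    v01 <- 1 - (rx[m + seq_len(n)] - rank(y, ties.method = "average")) / m
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  a <- comp(pr$a$score); b <- comp(pr$b$score)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- a$auc - b$auc
  if (var_diff <= .Machine$double.eps) {
    z <- 0; p <- if (abs(diff) < 1e-12) 1 else 0
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  new_paired_test("DeLong", z, p, alpha,
                  extra = list(auc_a = a$auc, auc_b = b$auc))
}

mcnemar_exact_p <- function(b, c) {
  n <- b + c
  if (n == 0L) return(1)
  binom.test(b, n, 0.5)$p.value
}

#' McNemar's test on discordant classifications
#'
#' `b` counts tiles misclassified by model A but correct under model B;
#' `c` the reverse. The default is the exact two-sided binomial p-value on
#' `(b, c)`; `method = "chisq"` gives the continuity-corrected chi-square
#' approximation for large `b + c`.
#'
#' @inheritParams delong_test
#' @param threshold Decision threshold applied to both models.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return A `paired_test_result` with fields `b` and `c`.
#' @export
mcnemar_test <- function(preds_a, preds_b, threshold = 0.5,
                         method = c("exact", "chisq"), alpha = 0.05) {
  method <- match.arg(method)
  pr <- pair_predictions(preds_a, preds_b)
  correct_a <- (pr$a$score >= threshold) == (pr$a$label == 1L)
  correct_b <- (pr$b$score >= threshold) == (pr$b$label == 1L)
  b <- sum(!correct_a & correct_b)
  c_ <- sum(correct_a & !correct_b)
  if (method == "exact") {
    p <- mcnemar_exact_p(b, c_)
    stat <- as.numeric(b)
  } else {
    if (b + c_ == 0L) { p <- 1; stat <- 0 }
    else {
      ct <- matrix(c(0, b, c_, 0), 2)  # only discordant cells matter
      res <- mcnemar.test(ct, correct = TRUE)
      p <- res$p.value; stat <- unname(res$statistic)
    }
  }
  new_paired_test(paste0("McNemar (", method, ")"), stat, p, alpha,
                  extra = list(b = b, c = c_))
}
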