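check_paired <- function(x, y, min_n = 3) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  if (length(x) < min_n) {
    abort(sprintf("At least %d paired observations are required.", min_n))
  }
  if (anyNA(x) || anyNA(y)) abort("Inputs must not contain NA.")
}

#' Pearson product-moment correlation
#'
#' Regression-task agreement between predicted and measured R-WT activity.
#'
#' @param x,y Numeric vectors of equal length (>= 3), both non-constant.
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  check_paired(x, y)
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Pearson correlation is undefined for a constant vector.",
          class = "stk11vep_undefined_metric")
  }
  cor(x, y, method = "pearson")
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall's tau. Tie-awareness matters here because
#' mean-imputation gives several variants the same score.
#'
#' @inheritParams pearson
#' @return Correlation in \[-1, 1\].
#' @export
kendall_tau <- function(x, y) {
  check_paired(x, y)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("Kendall's tau is undefined when one vector is all-tied.",
          class = "stk11vep_undefined_metric")
  }
  cor(x, y, method = "kendall")
}

as_lof_indicator <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (!all(labels %in% c("LoF", "WT-like"))) {
    abort("Labels must be 'LoF' or 'WT-like' (or a logical LoF indicator).")
  }
  labels == "LoF"
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' LoF is the positive class, so `scores` must be pathogenicity-oriented
#' (higher = more damaging). Over all (LoF, WT-like) pairs, the fraction
#' where the LoF variant scores strictly higher, with ties credited 0.5 —
#' computed via the rank-sum identity.
#'
#' @param scores Numeric vector of pathogenicity-oriented scores.
#' @param labels `"LoF"`/`"WT-like"` character vector or logical LoF
#'   indicator, same length as `scores`.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  pos <- as_lof_indicator(labels)
  if (length(scores) != length(pos)) {
    abort("scores and labels must have equal length.")
  }
  if (anyNA(scores)) abort("Scores must not contain NA.")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC is undefined with a single class.",
          class = "stk11vep_undefined_metric")
  }
  r <- rank(scores)  # midranks handle ties with 0.5 credit
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve by threshold sweep
#'
#' Sweeps the classification threshold from above the largest score
#' downward; all equal-scored items move together at one threshold, so tied
#' scores produce diagonal segments. The trapezoidal area under the returned
#' curve equals [auc()].
#'
#' @inheritParams auc
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, starting at
#'   (0, 0) and ending at (1, 1).
#' @export
roc_curve <- function(scores, labels) {
  pos <- as_lof_indicator(labels)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC is undefined with a single class.",
          class = "stk11vep_undefined_metric")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n_neg, numeric(1))
  tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Trapezoidal area under an ROC curve
#'
#' @param roc Tibble from [roc_curve()].
#' @return Area in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}
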