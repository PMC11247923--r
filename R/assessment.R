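#' Bootstrap resample indices over an evaluation set
#'
#' Draws `n_boot` resamples of variant indices with replacement. Given the
#' same `n`, `labels` and `seed`, the index matrix is identical — this is
#' what makes bootstrap estimates *paired* across predictors, as required by
#' [win_test()]. When `labels` are supplied, any resample containing a
#' single class (on which AUC is undefined) is redrawn, so exactly `n_boot`
#' valid resamples are returned; the redraw decision depends only on the
#' labels, never on a predictor's scores, preserving pairing.
#'
#' @param n Evaluation-set size.
#' @param n_boot Number of resamples (default 1000).
#' @param seed Integer seed (required; resampling is the only source of
#'   randomness).
#' @param labels Optional label vector of length `n` used to redraw
#'   single-class resamples.
#' @return Integer matrix, `n_boot` rows by `n` columns.
#' @export
bootstrap_resamples <- function(n, n_boot = 1000, seed, labels = NULL) {
  if (missing(seed)) abort("A bootstrap seed is required.")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE),
                nrow = n_boot, ncol = n)
  if (!is.null(labels)) {
    pos <- as_lof_indicator(labels)
    repeat {
      n_pos_row <- rowSums(matrix(pos[idx], nrow = n_boot))
      bad <- which(n_pos_row == 0 | n_pos_row == n)
      if (length(bad) == 0) break
      idx[bad, ] <- sample.int(n, n * length(bad), replace = TRUE)
    }
  }
  idx
}

#' Bootstrap a performance metric over the evaluation set
#'
#' Computes the point estimate of `metric_fn` on the full evaluation set and
#' its distribution over `n_boot` variant resamples drawn with replacement.
#' The 90% confidence interval is the 5th and 95th percentile of the
#' bootstrap estimates. All `n_boot` estimates are retained for downstream
#' paired win tests.
#'
#' @param metric_fn A function `(scores, truth) -> numeric(1)`, e.g.
#'   `pearson`, `kendall_tau` or `auc`.
#' @param scores Numeric vector of predictions on the evaluation set.
#' @param truth Numeric activity vector (for correlations) or label vector
#'   (for AUC), aligned with `scores`.
#' @param n_boot Number of resamples (default 1000).
#' @param seed Integer seed.
#' @param metric Optional metric name for reporting.
#' @param ci_percentiles Lower/upper percentile bounds (default `c(5, 95)`).
#' @return A `bootstrap_result` list: `metric`, `point_estimate`, `ci_low`,
#'   `ci_high`, `estimates`, `n_boot`, `seed`.
#' @export
bootstrap_metric <- function(metric_fn, scores, truth, n_boot = 1000, seed,
                             metric = NULL, ci_percentiles = c(5, 95)) {
  if (length(scores) != length(truth)) {
    abort("scores and truth must have equal length.")
  }
  labels <- if (!is.numeric(truth)) truth else NULL
  idx <- bootstrap_resamples(length(scores), n_boot = n_boot, seed = seed,
                             labels = labels)
  est <- apply(idx, 1, function(i) metric_fn(scores[i], truth[i]))
  ci <- quantile(est, ci_percentiles / 100, names = FALSE)
  structure(
    list(metric = metric %||% deparse(substitute(metric_fn)),
         point_estimate = metric_fn(scores, truth),
         ci_low = ci[1], ci_high = ci[2],
         estimates = est, n_boot = n_boot, seed = seed),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s = %.3f [%.3f, %.3f] (n_boot=%d, seed=%d)\n",
              x$metric, x$point_estimate, x$ci_low, x$ci_high,
              x$n_boot, x$seed))
  invisible(x)
}

#' Gaussian half-width from bootstrap estimates
#'
#' The 95% Gaussian-approximation half-width, 1.96 times the sample standard
#' deviation of the bootstrap estimates.
#'
#' @param boot_estimates Numeric vector of bootstrap estimates (length >= 2),
#'   or a `bootstrap_result`.
#' @return Half-width (numeric scalar).
#' @export
gaussian_ci <- function(boot_estimates) {
  if (inherits(boot_estimates, "bootstrap_result")) {
    boot_estimates <- boot_estimates$estimates
  }
  if (length(boot_estimates) < 2) abort("At least 2 estimates are required.")
  1.96 * sd(boot_estimates)
}

#' Rank predictors by average rank over three metrics
#'
#' Each predictor is ranked separately on Pearson correlation, Kendall's tau
#' and AUC (higher metric = better = smaller rank, ties receive average
#' ranks); the final ordering is by the mean of the three ranks.
#'
#' @param metrics Tibble/data frame with columns `predictor`, `pearson`,
#'   `kendall_tau`, `auc` (one row per predictor; >= 2 rows).
#' @return The input with added `rank_pearson`, `rank_tau`, `rank_auc`,
#'   `avg_rank`, sorted by `avg_rank` (ties broken by predictor name for a
#'   stable order).
#' @export
rank_predictors <- function(metrics) {
  needed <- c("predictor", "pearson", "kendall_tau", "auc")
  missing_cols <- setdiff(needed, names(metrics))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing metric column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(metrics[needed])) abort("Metric values must not be NA.")
  metrics |>
    dplyr::mutate(
      rank_pearson = rank(-.data$pearson),
      rank_tau = rank(-.data$kendall_tau),
      rank_auc = rank(-.data$auc),
      avg_rank = (.data$rank_pearson + .data$rank_tau + .data$rank_auc) / 3
    ) |>
    dplyr::arrange(.data$avg_rank, .data$predictor)
}

#' Select the best predictor from each team
#'
#' Applies [rank_predictors()] within each team and keeps the top-ranked
#' predictor per team; the representatives can then be re-ranked across
#' teams with another [rank_predictors()] call.
#'
#' @param metrics As in [rank_predictors()], with an additional `team`
#'   column.
#' @return One row per team (that team's best predictor), with within-team
#'   rank columns.
#' @export
select_team_representatives <- function(metrics) {
  if (!"team" %in% names(metrics)) abort("A 'team' column is required.")
  metrics |>
    dplyr::group_split(.data$team) |>
    purrr::map(function(g) {
      if (nrow(g) == 1) {
        dplyr::mutate(g, rank_pearson = 1, rank_tau = 1, rank_auc = 1,
                      avg_rank = 1)
      } else {
        rank_predictors(g)
      }
    }) |>
    purrr::map(~ dplyr::slice(.x, 1)) |>
    dplyr::bind_rows()
}

#' Paired bootstrap win test between two predictors
#'
#' Counts, over the shared bootstrap resamples, on how many the first
#' predictor's metric estimate strictly exceeds the second's, and tests the
#' win count against Binomial(n, 1/2): the p-value is the exact upper tail
#' \eqn{P[X \ge wins]}, computed in log space. Ties on a resample count as
#' non-wins (conservative).
#'
#' @param boot_a,boot_b Numeric vectors of bootstrap estimates from the same
#'   paired resamples (equal length, same seed), or `bootstrap_result`
#'   objects.
#' @return List with `wins`, `n`, `p_value`, `log10_p`.
#' @export
win_test <- function(boot_a, boot_b) {
  seed_a <- seed_b <- NULL
  if (inherits(boot_a, "bootstrap_result")) {
    seed_a <- boot_a$seed; boot_a <- boot_a$estimates
  }
  if (inherits(boot_b, "bootstrap_result")) {
    seed_b <- boot_b$seed; boot_b <- boot_b$estimates
  }
  if (length(boot_a) != length(boot_b)) {
    abort("Bootstrap estimate vectors are not paired (unequal lengths).",
          class = "stk11vep_pairing_error")
  }
  if (!is.null(seed_a) && !is.null(seed_b) && seed_a != seed_b) {
    abort("Bootstrap estimate vectors are not paired (different seeds).",
          class = "stk11vep_pairing_error")
  }
  wins <- sum(boot_a > boot_b)
  lp <- binom_tail_log10(wins, length(boot_a))
  list(wins = wins, n = length(boot_a),
       p_value = 10^lp, log10_p = lp)
}

#' Exact log10 upper tail of Binomial(n, 1/2)
#'
#' \eqn{\log_{10} P[X \ge k]} for \eqn{X \sim Binomial(n, 1/2)}, computed
#' with the log-space tail sum so values far below double underflow are
#' still exact in the log.
#'
#' @param k Number of wins.
#' @param n Number of trials.
#' @return log10 of the tail probability (0 when `k <= 0`).
#' @export
binom_tail_log10 <- function(k, n) {
  if (k <= 0) return(0)
  if (k > n) return(-Inf)
  pbinom(k - 1, n, 0.5, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Per-variant prediction difficulty matrix
#'
#' For each selected predictor (on the activity scale, all variants scored)
#' and each variant, the difficulty of the variant at that predictor:
#' * LoF variant `v`: the false positive rate when the predictor's value at
#'   `v` is used as the classification threshold — the fraction of WT-like
#'   variants predicted *less* active than `v`.
#' * WT-like variant `v`: the false negative rate — the fraction of LoF
#'   variants predicted *more* active than `v`.
#'
#' Computed over all variants in `truth` regardless of evaluation-set
#' exclusions.
#'
#' @param score_list Named list of named numeric vectors (predictor ->
#'   activity-scale scores covering every variant in `truth`).
#' @param truth Tibble with `variant_id` and `label` columns.
#' @return Matrix, predictors x variants, entries in \[0, 1\].
#' @export
difficulty_scores <- function(score_list, truth) {
  lab <- as_lof_indicator(truth$label)
  if (all(lab) || all(!lab)) {
    abort("Both classes are required for difficulty profiling.",
          class = "stk11vep_undefined_metric")
  }
  ids <- truth$variant_id
  out <- matrix(NA_real_, nrow = length(score_list), ncol = length(ids),
                dimnames = list(names(score_list), ids))
  for (p in names(score_list)) {
    s <- score_list[[p]][ids]
    if (anyNA(s)) {
      abort(sprintf("Predictor %s lacks scores for some variants.", p))
    }
    lof_scores <- s[lab]
    wt_scores <- s[!lab]
    out[p, lab] <- vapply(lof_scores,
                          function(v) mean(wt_scores < v), numeric(1))
    out[p, !lab] <- vapply(wt_scores,
                           function(v) mean(lof_scores > v), numeric(1))
  }
  out
}
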