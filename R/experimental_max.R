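#' Sample one Experimental-Max predictor
#'
#' Experimental-Max predicts each variant's R-WT activity by sampling a
#' single replicate measurement of that variant: first a biological
#' replicate in which the variant appears is picked uniformly, then a
#' technical replicate within it, and the normalized activity of that cell
#' is the prediction. Sampling is independent across variants. Because every
#' prediction is an actual replicate value, the predictor embodies the
#' assay's own measurement variability.
#'
#' @param normalized Tibble from [normalize_replicates()] (control rows are
#'   ignored).
#' @param variant_ids Variants to score (default: all variants present).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so repeated calls under one master seed give independent runs).
#' @return Named numeric vector of sampled R-WT activities.
#' @export
sample_expmax <- function(normalized, variant_ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dat <- dplyr::filter(normalized, !.data$variant_id %in% CONTROL_IDS)
  if (is.null(variant_ids)) variant_ids <- unique(dat$variant_id)
  groups <- split(dat[c("bio_rep", "r_wt")], dat$variant_id)
  missing_v <- setdiff(variant_ids, names(groups))
  if (length(missing_v) > 0) {
    abort(paste0("No measurements for variant(s): ",
                 paste(missing_v, collapse = ", ")),
          class = "stk11vep_missing_data")
  }
  vapply(variant_ids, function(v) {
    g <- groups[[v]]
    bios <- unique(g$bio_rep)
    b <- if (length(bios) == 1) bios else sample(bios, 1)
    vals <- g$r_wt[g$bio_rep == b]
    if (length(vals) == 1) vals else sample(vals, 1)
  }, numeric(1))
}

#' Evaluate the Experimental-Max performance ceiling
#'
#' Generates `n_runs` Experimental-Max predictors by replicate resampling
#' and scores each against the replicate-averaged ground truth with Pearson
#' correlation, Kendall's tau and AUC (sampled activities are negated for
#' AUC, exactly as activity-orientation predictor submissions are). The
#' summary per metric is the mean over runs with the 5th/95th percentile
#' band. Pearson and tau quantify the assay's consistency in measuring R-WT
#' activity; AUC its consistency in separating LoF from WT-like variants;
#' together they bound what any predictor can achieve against this assay.
#'
#' @param normalized Tibble from [normalize_replicates()].
#' @param truth Tibble with `variant_id`, `mean_r_wt`, `label` columns,
#'   restricted to the variants to evaluate on (e.g. the evaluation set).
#' @param n_runs Number of resampled predictors (default 1000).
#' @param seed Integer master seed.
#' @return List with `summary` (tibble: metric, mean, ci_low, ci_high),
#'   `estimates` (n_runs x 3 matrix), `n_runs`, `seed`.
#' @export
evaluate_experimental_max <- function(normalized, truth, n_runs = 1000,
                                      seed) {
  if (missing(seed)) abort("A seed is required.")
  set.seed(seed)
  ids <- truth$variant_id
  est <- matrix(NA_real_, nrow = n_runs, ncol = 3,
                dimnames = list(NULL, c("pearson", "kendall_tau", "auc")))
  for (r in seq_len(n_runs)) {
    s <- sample_expmax(normalized, variant_ids = ids)
    est[r, "pearson"] <- pearson(s, truth$mean_r_wt)
    est[r, "kendall_tau"] <- kendall_tau(s, truth$mean_r_wt)
    est[r, "auc"] <- auc(-s, truth$label)
  }
  summary <- tibble::tibble(
    metric = colnames(est),
    mean = colMeans(est),
    ci_low = apply(est, 2, quantile, 0.05, names = FALSE),
    ci_high = apply(est, 2, quantile, 0.95, names = FALSE)
  )
  list(summary = summary, estimates = est, n_runs = n_runs, seed = seed)
}
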