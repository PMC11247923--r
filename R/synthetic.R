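#' Configuration for a synthetic luciferase assay
#'
#' Describes a simulated dataset with the same nested structure as the real
#' assay: a pool of biological replicates, each containing 2-3 technical
#' replicates with their own EV/WT control levels, and each variant measured
#' in a random subset of the biological replicates. True activities are
#' drawn from a two-component mixture whose defaults resemble the observed
#' spread of LoF and WT-like variants (means around 0.25 and 1.1); they are
#' configuration, not estimates.
#'
#' @param n_variants Number of variants.
#' @param lof_fraction Fraction of variants drawn from the LoF component.
#' @param lof_mean,lof_sd Mean/sd of the LoF true-activity component.
#' @param wt_mean,wt_sd Mean/sd of the WT-like true-activity component.
#' @param n_bio_total Total biological replicates in the experiment
#'   (default 17).
#' @param n_bio_range Integer range of biological replicates per variant
#'   (default 3-6).
#' @param n_tech_range Integer range of technical replicates per biological
#'   replicate (default 2-3).
#' @param bio_noise_sd Sd of the per-(variant, biological replicate) shared
#'   offset, on the R-WT scale.
#' @param tech_noise_sd Sd of the per-measurement noise, on the R-WT scale.
#' @param ev_level_range,wt_level_range Uniform ranges for the raw EV and WT
#'   control levels of each (biological, technical) replicate; the EV range
#'   must lie entirely below the WT range.
#' @param seed Integer seed.
#' @return A validated `assay_sim_config` list.
#' @export
assay_sim_config <- function(n_variants = 28, lof_fraction = 15 / 28,
                             lof_mean = 0.25, lof_sd = 0.15,
                             wt_mean = 1.1, wt_sd = 0.25,
                             n_bio_total = 17,
                             n_bio_range = c(3L, 6L),
                             n_tech_range = c(2L, 3L),
                             bio_noise_sd = 0.15, tech_noise_sd = 0.05,
                             ev_level_range = c(50, 150),
                             wt_level_range = c(500, 1500),
                             seed = 1L) {
  stopifnot(n_variants >= 1, lof_fraction >= 0, lof_fraction <= 1,
            lof_sd >= 0, wt_sd >= 0,
            length(n_bio_range) == 2, n_bio_range[1] >= 1,
            n_bio_range[1] <= n_bio_range[2],
            n_bio_range[2] <= n_bio_total,
            length(n_tech_range) == 2, n_tech_range[1] >= 1,
            n_tech_range[1] <= n_tech_range[2],
            bio_noise_sd >= 0, tech_noise_sd >= 0)
  if (max(ev_level_range) >= min(wt_level_range)) {
    abort("EV raw level range must lie strictly below the WT range.",
          class = "stk11vep_validation_error")
  }
  structure(as.list(environment()), class = "assay_sim_config")
}

#' Simulate a replicate-level assay dataset
#'
#' Draws a true R-WT activity per variant from the configured mixture, then
#' emits raw luminescence readings for every (biological, technical)
#' replicate cell the variant is measured in:
#' `raw = ev + (wt - ev) * (true + bio_effect + tech_noise)`, where `ev` and
#' `wt` are the cell's own control levels, `bio_effect` is shared across a
#' variant's measurements within one biological replicate, and `tech_noise`
#' is per-measurement. Normalizing a reading against its own controls
#' therefore recovers `true + noise` exactly, so with zero noise the whole
#' normalization/aggregation pipeline round-trips the generating activities.
#' Control rows (EV, WT, and a kinase-dead KD at 2% activity) are emitted in
#' every cell. Identical config and seed give identical output.
#'
#' @param cfg An [assay_sim_config()].
#' @return List with `replicates` (raw measurement tibble including control
#'   rows) and `truth` (tibble: `variant_id`, `true_activity`, `class`,
#'   `true_label` — the 0.6-thresholded label of the true activity).
#' @export
simulate_assay <- function(cfg) {
  stopifnot(inherits(cfg, "assay_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_variants
  ids <- sprintf("p.SIM%03d", seq_len(n))
  n_lof <- round(n * cfg$lof_fraction)
  class <- c(rep("LoF", n_lof), rep("WT-like", n - n_lof))
  true <- ifelse(class == "LoF",
                 rnorm(n, cfg$lof_mean, cfg$lof_sd),
                 rnorm(n, cfg$wt_mean, cfg$wt_sd))

  # layout: technical replicate count and control levels per cell
  n_tech <- sample(seq(cfg$n_tech_range[1], cfg$n_tech_range[2]),
                   cfg$n_bio_total, replace = TRUE)
  cells <- tidyr::expand_grid(bio_rep = seq_len(cfg$n_bio_total),
                              tech_rep = seq_len(max(n_tech))) |>
    dplyr::filter(.data$tech_rep <= n_tech[.data$bio_rep]) |>
    dplyr::mutate(
      ev = runif(dplyr::n(), cfg$ev_level_range[1], cfg$ev_level_range[2]),
      wt = runif(dplyr::n(), cfg$wt_level_range[1], cfg$wt_level_range[2])
    )

  # unbalanced design: each variant in a random subset of biological reps
  assignments <- purrr::map(seq_len(n), function(i) {
    k <- sample(seq(cfg$n_bio_range[1], cfg$n_bio_range[2]), 1)
    sort(sample(seq_len(cfg$n_bio_total), k))
  })

  rows <- purrr::map2(seq_len(n), assignments, function(i, bios) {
    bio_eff <- rnorm(length(bios), 0, cfg$bio_noise_sd)
    purrr::map2(bios, bio_eff, function(b, eff) {
      cell <- cells[cells$bio_rep == b, ]
      tibble::tibble(
        variant_id = ids[i], bio_rep = b, tech_rep = cell$tech_rep,
        activity = true[i] + eff + rnorm(nrow(cell), 0, cfg$tech_noise_sd),
        ev = cell$ev, wt = cell$wt
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  measurements <- rows |>
    dplyr::mutate(raw_activity = .data$ev +
                    (.data$wt - .data$ev) * .data$activity) |>
    dplyr::select("variant_id", "bio_rep", "tech_rep", "raw_activity")

  controls <- cells |>
    dplyr::mutate(KD = .data$ev + (.data$wt - .data$ev) * 0.02) |>
    dplyr::rename(EV = "ev", WT = "wt") |>
    tidyr::pivot_longer(c("EV", "WT", "KD"), names_to = "variant_id",
                        values_to = "raw_activity") |>
    dplyr::select("variant_id", "bio_rep", "tech_rep", "raw_activity")

  replicates <- dplyr::bind_rows(measurements, controls) |>
    dplyr::arrange(.data$bio_rep, .data$tech_rep, .data$variant_id)

  list(
    replicates = replicates,
    truth = tibble::tibble(variant_id = ids, true_activity = true,
                           class = class,
                           true_label = assign_label(true))
  )
}

#' Simulate a predictor over known true activities
#'
#' Produces a [prediction_set()] whose scores are a monotone transform of
#' the true activity plus Gaussian noise. The default link is the identity
#' for activity-orientation predictors and a decreasing logistic centred at
#' the 0.6 threshold for pathogenicity-orientation predictors (scores are
#' clamped to \[0, 1\] after noise in that case). Listed ids are omitted to
#' exercise missing-score imputation.
#'
#' @param true_activity Named numeric vector of true activities.
#' @param orientation `"activity"` or `"pathogenicity_01"`.
#' @param link Strictly monotone transform applied to the true activity;
#'   `NULL` for the orientation default.
#' @param noise_sd Sd of additive Gaussian noise.
#' @param missing_ids Variant ids whose scores are dropped.
#' @param seed Integer seed.
#' @param name,team Passed to [prediction_set()].
#' @return A [prediction_set()].
#' @export
simulate_predictor <- function(true_activity,
                               orientation = c("activity",
                                               "pathogenicity_01"),
                               link = NULL, noise_sd = 0,
                               missing_ids = character(), seed = 1L,
                               name = "simulated", team = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(noise_sd >= 0, !is.null(names(true_activity)))
  if (is.null(link)) {
    link <- if (orientation == "activity") identity
            else function(a) stats::plogis(4 * (0.6 - a))
  }
  set.seed(seed)
  s <- link(true_activity) + rnorm(length(true_activity), 0, noise_sd)
  if (orientation == "pathogenicity_01") s <- pmin(pmax(s, 0), 1)
  s[names(s) %in% missing_ids] <- NA_real_
  prediction_set(name, s, orientation = orientation, team = team)
}

revel_interval_draw <- function(damaging) {
  if (damaging) {
    lo <- c(0.644, 0.773, 0.932)
    hi <- c(0.773, 0.932, 1.0)
  } else {
    lo <- c(0.183, 0.016, 0.003)
    hi <- c(0.290, 0.183, 0.016)
  }
  k <- sample(3, 1)
  runif(1, lo[k], hi[k])
}

#' Simulate a clinical evidence table
#'
#' Fabricates the evidence columns the ACMG point engine consumes, anchored
#' to known functional labels: both assay results equal the label, REVEL-like
#' scores fall in pathogenic-supporting intervals for LoF variants and in
#' benign-supporting intervals for WT-like variants (swapped with
#' probability `error_rate`), gnomAD allele frequencies are absent for most
#' LoF variants and occasionally common for WT-like variants (triggering
#' BS1), and co-located P/LP variants are attached at a configurable rate
#' (with 1-3 entries, so the multi-variant PM5 path is exercised).
#'
#' @param truth Tibble with `variant_id` and a label column (`true_label`
#'   or `label`).
#' @param seed Integer seed.
#' @param error_rate Probability a variant's REVEL score is drawn from the
#'   discordant side.
#' @param lof_absent_prob,wt_absent_prob Probability of absence from gnomAD
#'   per class.
#' @param wt_common_prob Probability a (gnomAD-present) WT-like variant has
#'   allele frequency above 0.001.
#' @param colocated_prob Probability of attaching co-located P/LP variants.
#' @param lof_revel_range,wt_revel_range Optional uniform ranges overriding
#'   the interval mixture (e.g. `c(0.99, 0.99)` for extreme scores).
#' @return Evidence tibble compatible with [classify_variants()].
#' @export
simulate_evidence <- function(truth, seed = 1L, error_rate = 0,
                              lof_absent_prob = 0.8, wt_absent_prob = 0.3,
                              wt_common_prob = 0.15, colocated_prob = 0.15,
                              lof_revel_range = NULL,
                              wt_revel_range = NULL) {
  lab_col <- intersect(c("true_label", "label"), names(truth))[1]
  if (is.na(lab_col)) abort("truth must have a 'true_label' or 'label' column.")
  set.seed(seed)
  purrr::map2(truth$variant_id, truth[[lab_col]], function(id, lab) {
    is_lof <- lab == "LoF"
    damaging <- xor(is_lof, runif(1) < error_rate)
    revel <- if (damaging) {
      if (is.null(lof_revel_range)) revel_interval_draw(TRUE)
      else runif(1, lof_revel_range[1], lof_revel_range[2])
    } else {
      if (is.null(wt_revel_range)) revel_interval_draw(FALSE)
      else runif(1, wt_revel_range[1], wt_revel_range[2])
    }
    af <- if (is_lof) {
      if (runif(1) < lof_absent_prob) NA_real_ else runif(1, 1e-6, 1e-4)
    } else if (runif(1) < wt_absent_prob) {
      NA_real_
    } else if (runif(1) < wt_common_prob) {
      runif(1, 0.002, 0.01)
    } else {
      runif(1, 1e-6, 5e-4)
    }
    colocated <- if (runif(1) < colocated_prob) {
      k <- sample(3, 1)
      paste(sprintf("%s_co%d:%s:%.2f", id, seq_len(k),
                    sample(c("P", "LP"), k, replace = TRUE),
                    runif(k, 0.6, 1)),
            collapse = ";")
    } else {
      NA_character_
    }
    tibble::tibble(variant_id = id, gnomad_af = af,
                   luciferase_result = lab, gel_shift_result = lab,
                   revel = round(revel, 3), colocated = colocated)
  }) |> dplyr::bind_rows()
}
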