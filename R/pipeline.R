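#' Validate pipeline input tables
#'
#' Schema checks for the three tabular inputs: required columns, key
#' uniqueness, enum domains, numeric ranges, and per-replicate control
#' presence. Every violation found is reported; an empty result means the
#' inputs are well formed.
#'
#' @param replicates,variants,evidence Data frames (or TSV paths) for the
#'   raw replicate table, the variant annotation table, and the clinical
#'   evidence table; any subset may be supplied.
#' @return Tibble of violations with columns `table`, `check`, `detail`.
#' @export
validate_inputs <- function(replicates = NULL, variants = NULL,
                            evidence = NULL) {
  v <- list()
  note <- function(table, check, detail) {
    v[[length(v) + 1]] <<- tibble::tibble(table = table, check = check,
                                          detail = detail)
  }
  load_tab <- function(x, reader) if (is.character(x)) reader(x) else x

  if (!is.null(replicates)) {
    rep <- load_tab(replicates, read_replicates)
    need <- c("variant_id", "bio_rep", "tech_rep", "raw_activity")
    miss <- setdiff(need, names(rep))
    if (length(miss) > 0) {
      note("replicates", "columns",
           paste("missing:", paste(miss, collapse = ", ")))
    } else {
      dup <- rep |>
        dplyr::count(.data$variant_id, .data$bio_rep, .data$tech_rep) |>
        dplyr::filter(.data$n > 1)
      if (nrow(dup) > 0) {
        note("replicates", "unique_key",
             paste0(nrow(dup), " duplicated (variant, bio, tech) keys"))
      }
      if (any(rep$raw_activity < 0, na.rm = TRUE)) {
        note("replicates", "range", "negative raw_activity")
      }
      cells <- dplyr::distinct(rep, .data$bio_rep, .data$tech_rep)
      for (ctrl in c("EV", "WT")) {
        have <- rep |>
          dplyr::filter(.data$variant_id == ctrl) |>
          dplyr::distinct(.data$bio_rep, .data$tech_rep)
        absent <- dplyr::anti_join(cells, have,
                                   by = c("bio_rep", "tech_rep"))
        if (nrow(absent) > 0) {
          note("replicates", "controls",
               sprintf("%s control missing in (bio_rep=%s, tech_rep=%s)",
                       ctrl, absent$bio_rep[1], absent$tech_rep[1]))
        }
      }
    }
  }

  if (!is.null(variants)) {
    var <- load_tab(variants, function(p) {
      readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    })
    if (!"variant_id" %in% names(var)) {
      note("variants", "columns", "missing: variant_id")
    } else if (anyDuplicated(var$variant_id)) {
      note("variants", "unique_key", "duplicated variant_id")
    }
    if ("clinvar" %in% names(var)) {
      ok <- c("P", "LP", "P/LP", "VUS", "VUS/LB", "B", "LB", "B/LB", "none")
      bad <- setdiff(unique(var$clinvar[!is.na(var$clinvar)]), ok)
      if (length(bad) > 0) {
        note("variants", "enum",
             paste("invalid clinvar:", paste(bad, collapse = ", ")))
      }
    }
    if ("hgmd" %in% names(var)) {
      bad <- setdiff(unique(var$hgmd[!is.na(var$hgmd)]),
                     c("DM", "DM?", "none"))
      if (length(bad) > 0) {
        note("variants", "enum",
             paste("invalid hgmd:", paste(bad, collapse = ", ")))
      }
    }
    if ("gnomad_af" %in% names(var)) {
      af <- var$gnomad_af
      if (any(!is.na(af) & (af < 0 | af > 1))) {
        note("variants", "range", "gnomad_af outside [0, 1]")
      }
    }
  }

  if (!is.null(evidence)) {
    ev <- load_tab(evidence, read_evidence)
    for (col in c("luciferase_result", "gel_shift_result")) {
      if (col %in% names(ev)) {
        bad <- setdiff(unique(ev[[col]][!is.na(ev[[col]])]),
                       c("LoF", "WT-like"))
        if (length(bad) > 0) {
          note("evidence", "enum",
               paste0("invalid ", col, ": ", paste(bad, collapse = ", ")))
        }
      }
    }
    if ("revel" %in% names(ev)) {
      r <- ev$revel
      if (any(!is.na(r) & (r < 0 | r > 1))) {
        note("evidence", "range", "revel outside [0, 1]")
      }
    }
    if ("gnomad_af" %in% names(ev)) {
      af <- ev$gnomad_af
      if (any(!is.na(af) & (af <= 0 | af > 1))) {
        note("evidence", "range", "gnomad_af outside (0, 1]")
      }
    }
  }

  if (length(v) == 0) {
    tibble::tibble(table = character(), check = character(),
                   detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}

evaluate_prediction_set <- function(p, truth_eval, n_boot, seed) {
  ids <- truth_eval$variant_id
  act <- impute_missing(to_activity_scale(p), ids)$scores[ids]
  pat <- impute_missing(to_pathogenicity_scale(p), ids)$scores[ids]
  boot <- list(
    pearson = bootstrap_metric(pearson, act, truth_eval$mean_r_wt,
                               n_boot = n_boot, seed = seed,
                               metric = "pearson"),
    kendall_tau = bootstrap_metric(kendall_tau, act, truth_eval$mean_r_wt,
                                   n_boot = n_boot, seed = seed,
                                   metric = "kendall_tau"),
    auc = bootstrap_metric(auc, pat, truth_eval$label,
                           n_boot = n_boot, seed = seed, metric = "auc")
  )
  list(boot = boot,
       row = tibble::tibble(
         predictor = p$name, team = p$team %||% NA_character_,
         pearson = boot$pearson$point_estimate,
         kendall_tau = boot$kendall_tau$point_estimate,
         auc = boot$auc$point_estimate
       ))
}

#' Run the full assessment pipeline
#'
#' Orchestrates every stage: replicate normalization and ground-truth
#' construction (or a precomputed ground-truth table), evaluation-set
#' marking, score orientation and imputation, the three metrics with paired
#' bootstrap confidence intervals, predictor ranking, paired win tests of
#' the top-ranked predictor against every other, the Experimental-Max
#' ceiling (when replicates are available), per-variant difficulty
#' profiling of predictors above the AUC selection threshold, and
#' point-based clinical classification (when evidence is available). When
#' `out_dir` is given, every result table is written as TSV together with a
#' JSON run manifest recording the configuration and seeds, so a run is
#' fully reproducible from the manifest.
#'
#' @param replicates Raw replicate tibble or TSV path (optional if
#'   `ground_truth` is given).
#' @param ground_truth Precomputed per-variant table with `variant_id`,
#'   `mean_r_wt`, `label` (used when raw replicates are unavailable, e.g.
#'   the packaged published summary).
#' @param predictions List of [prediction_set()] objects (possibly empty).
#' @param evidence Evidence tibble or TSV path for clinical classification
#'   (optional).
#' @param exclusions Variant ids excluded from the evaluation set.
#' @param tau LoF threshold on mean R-WT activity (default 0.6).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param n_runs Experimental-Max resampled predictors (default 1000).
#' @param seed Integer seed used for all resampling.
#' @param auc_selection_threshold Minimum AUC for inclusion in the
#'   difficulty matrix (default 0.8).
#' @param out_dir Optional output directory.
#' @return List with `ground_truth`, `metrics_summary`, `ranking`,
#'   `win_tests`, `bootstrap` (per-predictor bootstrap results),
#'   `experimental_max`, `difficulty`, `classification`, `config`.
#' @export
run_pipeline <- function(replicates = NULL, ground_truth = NULL,
                         predictions = list(), evidence = NULL,
                         exclusions = character(), tau = 0.6,
                         n_boot = 1000, n_runs = 1000, seed = 1L,
                         auc_selection_threshold = 0.8, out_dir = NULL) {
  if (is.null(replicates) && is.null(ground_truth)) {
    abort("Either replicates or a ground_truth table is required.")
  }
  normalized <- NULL
  if (!is.null(replicates)) {
    if (is.character(replicates)) replicates <- read_replicates(replicates)
    normalized <- normalize_replicates(replicates)
    ground_truth <- aggregate_activity(normalized) |>
      dplyr::mutate(label = assign_label(.data$mean_r_wt, tau = tau))
  }
  ground_truth <- build_evaluation_set(ground_truth, exclusions)
  truth_eval <- dplyr::filter(ground_truth, .data$in_evaluation_set)

  metrics_summary <- NULL
  ranking <- NULL
  win_tests <- NULL
  boots <- list()
  if (length(predictions) > 0) {
    evaluated <- purrr::map(predictions, evaluate_prediction_set,
                            truth_eval = truth_eval, n_boot = n_boot,
                            seed = seed)
    boots <- purrr::map(evaluated, "boot")
    names(boots) <- purrr::map_chr(evaluated, ~ .x$row$predictor)
    point_rows <- purrr::map(evaluated, "row") |> dplyr::bind_rows()
    metrics_summary <- purrr::imap(boots, function(b, pred) {
      purrr::map(b, function(m) {
        tibble::tibble(predictor = pred, metric = m$metric,
                       estimate = m$point_estimate,
                       ci_low = m$ci_low, ci_high = m$ci_high)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    if (nrow(point_rows) >= 2) {
      ranking <- rank_predictors(point_rows)
      top <- ranking$predictor[1]
      others <- setdiff(ranking$predictor, top)
      win_tests <- purrr::map(others, function(o) {
        purrr::map(c("pearson", "kendall_tau", "auc"), function(m) {
          wt <- win_test(boots[[top]][[m]], boots[[o]][[m]])
          tibble::tibble(predictor_a = top, predictor_b = o, metric = m,
                         wins = wt$wins, n = wt$n, p_value = wt$p_value,
                         log10_p = wt$log10_p)
        }) |> dplyr::bind_rows()
      }) |> dplyr::bind_rows()
    }
  } else {
    message("No predictions supplied; predictor metrics skipped.")
  }

  expmax <- NULL
  if (!is.null(normalized)) {
    expmax <- evaluate_experimental_max(normalized, truth_eval,
                                        n_runs = n_runs, seed = seed)
    metrics_summary <- dplyr::bind_rows(
      metrics_summary,
      dplyr::mutate(expmax$summary, predictor = "Experimental-Max") |>
        dplyr::rename(estimate = "mean") |>
        dplyr::select("predictor", "metric", "estimate", "ci_low", "ci_high")
    )
  }

  difficulty <- NULL
  if (length(predictions) > 0) {
    aucs <- purrr::map_dbl(boots, ~ .x$auc$point_estimate)
    selected <- predictions[aucs > auc_selection_threshold]
    if (length(selected) > 0) {
      all_ids <- ground_truth$variant_id
      score_list <- purrr::map(selected, function(p) {
        impute_missing(to_activity_scale(p), all_ids)$scores[all_ids]
      })
      names(score_list) <- purrr::map_chr(selected, "name")
      difficulty <- difficulty_scores(score_list, ground_truth)
    }
  }

  classification <- NULL
  if (!is.null(evidence)) {
    if (is.character(evidence)) evidence <- read_evidence(evidence)
    classification <- classify_variants(evidence)
  }

  config <- list(tau = tau, n_boot = n_boot, n_runs = n_runs, seed = seed,
                 auc_selection_threshold = auc_selection_threshold,
                 exclusions = exclusions,
                 ci_percentiles = c(5, 95))

  result <- list(ground_truth = ground_truth,
                 metrics_summary = metrics_summary, ranking = ranking,
                 win_tests = win_tests, bootstrap = boots,
                 experimental_max = expmax, difficulty = difficulty,
                 classification = classification, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ground_truth(ground_truth, file.path(out_dir, "ground_truth.tsv"))
    if (!is.null(metrics_summary)) {
      readr::write_tsv(metrics_summary,
                       file.path(out_dir, "metrics_summary.tsv"))
    }
    if (!is.null(ranking)) {
      readr::write_tsv(ranking, file.path(out_dir, "ranking.tsv"))
    }
    if (!is.null(win_tests)) {
      readr::write_tsv(win_tests, file.path(out_dir, "win_tests.tsv"))
    }
    if (!is.null(difficulty)) {
      readr::write_tsv(
        tibble::as_tibble(difficulty, rownames = "predictor"),
        file.path(out_dir, "difficulty_matrix.tsv")
      )
    }
    if (!is.null(classification)) {
      readr::write_tsv(classification,
                       file.path(out_dir, "classification.tsv"))
    }
    manifest <- c(config,
                  list(package_version =
                         as.character(utils::packageVersion("stk11vep")),
                       n_predictions = length(predictions)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(result)
}
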