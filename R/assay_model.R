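#' @importFrom rlang .data abort
#' @importFrom stats quantile sd cor rnorm runif pbinom setNames
NULL

# Reserved control identifiers carried in replicate tables: empty vector
# (background), wildtype (positive control) and kinase-dead p.K78I.
CONTROL_IDS <- c(EV = "EV", WT = "WT", KD = "KD")

#' Normalize a raw luciferase reading to relative-wildtype activity
#'
#' Rescales a transfection-adjusted luminescence reading so that the empty
#' vector (EV) background of the same replicate maps to 0 and the wildtype
#' (WT) control maps to 1:
#' \deqn{R\text{-}WT = (Activity_{Var} - Activity_{EV}) /
#'       (Activity_{WT} - Activity_{EV})}
#' Values may be negative (below background) or exceed 1 (above wildtype).
#'
#' @param raw_var Raw activity of the variant (vectorized).
#' @param raw_ev Raw activity of the EV control from the same
#'   biological/technical replicate.
#' @param raw_wt Raw activity of the WT control from the same replicate.
#' @param replicate Optional identifier used in error messages when a
#'   replicate is degenerate.
#' @return Numeric vector of R-WT activities.
#' @export
#' @examples
#' normalize_replicate(30, raw_ev = 10, raw_wt = 50)  # 0.5
normalize_replicate <- function(raw_var, raw_ev, raw_wt, replicate = NULL) {
  bad <- !(raw_wt > raw_ev)
  if (any(bad)) {
    where <- if (is.null(replicate)) which(bad)[1] else replicate[bad][1]
    abort(sprintf(
      "Degenerate replicate %s: WT control (%g) does not exceed EV control (%g).",
      as.character(where), raw_wt[bad][1], raw_ev[bad][1]
    ), class = "stk11vep_degenerate_replicate")
  }
  (raw_var - raw_ev) / (raw_wt - raw_ev)
}

#' Normalize a replicate-level measurement table
#'
#' Applies [normalize_replicate()] to every row of a raw replicate table,
#' using the EV and WT control rows of the same (biological, technical)
#' replicate. Control rows (`EV`, `WT`, `KD`) are normalized too, so the WT
#' row is exactly 1 and the EV row exactly 0 in every replicate; the
#' kinase-dead control is carried through for reporting but plays no role in
#' the normalization itself.
#'
#' @param replicates Tibble with columns `variant_id`, `bio_rep`, `tech_rep`,
#'   `raw_activity`; control rows use the reserved ids `"EV"`, `"WT"`, `"KD"`.
#' @return Tibble with columns `variant_id`, `bio_rep`, `tech_rep`, `r_wt`.
#' @export
normalize_replicates <- function(replicates) {
  required <- c("variant_id", "bio_rep", "tech_rep", "raw_activity")
  missing_cols <- setdiff(required, names(replicates))
  if (length(missing_cols) > 0) {
    abort(paste0("Replicate table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  controls <- replicates |>
    dplyr::filter(.data$variant_id %in% c("EV", "WT")) |>
    tidyr::pivot_wider(names_from = "variant_id",
                       values_from = "raw_activity") |>
    dplyr::rename(raw_ev = "EV", raw_wt = "WT")
  if (!all(c("raw_ev", "raw_wt") %in% names(controls))) {
    abort("Replicate table has no EV/WT control rows.")
  }
  joined <- dplyr::left_join(replicates, controls,
                             by = c("bio_rep", "tech_rep"))
  no_ctrl <- is.na(joined$raw_ev) | is.na(joined$raw_wt)
  if (any(no_ctrl)) {
    r <- joined[no_ctrl, ][1, ]
    abort(sprintf(
      "Replicate (bio_rep=%s, tech_rep=%s) lacks an EV or WT control row.",
      r$bio_rep, r$tech_rep
    ), class = "stk11vep_missing_control")
  }
  joined |>
    dplyr::mutate(r_wt = normalize_replicate(
      .data$raw_activity, .data$raw_ev, .data$raw_wt,
      replicate = paste0("(bio_rep=", .data$bio_rep,
                         ", tech_rep=", .data$tech_rep, ")")
    )) |>
    dplyr::select("variant_id", "bio_rep", "tech_rep", "r_wt")
}

#' Aggregate normalized activity across replicates
#'
#' Per-variant unweighted arithmetic mean over all (biological, technical)
#' measurements, with 25th/75th percentiles (linear interpolation between
#' order statistics) of the same values. Variants measured in only a subset
#' of biological replicates are aggregated over whatever measurements exist.
#'
#' @param normalized Tibble from [normalize_replicates()]; control rows
#'   (`EV`, `WT`, `KD`) are dropped before aggregation.
#' @return Tibble with columns `variant_id`, `mean_r_wt`, `q25`, `q75`,
#'   `n_measurements`.
#' @export
aggregate_activity <- function(normalized) {
  dat <- dplyr::filter(normalized, !.data$variant_id %in% CONTROL_IDS)
  if (nrow(dat) == 0) {
    abort("No variant measurements to aggregate (only controls present).",
          class = "stk11vep_missing_data")
  }
  if (anyNA(dat$r_wt)) {
    abort("Normalized activities contain NA.", class = "stk11vep_missing_data")
  }
  dat |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      mean_r_wt = mean(.data$r_wt),
      q25 = quantile(.data$r_wt, 0.25, names = FALSE),
      q75 = quantile(.data$r_wt, 0.75, names = FALSE),
      n_measurements = dplyr::n(),
      .groups = "drop"
    )
}

#' Assign the LoF / WT-like functional label
#'
#' A variant is loss-of-function when its mean R-WT activity is strictly
#' below the threshold `tau`, and wildtype-like otherwise (a mean exactly at
#' the threshold is WT-like).
#'
#' @param mean_r_wt Numeric vector of replicate-averaged R-WT activities.
#' @param tau Classification threshold (default 0.6).
#' @return Character vector of `"LoF"` / `"WT-like"`.
#' @export
#' @examples
#' assign_label(c(0.56, 0.69, 0.6))  # LoF, WT-like, WT-like
assign_label <- function(mean_r_wt, tau = 0.6) {
  if (anyNA(mean_r_wt) || any(!is.finite(mean_r_wt))) {
    abort("mean_r_wt must be finite.")
  }
  ifelse(mean_r_wt < tau, "LoF", "WT-like")
}

#' Build per-variant ground truth from raw replicates
#'
#' Convenience wrapper: normalize, aggregate, and label.
#'
#' @inheritParams normalize_replicates
#' @inheritParams assign_label
#' @return Tibble with columns `variant_id`, `mean_r_wt`, `q25`, `q75`,
#'   `n_measurements`, `label`.
#' @export
build_ground_truth <- function(replicates, tau = 0.6) {
  replicates |>
    normalize_replicates() |>
    aggregate_activity() |>
    dplyr::mutate(label = assign_label(.data$mean_r_wt, tau = tau))
}

#' Mark the evaluation subset of a ground-truth table
#'
#' Variants with a prior non-conflicting clinical assertion are excluded from
#' predictor evaluation (they may have been used to train predictors). The
#' returned table carries an `in_evaluation_set` flag; excluded variants are
#' retained in the table because downstream difficulty profiling uses all
#' variants.
#'
#' @param ground_truth Tibble with a `variant_id` column.
#' @param exclusions Character vector of variant ids to exclude; every id
#'   must be present in `ground_truth`.
#' @return `ground_truth` with an added/overwritten logical
#'   `in_evaluation_set` column.
#' @export
build_evaluation_set <- function(ground_truth, exclusions = character()) {
  unknown <- setdiff(exclusions, ground_truth$variant_id)
  if (length(unknown) > 0) {
    abort(paste0("Unknown variant id(s) in exclusions: ",
                 paste(unknown, collapse = ", ")),
          class = "stk11vep_unknown_variant")
  }
  dplyr::mutate(ground_truth,
                in_evaluation_set = !.data$variant_id %in% exclusions)
}

#' Read a raw replicate table from TSV
#'
#' @param path Path to a TSV with columns `variant_id`, `bio_rep`,
#'   `tech_rep`, `raw_activity`.
#' @return Tibble.
#' @export
read_replicates <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    variant_id = "c", bio_rep = "i", tech_rep = "i", raw_activity = "d"
  ), progress = FALSE)
}

#' Write a ground-truth table to TSV
#'
#' @param ground_truth Tibble as returned by [build_ground_truth()] (with or
#'   without the evaluation flag).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  readr::write_tsv(ground_truth, path)
  invisible(path)
}
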