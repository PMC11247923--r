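#' Create a predictor score set
#'
#' A predictor's scores with a declared orientation. Orientation is never
#' inferred from the data:
#' * `"activity"` — scores on the assay's own scale: 0 is no activity, 1 is
#'   wildtype, values above 1 are super-wildtype (participant submissions).
#' * `"pathogenicity_01"` — probability-like scores in \[0, 1\], higher =
#'   more damaging (public tools such as REVEL).
#'
#' @param name Predictor name.
#' @param scores Named numeric vector (names = variant ids). `NA` entries are
#'   treated as missing.
#' @param orientation `"activity"` or `"pathogenicity_01"`.
#' @param team Optional team name (used for within-team ranking).
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(name, scores,
                           orientation = c("activity", "pathogenicity_01"),
                           team = NULL) {
  if (length(orientation) != 1 ||
      !orientation %in% c("activity", "pathogenicity_01")) {
    abort("Orientation must be declared as 'activity' or 'pathogenicity_01'.",
          class = "stk11vep_configuration_error")
  }
  if (is.null(names(scores)) || any(names(scores) == "")) {
    abort("Scores must be a named numeric vector (names = variant ids).")
  }
  ok <- !is.na(scores)
  if (orientation == "pathogenicity_01" &&
      any(scores[ok] < 0 | scores[ok] > 1)) {
    abort("pathogenicity_01 scores must lie in [0, 1].",
          class = "stk11vep_validation_error")
  }
  structure(
    list(name = name, team = team, orientation = orientation,
         scores = scores),
    class = "prediction_set"
  )
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %s (%s)%s: %d scores, %d missing\n",
              x$name, x$orientation,
              if (is.null(x$team)) "" else paste0(" team=", x$team),
              sum(!is.na(x$scores)), sum(is.na(x$scores))))
  invisible(x)
}

oriented_scores <- function(scores, scale, imputed = character(),
                            predictor = NULL) {
  structure(list(scores = scores, scale = scale, imputed = imputed,
                 predictor = predictor),
            class = "oriented_scores")
}

#' @export
print.oriented_scores <- function(x, ...) {
  cat(sprintf("<oriented_scores> %s scale, %d variants (%d imputed)\n",
              x$scale, sum(!is.na(x$scores)), length(x$imputed)))
  invisible(x)
}

#' Orient predictor scores to the activity scale
#'
#' Correlation metrics are computed against R-WT activity, so
#' pathogenicity-style scores \eqn{\hat y} are mapped to \eqn{1 - \hat y};
#' activity-orientation scores pass through unaltered.
#'
#' @param p A [prediction_set()].
#' @return An `oriented_scores` object on the activity scale.
#' @export
to_activity_scale <- function(p) {
  stopifnot(inherits(p, "prediction_set"))
  s <- if (p$orientation == "activity") p$scores else 1 - p$scores
  oriented_scores(s, scale = "activity", predictor = p$name)
}

#' Orient predictor scores to the pathogenicity scale
#'
#' AUC treats LoF as the positive class, so a higher score must mean more
#' damaging: activity-orientation scores are negated (multiplied by -1);
#' pathogenicity scores pass through unaltered.
#'
#' @inheritParams to_activity_scale
#' @return An `oriented_scores` object on the pathogenicity scale.
#' @export
to_pathogenicity_scale <- function(p) {
  stopifnot(inherits(p, "prediction_set"))
  s <- if (p$orientation == "activity") -p$scores else p$scores
  oriented_scores(s, scale = "pathogenicity", predictor = p$name)
}

#' Impute missing predictions with the evaluation-set mean
#'
#' Each missing prediction on an evaluation-set variant is replaced by the
#' arithmetic mean of the predictor's non-missing scores over the evaluation
#' set, so every predictor can be compared on the identical variant set. The
#' ids that received an imputed value are recorded. Variants outside the
#' evaluation set are left untouched.
#'
#' @param os An `oriented_scores` object.
#' @param eval_ids Character vector of evaluation-set variant ids.
#' @return An `oriented_scores` object defined on every id in `eval_ids`.
#' @export
impute_missing <- function(os, eval_ids) {
  stopifnot(inherits(os, "oriented_scores"))
  s <- os$scores[eval_ids]
  names(s) <- eval_ids
  missing_ids <- eval_ids[is.na(s)]
  if (length(missing_ids) == length(eval_ids)) {
    abort(sprintf("Predictor %s has no scores on the evaluation set.",
                  os$predictor %||% "<unnamed>"),
          class = "stk11vep_unusable_predictor")
  }
  s[missing_ids] <- mean(s[!is.na(s)])
  out <- os$scores
  out[missing_ids] <- s[missing_ids]
  # ensure all eval ids present even if absent from the original vector
  absent <- setdiff(eval_ids, names(out))
  if (length(absent) > 0) out <- c(out, s[absent])
  oriented_scores(out, scale = os$scale,
                  imputed = union(os$imputed, missing_ids),
                  predictor = os$predictor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a predictor score table from TSV
#'
#' @param path TSV with columns `variant_id`, `score`.
#' @param name Predictor name (defaults to the file name).
#' @inheritParams prediction_set
#' @return A [prediction_set()].
#' @export
read_prediction_set <- function(path, orientation, team = NULL,
                                name = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    variant_id = "c", score = "d"
  ), progress = FALSE)
  prediction_set(
    name = name %||% sub("\\.tsv$", "", basename(path)),
    scores = setNames(tab$score, tab$variant_id),
    orientation = orientation, team = team
  )
}
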