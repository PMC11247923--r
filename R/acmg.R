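applied_code <- function(code, points) {
  tibble::tibble(code = code, points = as.integer(points))
}

no_code <- function() {
  tibble::tibble(code = character(), points = integer())
}

#' Population-frequency evidence (PM2 / BS1)
#'
#' Variants completely absent from gnomAD receive PM2 at supporting strength
#' (+1 point, per the updated guideline downgrade from moderate). An allele
#' frequency strictly above 0.001 — implausibly common for a dominant
#' disease allele — receives BS1 at strong strength (-4). Frequencies in
#' between (present but rare) are indeterminate: no code.
#'
#' @param gnomad_af Allele frequency in (0, 1\], or `NA` when the variant is
#'   absent from gnomAD.
#' @return Tibble of applied codes (0 or 1 row).
#' @export
#' @examples
#' score_population(NA)       # PM2 (+1)
#' score_population(0.0051)   # BS1 (-4)
#' score_population(3.16e-6)  # no code
score_population <- function(gnomad_af) {
  if (is.na(gnomad_af)) return(applied_code("PM2", 1L))
  if (gnomad_af <= 0 || gnomad_af > 1) {
    abort("gnomad_af must be in (0, 1] or NA (absent).",
          class = "stk11vep_validation_error")
  }
  if (gnomad_af > 0.001) return(applied_code("BS1", -4L))
  no_code()
}

#' Functional-assay evidence (PS3 / BS3)
#'
#' Each of the two assays contributes one supporting-level code: a LoF
#' result gives PS3 (+1), a WT-like result BS3 (-1). Concordant assays
#' therefore sum to +2 or -2; the single discordant variant nets 0.
#'
#' @param luciferase_result,gel_shift_result `"LoF"` or `"WT-like"`.
#' @return Tibble of two applied codes (one per assay).
#' @export
score_functional <- function(luciferase_result, gel_shift_result) {
  one <- function(res, assay) {
    if (is.na(res) || !res %in% c("LoF", "WT-like")) {
      abort(sprintf("Missing or invalid %s assay result.", assay),
            class = "stk11vep_validation_error")
    }
    if (res == "LoF") applied_code("PS3", 1L) else applied_code("BS3", -1L)
  }
  dplyr::bind_rows(one(luciferase_result, "luciferase"),
                   one(gel_shift_result, "gel-shift"))
}

# Calibrated REVEL evidence-strength intervals (points; interval bounds as
# printed: PP3 lower bounds closed, BP4 upper bounds closed).
pp3_points <- function(r) {
  if (r >= 0.932 && r <= 1) 4L
  else if (r >= 0.773) 2L
  else if (r >= 0.644) 1L
  else NA_integer_
}
bp4_points <- function(r) {
  if (r > 0.183 && r <= 0.290) -1L
  else if (r > 0.016 && r <= 0.183) -2L
  else if (r > 0.003 && r <= 0.016) -4L
  else NA_integer_
}

#' Computational evidence from a calibrated REVEL score (PP3 / BP4)
#'
#' Maps a REVEL score to an evidence code via the calibrated strength
#' intervals: PP3 at +1/+2/+4 for scores in \[0.644, 0.773), \[0.773,
#' 0.932), \[0.932, 1\]; BP4 at -1/-2/-4 for scores in (0.183, 0.290\],
#' (0.016, 0.183\], (0.003, 0.016\]. Scores of 0.003 or below, scores in the
#' indeterminate gap (0.290, 0.644), and missing scores (e.g. indels REVEL
#' does not cover) yield no code.
#'
#' @param revel REVEL score in \[0, 1\], or `NA`.
#' @return Tibble of applied codes (0 or 1 row).
#' @export
#' @examples
#' score_computational(0.932)  # PP3 (+4); lower bound inclusive
#' score_computational(0.424)  # no code
#' score_computational(0.102)  # BP4 (-2)
score_computational <- function(revel) {
  if (is.na(revel)) return(no_code())
  if (revel < 0 || revel > 1) {
    abort("REVEL score must be in [0, 1].",
          class = "stk11vep_validation_error")
  }
  p <- pp3_points(revel)
  if (!is.na(p)) return(applied_code("PP3", p))
  b <- bp4_points(revel)
  if (!is.na(b)) return(applied_code("BP4", b))
  no_code()
}

#' Co-located pathogenic variant evidence (PM5)
#'
#' A known P or LP missense variant at the same residue supports
#' pathogenicity when the tested variant is predicted at least as damaging:
#' a co-located variant *qualifies* when its REVEL score is less than or
#' equal to the tested variant's REVEL score rounded to 2 decimal places.
#' With at least one qualifying variant, PM5 is applied with 2 points if any
#' qualifying variant is P (1 point if only LP variants qualify), plus 1
#' point for each additional qualifying variant.
#'
#' @param revel_tested REVEL score of the tested variant (required when
#'   `colocated` is non-empty).
#' @param colocated Tibble/data frame with columns `classification` (`"P"`
#'   or `"LP"`) and `revel`; possibly zero rows.
#' @return Tibble of applied codes (0 or 1 row).
#' @export
#' @examples
#' score_pm5(0.936, data.frame(classification = "P", revel = 0.94))  # PM5 (+2)
score_pm5 <- function(revel_tested, colocated) {
  if (is.null(colocated) || nrow(colocated) == 0) return(no_code())
  if (!all(colocated$classification %in% c("P", "LP"))) {
    abort("Co-located classifications must be P or LP.",
          class = "stk11vep_validation_error")
  }
  if (is.na(revel_tested)) {
    abort("A REVEL score for the tested variant is required for PM5.",
          class = "stk11vep_validation_error")
  }
  r <- round(revel_tested, 2)
  qual <- colocated[colocated$revel <= r, , drop = FALSE]
  k <- nrow(qual)
  if (k == 0) return(no_code())
  base <- if (any(qual$classification == "P")) 2L else 1L
  applied_code("PM5", base + (k - 1L))
}

#' Map a point total to a clinical category
#'
#' The integer point ranges partition the total-score line: pathogenic at
#' >= 10, likely pathogenic in \[6, 9\], VUS in \[0, 5\] (subdivided low
#' \[0, 1\], mid \[2, 3\], high \[4, 5\]), likely benign in \[-6, -1\],
#' benign at <= -7.
#'
#' @param total Integer point total.
#' @return List with `category` (`"P"`, `"LP"`, `"VUS"`, `"LB"`, `"B"`) and
#'   `vus_sub` (`"low"`, `"mid"`, `"high"`, or `NA` outside VUS).
#' @export
classify_points <- function(total) {
  stopifnot(length(total) == 1, !is.na(total))
  if (total >= 10) return(list(category = "P", vus_sub = NA_character_))
  if (total >= 6) return(list(category = "LP", vus_sub = NA_character_))
  if (total >= 0) {
    sub <- if (total <= 1) "low" else if (total <= 3) "mid" else "high"
    return(list(category = "VUS", vus_sub = sub))
  }
  if (total >= -6) return(list(category = "LB", vus_sub = NA_character_))
  list(category = "B", vus_sub = NA_character_)
}

#' Parse a co-located variant field
#'
#' Decodes semicolon-separated `ID:CLASS:REVEL` triplets, e.g.
#' `"W308C:LP:0.73;W308L:LP:0.84"`.
#'
#' @param x Single string (possibly `NA` or empty).
#' @return Tibble with columns `variant_id`, `classification`, `revel`.
#' @export
parse_colocated <- function(x) {
  empty <- tibble::tibble(variant_id = character(),
                          classification = character(), revel = numeric())
  if (is.na(x) || !nzchar(x)) return(empty)
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3
  if (any(bad)) {
    abort("Co-located entries must be 'ID:CLASS:REVEL' triplets.",
          class = "stk11vep_validation_error")
  }
  tibble::tibble(
    variant_id = vapply(parts, `[`, character(1), 1),
    classification = vapply(parts, `[`, character(1), 2),
    revel = as.numeric(vapply(parts, `[`, character(1), 3))
  )
}

#' Classify one variant from its evidence
#'
#' Applies all four evidence dimensions — population frequency (PM2/BS1),
#' functional assays (PS3/BS3), computational (PP3/BP4) and co-located
#' pathogenic variants (PM5) — sums the points, and maps the total to a
#' clinical category.
#'
#' @param variant_id Variant identifier.
#' @param gnomad_af Allele frequency or `NA` (absent from gnomAD).
#' @param luciferase_result,gel_shift_result `"LoF"` or `"WT-like"`.
#' @param revel REVEL score or `NA`.
#' @param colocated Tibble of co-located P/LP variants (see [score_pm5()]),
#'   or a `"ID:CLASS:REVEL;..."` string, or `NULL`.
#' @return List with `variant_id`, `applied` (tibble of codes and points),
#'   `total`, `category`, `vus_sub`.
#' @export
classify_variant <- function(variant_id, gnomad_af, luciferase_result,
                             gel_shift_result, revel, colocated = NULL) {
  if (is.character(colocated) && length(colocated) == 1) {
    colocated <- parse_colocated(colocated)
  }
  applied <- dplyr::bind_rows(
    score_population(gnomad_af),
    score_functional(luciferase_result, gel_shift_result),
    score_computational(revel),
    score_pm5(revel, colocated)
  )
  total <- sum(applied$points)
  cls <- classify_points(total)
  list(variant_id = variant_id, applied = applied, total = as.integer(total),
       category = cls$category, vus_sub = cls$vus_sub)
}

#' Classify a table of variants
#'
#' Runs [classify_variant()] on every row of an evidence table.
#'
#' @param evidence Tibble with columns `variant_id`, `gnomad_af`,
#'   `luciferase_result`, `gel_shift_result`, `revel`, `colocated` (triplet
#'   string or `NA`), e.g. from [stk11_evidence()] or [read_evidence()].
#' @return Tibble with one row per variant: the net points per evidence
#'   dimension (`population_points`, `functional_points`,
#'   `computational_points`, `pm5_points`), the applied code labels, the
#'   `total`, and the `category`/`vus_sub` call.
#' @export
classify_variants <- function(evidence) {
  purrr::pmap(
    evidence[c("variant_id", "gnomad_af", "luciferase_result",
               "gel_shift_result", "revel", "colocated")],
    function(variant_id, gnomad_af, luciferase_result, gel_shift_result,
             revel, colocated) {
      res <- classify_variant(variant_id, gnomad_af, luciferase_result,
                              gel_shift_result, revel, colocated)
      a <- res$applied
      pick <- function(codes) sum(a$points[a$code %in% codes])
      lab <- function(codes) {
        hit <- intersect(codes, a$code)
        if (length(hit) == 0) NA_character_ else paste(unique(hit),
                                                       collapse = "+")
      }
      tibble::tibble(
        variant_id = res$variant_id,
        population_code = lab(c("PM2", "BS1")),
        population_points = pick(c("PM2", "BS1")),
        functional_code = lab(c("PS3", "BS3")),
        functional_points = pick(c("PS3", "BS3")),
        computational_code = lab(c("PP3", "BP4")),
        computational_points = pick(c("PP3", "BP4")),
        pm5_points = pick("PM5"),
        total = res$total,
        category = res$category,
        vus_sub = res$vus_sub
      )
    }
  ) |>
    dplyr::bind_rows()
}

#' Read an evidence table from TSV
#'
#' @param path TSV with columns `variant_id`, `gnomad_af` (blank = absent),
#'   `luciferase_result`, `gel_shift_result`, `revel` (blank = absent),
#'   `colocated` (semicolon-separated `ID:CLASS:REVEL` triplets).
#' @return Tibble.
#' @export
read_evidence <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    variant_id = "c", gnomad_af = "d", luciferase_result = "c",
    gel_shift_result = "c", revel = "d", colocated = "c", .default = "c"
  ), progress = FALSE)
}
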