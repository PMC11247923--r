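#' Packaged STK11 challenge variant table
#'
#' The 28 STK11 variants identified in primary non-small cell lung cancer
#' biopsies, with their clinical annotations (ClinVar, HGMD), gnomAD allele
#' counts and frequencies, replicate-averaged relative-wildtype (R-WT)
#' luciferase activity with interquartile bounds, the functional labels from
#' both assays, and the evaluation-set exclusion flag for variants with a
#' prior non-conflicting pathogenic/benign assertion.
#'
#' @return A tibble with one row per variant. `mean_r_wt`, `q25`, `q75` are
#'   the replicate-aggregated R-WT activity summaries; `label` is the
#'   luciferase LoF/WT-like call at the 0.6 threshold; `gel_shift_label` is
#'   the binary autophosphorylation (gel-shift) call; `gnomad_ac`/`gnomad_af`
#'   are `NA` for variants absent from gnomAD.
#' @export
#' @examples
#' v <- stk11_variants()
#' table(v$label)
stk11_variants <- function() {
  path <- system.file("extdata", "stk11_variants.tsv", package = "stk11vep",
                      mustWork = TRUE)
  readr::read_tsv(
    path,
    col_types = readr::cols(
      variant_id = "c", genomic_hgvs = "c", variant_class = "c",
      clinvar = "c", hgmd = "c", gnomad_ac = "i", gnomad_af = "d",
      mean_r_wt = "d", q25 = "d", q75 = "d",
      label = "c", gel_shift_label = "c", gel_shift_note = "c",
      excluded_from_evaluation = "l"
    ),
    progress = FALSE
  )
}

#' Packaged STK11 clinical evidence table
#'
#' The per-variant evidence used by the point-based ACMG/AMP classification
#' engine: gnomAD allele frequency (`NA` means absent from gnomAD), the two
#' functional assay results, the REVEL score, and co-located P/LP ClinVar
#' variants at the same residue encoded as semicolon-separated
#' `ID:CLASS:REVEL` triplets. `printed_total` and `printed_category` carry the
#' published classification for regression testing; `clinvar_definitive`
#' flags the four variants that already held a non-conflicting P/LP or B/LB
#' ClinVar assertion.
#'
#' @return A tibble with one row per variant.
#' @export
#' @examples
#' e <- stk11_evidence()
#' sum(!e$clinvar_definitive)
stk11_evidence <- function() {
  path <- system.file("extdata", "stk11_evidence.tsv", package = "stk11vep",
                      mustWork = TRUE)
  readr::read_tsv(
    path,
    col_types = readr::cols(
      variant_id = "c", gnomad_af = "d",
      luciferase_result = "c", gel_shift_result = "c",
      revel = "d", colocated = "c", clinvar_definitive = "l",
      printed_total = "i", printed_category = "c"
    ),
    progress = FALSE
  )
}

#' Published predictor performance summary
#'
#' Point estimates and 90% bootstrap confidence bounds for Pearson
#' correlation, Kendall's tau and AUC of the best predictor per participating
#' team, the publicly available baseline tools, and the Experimental-Max
#' replicate-resampling ceiling, all evaluated on the 22-variant set.
#'
#' @return A tibble with columns `predictor`, `group`
#'   (participant/baseline/ceiling) and per-metric estimate/lo/hi columns.
#' @export
stk11_predictor_metrics <- function() {
  path <- system.file("extdata", "stk11_predictor_metrics.tsv",
                      package = "stk11vep", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    predictor = "c", group = "c", .default = "d"
  ), progress = FALSE)
}
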