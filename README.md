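# stk11vep

Benchmarking variant effect predictors against a functional assay of STK11
kinase activity, and turning the assay results into clinical variant
classifications.

STK11 (LKB1) is a tumor-suppressor kinase: germline variants cause
Peutz–Jeghers syndrome and somatic variants are frequent in non-small cell
lung cancer. For 28 rare STK11 variants found in lung-cancer biopsies, a
p53-dependent luciferase reporter assay measured each variant's activity in
nested biological × technical replicates. This package implements the full
assessment pipeline around such data, for assessors and method developers
who want to score computational predictors against a replicated functional
assay:

- **Assay model** — raw luminescence is normalized per replicate to
  relative-wildtype activity,
  `R-WT = (Activity_Var − Activity_EV) / (Activity_WT − Activity_EV)`,
  so the empty-vector background maps to 0 and wildtype to 1; replicate
  values are averaged into a per-variant ground truth, and variants with
  mean R-WT < 0.6 are labeled loss-of-function (LoF), the rest
  wildtype-like (WT-like).
- **Predictor evaluation** — Pearson correlation and Kendall's tau-b
  against the continuous activity, and Mann–Whitney AUC (LoF = positive
  class) for the binary task, with declared score orientations
  (activity-scale submissions pass through; pathogenicity-scale tools are
  transformed `1 − ŷ` for correlations and negated activities for AUC) and
  mean-imputation of missing predictions over the evaluation set.
- **Uncertainty and comparison** — 90% percentile confidence intervals
  from 1000 variant bootstrap resamples, paired across predictors so two
  predictors can be compared by a one-sided exact binomial *win test* on
  the shared resamples; predictors are ranked by their average rank over
  the three metrics.
- **Experimental-Max** — a stochastic pseudo-predictor that predicts each
  variant with one randomly sampled replicate measurement (biological
  replicate first, then technical). Its average performance over 1000
  resampled predictors quantifies assay consistency and is a ceiling for
  what any predictor can achieve against this assay.
- **Difficulty profiling** — per-variant FPR (for LoF variants) / FNR
  (for WT-like variants) at the threshold placed on each predictor's value
  at that variant, across predictors with AUC > 0.8.
- **ACMG/AMP point engine** — functional (PS3/BS3), population (PM2/BS1),
  computational (PP3/BP4 from calibrated REVEL intervals) and co-located
  pathogenic variant (PM5) evidence combined as integer points
  (supporting/moderate/strong/very strong = ±1/±2/±4/±8), with categories
  P (≥ 10), LP (6–9), VUS (0–5, split low/mid/high), LB (−6…−1), B (≤ −7).
- **Synthetic data** — a generator that emulates the nested replicate
  design (17 biological replicates, 2–3 technical replicates, each variant
  in a 3–6 replicate subset) with two-level noise, plus simulated
  predictors and evidence tables, so every stage is testable end to end.

The published per-variant summary (activities, labels, annotations),
evidence table and predictor performance table ship as plain-TSV fixtures
(`stk11_variants()`, `stk11_evidence()`, `stk11_predictor_metrics()`).

## Worked example

Evaluate REVEL against the packaged assay ground truth and classify the
variants clinically:

```r
library(stk11vep)

v <- stk11_variants()
e <- stk11_evidence()
revel <- prediction_set("REVEL", setNames(e$revel, e$variant_id),
                        orientation = "pathogenicity_01")

res <- run_pipeline(
  ground_truth = v,
  predictions  = list(revel),
  evidence     = e,
  exclusions   = v$variant_id[v$excluded_from_evaluation],
  seed         = 17, n_boot = 1000
)

res$metrics_summary
#> # A tibble: 3 × 5
#>   predictor metric      estimate ci_low ci_high
#>   <chr>     <chr>          <dbl>  <dbl>   <dbl>
#> 1 REVEL     pearson        0.825  0.707   0.913
#> 2 REVEL     kendall_tau    0.659  0.497   0.818
#> 3 REVEL     auc            0.95   0.863   1

table(res$classification$category)
#>
#>  B LB LP VUS
#>  1 10  9  8
```

The three REVEL rows say: on the 22-variant evaluation set (six variants
with settled clinical classifications are held out, and the one indel
REVEL does not score is mean-imputed), REVEL's `1 − ŷ` correlates 0.825
with measured R-WT activity, agrees with the activity ordering at tau-b
0.659, and separates LoF from WT-like variants with AUC 0.950 — the
bracketed values are 90% bootstrap confidence bounds. The classification
table combines both assays with population, computational and co-located
evidence: across all 28 variants it yields 9 likely pathogenic and 10
likely benign calls (plus 1 benign, and 8 variants staying VUS), of which
16 are *new* actionable classifications for variants that previously
lacked a definitive assertion.

The win test compares two predictors on their shared bootstrap resamples:

```r
win_test(res$bootstrap$REVEL$auc, res$bootstrap$REVEL$auc)$p_value
#> [1] 1
```

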