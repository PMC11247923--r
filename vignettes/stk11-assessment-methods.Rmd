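---
title: "Methods: assessing variant effect predictors against a replicated STK11 activity assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assessing variant effect predictors against a replicated STK11 activity assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stk11vep)
```

This vignette documents the statistical model behind `stk11vep`, the
choices made where the design was genuinely open, and what the synthetic
data generator does and does not emulate.

## The assay model

A cell-based luciferase reporter measures how an STK11 variant affects
p53's transcriptional activity. Every (biological, technical) replicate
cell carries its own empty-vector (EV) background and wildtype (WT)
positive control, plus a kinase-dead control (p.K78I). Raw,
transfection-adjusted luminescence is normalized within its own cell:

$$R\text{-}WT_{var} = \frac{Activity_{var} - Activity_{EV}}
                           {Activity_{WT} - Activity_{EV}}$$

so EV maps to exactly 0 and WT to exactly 1 in every cell, and the result
is invariant to any affine rescaling of the raw luminescence scale.
Values below 0 (below background) and above 1 (super-wildtype) are
legitimate and retained. A cell whose WT reading does not exceed its EV
reading is degenerate and rejected with an error naming the replicate —
the quantity is undefined there, and silently dropping readings would
bias the per-variant mean.

The per-variant ground truth is the unweighted ("flat") arithmetic mean
over all of a variant's (biological, technical) measurements. For
variants measured in only a subset of biological replicates, the mean is
taken over whatever measurements exist, with no reweighting. A mean of
per-biological-replicate means would be an equally defensible convention
(the two coincide for balanced designs); the flat mean is used because
the averaging is defined over *all* replicates, and the choice is
recorded here rather than hidden. The 25th/75th percentiles reported
alongside use linear interpolation between order statistics
(`quantile(type = 7)`); labels depend only on the mean, so any consistent
percentile convention would leave every downstream result unchanged.

A variant is **LoF** when its mean R-WT activity is strictly below
$\tau = 0.6$, **WT-like** otherwise; a mean exactly at the threshold is
WT-like. On the packaged 28-variant table this yields 15 LoF and 13
WT-like. Six variants with settled, non-conflicting clinical assertions
are excluded from the predictor evaluation set (22 variants remain),
because they may have been part of predictors' training data; a reduced
21-variant missense-only set additionally drops the single inframe
deletion. Excluded variants still participate in difficulty profiling
and classification.

## Score orientation and imputation

Two orientations are supported and must be declared, never inferred:
activity-scale submissions (0 = dead, 1 = wildtype) and
pathogenicity-style tools with scores in $[0, 1]$, higher = damaging.
For correlations against activity, pathogenicity scores become
$1 - \hat y$; for AUC (LoF is the positive class) activity scores are
negated. The two transforms induce exactly opposite rankings, so
rank-based results are consistent across scales by construction.

A predictor that does not score some evaluation-set variants has each
missing value replaced by the mean of its non-missing scores *over the
evaluation set*, and the imputed ids are recorded. Restricting the mean
to the evaluation set (rather than all 28 variants) matches the purpose
of the imputation — comparing all tools on the same variant set — and is
applied per orientation scale, which is equivalent under the affine and
negation transforms above. Imputation creates ties; every metric
downstream is therefore tie-aware.

## Metrics

* **Pearson correlation** and **Kendall's tau-b** (tie-corrected; plain
  tau-a would be ill-defined after imputation) for the regression task.
* **Mann–Whitney AUC** for classification: over all (LoF, WT-like)
  pairs, the fraction where the LoF variant gets the higher
  pathogenicity score, ties credited 0.5, computed via the midrank
  identity. The ROC sweep moves all equal-scored variants together, so
  tied scores produce diagonal segments, and the trapezoidal area under
  the returned curve equals the Mann–Whitney value exactly.

## Uncertainty, ranking and win tests

Each metric's 90% confidence interval is the 5th/95th percentile of 1000
bootstrap estimates obtained by resampling evaluation-set variants with
replacement; a Gaussian 95% half-width, $1.96 \times sd$ of the same
estimates, is also available. The resample index sets depend only on the
evaluation-set size, the labels and the seed — not on any predictor's
scores — so all predictors share identical resamples and their bootstrap
estimates are *paired*. A resample containing a single class (AUC
undefined) is redrawn; at the packaged 10/12 class split this affects a
negligible fraction of draws and keeps exactly 1000 valid estimates per
metric. Dropping such resamples instead would be equally defensible but
would leave metrics with unequal effective resample counts.

Predictors are ranked per metric (higher is better, average ranks on
ties) and ordered by the mean of their three ranks; team representatives
are chosen by the same procedure within each team before re-ranking
across teams. The ranking is invariant to strictly monotone rescaling of
any one metric's values.

The **win test** compares predictors A and B by counting resamples where
A's estimate strictly exceeds B's; ties count against A (conservative —
the convention matters only when estimates coincide exactly). The
p-value is the exact upper tail $P[X \ge wins]$, $X \sim
\text{Binomial}(n, 1/2)$, evaluated in log space so extreme significance
levels are reported as exact log10 tails rather than "below $10^{-k}$"
bounds. For reference, the tails at 629, 687 and 838 wins out of 1000
are $10^{-15.82}$, $10^{-32.43}$ and $10^{-110.02}$.

## Experimental-Max

The replicate structure bounds achievable performance: no predictor can
be expected to match the assay average better than the assay's own
replicates do. Experimental-Max predicts each variant by sampling one of
its biological replicates uniformly, then one technical measurement
within it — a two-stage scheme that weights biological variability the
way the experiment nests it, rather than flat sampling over cells.
Sampling is independent across variants. The performance of 1000 such
resampled predictors (means and 5th/95th percentile bands, the same
convention as the bootstrap CIs) summarizes assay consistency: Pearson
and tau measure consistency on the continuous activity, AUC on the
LoF/WT-like separation.

One master seed drives sequential draws across the 1000 runs; results
are reproducible given the seed, and summary means are stable to well
under 0.01 across seeds. The ground truth each run is scored against is
the all-replicate mean, including the sampled replicate; excluding it
per run would give a marginally harsher ceiling, and the as-is
convention is retained deliberately and noted here.

## Difficulty profiling

For each predictor with AUC above 0.8 (on the activity scale, all 28
variants, missing scores imputed), the difficulty of a LoF variant is
the predictor's false positive rate with the threshold placed at that
variant — the fraction of WT-like variants predicted less active — and
symmetrically the FNR for WT-like variants. Entries are exactly the ROC
coordinates at the variant's own threshold; a perfectly separating
predictor has an all-zero row. A variant with high values across
predictors is genuinely hard, not just mis-scored by one tool.

## The point-based classification engine

Evidence is combined on the integer point scale: supporting/moderate/
strong/very strong toward pathogenicity are +1/+2/+4/+8, toward
benignity the negatives. Totals map to categories P ($\ge 10$), LP
(6–9), VUS (0–5; subdivided low 0–1, mid 2–3, high 4–5), LB (−6…−1), B
($\le -7$) — ranges that partition the integers, so every total has
exactly one category and adding pathogenic-direction points can never
move a variant toward benign.

* **PS3/BS3**: each assay contributes ±1 at supporting strength; the
  two concordant assays therefore net ±2, and the single discordant
  variant nets 0.
* **PM2/BS1**: PM2 (+1, supporting per the updated guidance rather than
  the original moderate) only for complete absence from gnomAD — for a
  dominant condition, presence at any frequency is informative; BS1
  (−4) strictly above allele frequency 0.001; frequencies between are
  indeterminate and yield no code.
* **PP3/BP4**: calibrated REVEL intervals, $[0.644, 0.773)$,
  $[0.773, 0.932)$, $[0.932, 1]$ for +1/+2/+4 and $(0.183, 0.290]$,
  $(0.016, 0.183]$, $(0.003, 0.016]$ for −1/−2/−4. Boundaries follow the
  interval notation exactly: 0.932 is strong-pathogenic, 0.644 is
  supporting, a score of exactly 0.003 yields no code. Variants without
  a REVEL score (the indel) receive no computational code and no PM5.
* **PM5**: a co-located P/LP variant qualifies when its REVEL score is
  at or below the tested variant's score rounded to two decimals
  (ties qualify); points are 2 if any qualifying variant is P else 1,
  plus 1 per additional qualifying variant.

On the packaged evidence table the engine reproduces the published
totals and categories for 27 of 28 variants. For p.D194Y the PM5 rule as
written admits only one of the three co-located pathogenic variants
(tested 0.929 → 0.93; co-located scores 0.94, 0.94, 0.84), giving +2 and
a total of 7 where the published table prints +4 and 9. The engine
implements the written rule; the regression test documents the
divergence, and the final LP category is identical either way. De novo,
segregation and case-level codes are deliberately unsupported: no case
data exists for these biopsy-derived variants, and the engine makes no
claim to being a general ACMG implementation.

## Synthetic data

`simulate_assay()` emulates the *statistical* structure of the
experiment: true activities from a two-component Gaussian mixture (LoF
mean 0.25, sd 0.15; WT-like mean 1.1, sd 0.25 — chosen to resemble the
observed spread of the two classes, and configuration rather than an
estimate), 17 biological replicates with 2–3 technical replicates each,
every variant measured in a random 3–6-replicate subset, a shared
per-(variant, biological replicate) offset for biological noise
(defaults: sd 0.15) and per-measurement technical noise (sd 0.05), and
per-cell EV/WT raw control levels so raw readings are emitted on an
arbitrary luminescence scale. Normalization against a cell's own
controls recovers the generating activity plus noise exactly, which is
what makes zero-noise round-trip tests exact. It does **not** model
luciferase biochemistry, transfection-efficiency correction (inputs are
taken as already adjusted), heteroscedastic or non-Gaussian assay error,
or any relationship between a variant's sequence and its activity — so
passing synthetic tests demonstrates the pipeline's correctness, not
that real predictors will perform comparably on other genes.

`simulate_predictor()` produces scores as a monotone link of the true
activity plus Gaussian noise, under either orientation (the
pathogenicity default link is a decreasing logistic centred at the 0.6
threshold, clamped to $[0,1]$ after noise), with configurable missing
ids to exercise imputation. `simulate_evidence()` fabricates evidence
tables that exercise every code path of the classification engine,
including BS1 and the multi-variant PM5 branch.

## Problem sizes and numerical conventions

Defaults follow the study conditions: 1000 bootstrap resamples, 1000
Experimental-Max runs, 5th/95th percentile intervals, AUC selection
threshold 0.8, $\tau = 0.6$. The test suite scales Monte-Carlo checks to
what they need rather than to the defaults — e.g. the noise-sweep
property uses 24-variant assays, 50 seeds per noise level and 40
Experimental-Max runs per assay, and the bootstrap-shrinkage property
uses 400 resamples at set sizes 22 and 88 — sizes at which the asserted
orderings are stable by a comfortable margin. All randomness flows from
explicit integer seeds; identical configuration and seed give
byte-identical outputs, including the TSV/JSON files written by
`run_pipeline()`.

## Known limitations

* The published raw replicate measurements are not redistributable
  here, so replicate-level behaviour (Experimental-Max point values,
  bootstrap CI widths on real data) is validated against the published
  summary table and on synthetic assays, not against the original raw
  data.
* The evaluation set is small (22 variants); bootstrap intervals on
  real data are wide, and conclusions about any single predictor's
  superiority should rest on the paired win test, not on CI overlap.
* The classification engine covers exactly the seven evidence codes
  used for this variant set, with REVEL as the only calibrated
  computational source.
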