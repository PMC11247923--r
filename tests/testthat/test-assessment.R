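test_that("bootstrap resamples are seed-deterministic and label-balanced", {
  labels <- rep(c("LoF", "WT-like"), c(4, 4))
  a <- bootstrap_resamples(8, n_boot = 50, seed = 9, labels = labels)
  b <- bootstrap_resamples(8, n_boot = 50, seed = 9, labels = labels)
  expect_identical(a, b)
  pos <- labels == "LoF"
  n_pos <- apply(a, 1, function(i) sum(pos[i]))
  expect_true(all(n_pos > 0 & n_pos < 8))
  expect_error(bootstrap_resamples(8, n_boot = 10),
               regexp = "seed")
})

test_that("bootstrap CI brackets a constant metric exactly", {
  scores <- c(10, 9, 8, 1, 2, 3)
  labels <- rep(c("LoF", "WT-like"), each = 3)
  br <- bootstrap_metric(auc, scores, labels, n_boot = 100, seed = 4,
                         metric = "auc")
  expect_equal(br$point_estimate, 1)
  expect_equal(br$ci_low, 1)
  expect_equal(br$ci_high, 1)
  expect_length(br$estimates, 100)
})

test_that("bootstrap CI contains the point estimate and tightens with n", {
  widths <- sapply(c(15, 60, 240), function(n) {
    set.seed(100 + n)
    x <- runif(n)
    y <- x + rnorm(n, 0, 0.4)
    br <- bootstrap_metric(pearson, y, x, n_boot = 300, seed = 21,
                           metric = "pearson")
    expect_gte(br$point_estimate, br$ci_low)
    expect_lte(br$point_estimate, br$ci_high)
    br$ci_high - br$ci_low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("gaussian half-width is 1.96 sd of the estimates", {
  expect_equal(gaussian_ci(rep(0.8, 10)), 0)
  est <- rep(c(0, 1), 50)
  expect_equal(gaussian_ci(est), 1.96 * sd(est))
})

test_that("REVEL bootstrap AUC CI on the packaged data matches the published band", {
  v <- stk11_variants()
  e <- stk11_evidence()
  eval_ids <- v$variant_id[!v$excluded_from_evaluation]
  revel <- prediction_set("REVEL",
                          setNames(e$revel, e$variant_id),
                          orientation = "pathogenicity_01")
  pat <- impute_missing(to_pathogenicity_scale(revel), eval_ids)$scores[eval_ids]
  labels <- v$label[match(eval_ids, v$variant_id)]
  br <- bootstrap_metric(auc, pat, labels, n_boot = 1000, seed = 2024,
                         metric = "auc")
  expect_equal(br$point_estimate, 0.95, tolerance = 1e-12)
  expect_equal(br$ci_low, 0.867, tolerance = 0.02)
  expect_equal(br$ci_high, 1.000, tolerance = 0.02)
})

test_that("rank averaging reproduces the published predictor order", {
  m <- stk11_predictor_metrics()
  participants <- m[m$group == "participant",
                    c("predictor", "pearson", "kendall_tau", "auc")]
  ranked <- rank_predictors(participants)
  expect_equal(ranked$predictor,
               c("3Cnet", "Evolutionary Action", "Protein language model",
                 "Bologna Biocomputing"))
  expect_equal(ranked$avg_rank, c(1, 2, 10 / 3, 11 / 3))
  baselines <- m[m$group == "baseline",
                 c("predictor", "pearson", "kendall_tau", "auc")]
  expect_equal(rank_predictors(baselines)$predictor[1], "REVEL")
})

test_that("ranking handles ties and monotone rescaling of one metric", {
  two <- tibble::tibble(predictor = c("a", "b"), pearson = 0.5,
                        kendall_tau = 0.4, auc = 0.9)
  r <- rank_predictors(two)
  expect_equal(r$avg_rank, c(1.5, 1.5))
  m <- tibble::tibble(predictor = c("a", "b", "c"),
                      pearson = c(0.9, 0.5, 0.1),
                      kendall_tau = c(0.7, 0.6, 0.2),
                      auc = c(0.95, 0.8, 0.6))
  m2 <- dplyr::mutate(m, auc = exp(5 * auc))  # strictly monotone rescale
  expect_equal(rank_predictors(m)$predictor, rank_predictors(m2)$predictor)
  expect_equal(rank_predictors(m)$avg_rank, rank_predictors(m2)$avg_rank)
})

test_that("team representatives are picked within team then re-ranked", {
  m <- tibble::tibble(
    predictor = c("a1", "a2", "b1", "b2"),
    team = c("A", "A", "B", "B"),
    pearson = c(0.9, 0.3, 0.5, 0.6),
    kendall_tau = c(0.8, 0.2, 0.4, 0.5),
    auc = c(0.95, 0.6, 0.7, 0.8)
  )
  reps <- select_team_representatives(m)
  expect_setequal(reps$predictor, c("a1", "b2"))
  expect_equal(rank_predictors(reps)$predictor, c("a1", "b2"))
})

test_that("win test uses the exact upper binomial tail", {
  # frozen values computed with exact rational arithmetic
  expect_equal(binom_tail_log10(838, 1000), -110.0226, tolerance = 1e-5)
  expect_equal(binom_tail_log10(687, 1000), -32.42795, tolerance = 1e-6)
  expect_equal(binom_tail_log10(629, 1000), -15.81982, tolerance = 1e-6)
  expect_equal(10^binom_tail_log10(500, 1000), 0.5126125, tolerance = 1e-6)
  expect_equal(binom_tail_log10(1000, 1000), -1000 * log10(2))
  expect_equal(binom_tail_log10(0, 1000), 0)
})

test_that("win test pairs estimates and is conservative on ties", {
  a <- c(0.9, 0.8, 0.7, 0.6)
  wt <- win_test(a, a)  # self-comparison: no strict wins
  expect_equal(wt$wins, 0)
  expect_equal(wt$p_value, 1)
  wt2 <- win_test(c(1, 1, 0, 1), c(0, 0, 1, 1))  # tie counts as non-win
  expect_equal(wt2$wins, 2)
  expect_error(win_test(1:5, 1:4), class = "stk11vep_pairing_error")
  ba <- bootstrap_metric(pearson, runif(10), runif(10), n_boot = 20, seed = 1)
  bb <- bootstrap_metric(pearson, runif(10), runif(10), n_boot = 20, seed = 2)
  expect_error(win_test(ba, bb), class = "stk11vep_pairing_error")
})

test_that("difficulty entries follow the FPR/FNR threshold definition", {
  truth <- tibble::tibble(variant_id = c("l1", "l2", "w1", "w2"),
                          label = c("LoF", "LoF", "WT-like", "WT-like"))
  scores <- list(p = c(l1 = 0.2, l2 = 0.5, w1 = 0.3, w2 = 0.9))
  d <- difficulty_scores(scores, truth)
  expect_equal(d["p", "l2"], 0.5)  # one of two WT-like scores below 0.5
  expect_equal(d["p", "l1"], 0)
  expect_equal(d["p", "w1"], 0.5)  # l2 predicted above w1
  expect_true(all(d >= 0 & d <= 1))
  # a perfectly separating predictor has an all-zero row
  perfect <- list(q = c(l1 = 0.1, l2 = 0.2, w1 = 0.8, w2 = 0.9))
  expect_true(all(difficulty_scores(perfect, truth) == 0))
})

test_that("difficulty FPR equals the ROC false-positive coordinate at the variant", {
  set.seed(23)
  truth <- tibble::tibble(variant_id = paste0("v", 1:12),
                          label = rep(c("LoF", "WT-like"), each = 6))
  s <- setNames(runif(12), truth$variant_id)
  d <- difficulty_scores(list(p = s), truth)
  roc <- roc_curve(-s, truth$label)  # pathogenicity orientation
  for (v in truth$variant_id[truth$label == "LoF"]) {
    expect_equal(unname(d["p", v]), roc$fpr[roc$threshold == -s[v]])
  }
})
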