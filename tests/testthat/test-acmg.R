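test_that("population evidence: PM2 for absence, BS1 above 0.001, else none", {
  pm2 <- score_population(NA)
  expect_equal(pm2$code, "PM2")
  expect_equal(pm2$points, 1L)
  bs1 <- score_population(0.0051)
  expect_equal(bs1$code, "BS1")
  expect_equal(bs1$points, -4L)
  expect_equal(nrow(score_population(3.16e-06)), 0)
  expect_equal(nrow(score_population(0.001)), 0)  # boundary: strictly above
  expect_error(score_population(1.5), class = "stk11vep_validation_error")
})

test_that("functional evidence nets +2, -2 or 0 from the two assays", {
  both_lof <- score_functional("LoF", "LoF")
  expect_equal(sum(both_lof$points), 2L)
  expect_setequal(both_lof$code, "PS3")
  both_wt <- score_functional("WT-like", "WT-like")
  expect_equal(sum(both_wt$points), -2L)
  discord <- score_functional("LoF", "WT-like")
  expect_equal(sum(discord$points), 0L)
  expect_setequal(discord$code, c("PS3", "BS3"))
  expect_error(score_functional("LoF", NA),
               class = "stk11vep_validation_error")
})

test_that("computational evidence follows the calibrated REVEL intervals", {
  cases <- list(
    list(0.932, "PP3", 4L),   # strong lower bound inclusive
    list(0.954, "PP3", 4L),
    list(0.871, "PP3", 2L),
    list(0.773, "PP3", 2L),   # moderate lower bound inclusive
    list(0.728, "PP3", 1L),
    list(0.644, "PP3", 1L),
    list(0.215, "BP4", -1L),
    list(0.290, "BP4", -1L),  # supporting upper bound inclusive
    list(0.102, "BP4", -2L),
    list(0.183, "BP4", -2L),
    list(0.010, "BP4", -4L),
    list(0.016, "BP4", -4L)
  )
  for (cs in cases) {
    res <- score_computational(cs[[1]])
    expect_equal(res$code, cs[[2]])
    expect_equal(res$points, cs[[3]])
  }
  for (none in c(NA, 0.424, 0.003, 0.0005, 0.5, 0.6439)) {
    expect_equal(nrow(score_computational(none)), 0)
  }
  expect_error(score_computational(1.2), class = "stk11vep_validation_error")
})

test_that("PM5 compares 2-dp-rounded scores and scales with qualifying count", {
  co <- function(cls, rev) data.frame(classification = cls, revel = rev)
  # two qualifying LP variants -> 1 + 1
  expect_equal(score_pm5(0.881, co(c("LP", "LP"), c(0.73, 0.84)))$points, 2L)
  # tie after rounding qualifies (0.936 -> 0.94 vs P at 0.94) -> 2
  expect_equal(score_pm5(0.936, co("P", 0.94))$points, 2L)
  # rounded below the co-located score -> no code (0.933 -> 0.93 < 0.95)
  expect_equal(nrow(score_pm5(0.933, co("P", 0.95))), 0)
  # first P dominates mixed sets: P + LP + LP all qualifying -> 2 + 2
  expect_equal(score_pm5(0.99, co(c("LP", "P", "LP"), c(0.8, 0.9, 0.7)))$points,
               4L)
  expect_equal(nrow(score_pm5(NA, co("P", 0.94)[0, ])), 0)  # empty list
  expect_error(score_pm5(0.9, co("B", 0.5)),
               class = "stk11vep_validation_error")
  expect_error(score_pm5(NA, co("P", 0.94)),
               class = "stk11vep_validation_error")
})

test_that("point totals partition the integer line into the five categories", {
  expected <- function(t) {
    if (t >= 10) "P" else if (t >= 6) "LP" else if (t >= 0) "VUS"
    else if (t >= -7 + 1) "LB" else "B"
  }
  cats <- sapply(-20:20, function(t) classify_points(t)$category)
  expect_equal(cats, sapply(-20:20, expected))
  expect_equal(classify_points(0)$vus_sub, "low")
  expect_equal(classify_points(1)$vus_sub, "low")
  expect_equal(classify_points(2)$vus_sub, "mid")
  expect_equal(classify_points(3)$vus_sub, "mid")
  expect_equal(classify_points(4)$vus_sub, "high")
  expect_equal(classify_points(5)$vus_sub, "high")
  expect_true(is.na(classify_points(6)$vus_sub))
})

test_that("adding pathogenic points never moves the category toward benign", {
  order_map <- c(B = 1, LB = 2, VUS = 3, LP = 4, P = 5)
  for (t in -20:19) {
    expect_gte(order_map[classify_points(t + 1)$category],
               order_map[classify_points(t)$category])
  }
})

test_that("single-variant classification assembles all evidence dimensions", {
  # absent from gnomAD, concordant LoF, strong computational, co-located P
  r297m <- classify_variant("p.R297M", NA, "LoF", "LoF", 0.936,
                            "R297S:P:0.94")
  expect_equal(r297m$total, 9L)
  expect_equal(r297m$category, "LP")
  # common allele, concordant WT-like, moderate benign computational
  f354l <- classify_variant("p.F354L", 0.0051, "WT-like", "WT-like", 0.156,
                            NULL)
  expect_equal(f354l$total, -8L)
  expect_equal(f354l$category, "B")
  # discordant assays, indeterminate elsewhere -> all evidence cancels
  h202r <- classify_variant("p.H202R", 3.16e-06, "LoF", "WT-like", 0.424,
                            NULL)
  expect_equal(h202r$total, 0L)
  expect_equal(h202r$category, "VUS")
  expect_equal(h202r$vus_sub, "low")
  # empty evidence -> 0 points -> VUS-low
  none <- classify_variant("p.X", 1e-05, "LoF", "WT-like", NA, NULL)
  expect_equal(none$total, 0L)
  expect_equal(none$vus_sub, "low")
})

test_that("the engine reproduces the published classification table", {
  e <- stk11_evidence()
  cls <- classify_variants(e)
  merged <- dplyr::left_join(cls, e, by = "variant_id")
  printed_cat <- sub("-.*", "", merged$printed_category)
  printed_sub <- ifelse(grepl("-", merged$printed_category),
                        sub(".*-", "", merged$printed_category),
                        NA_character_)
  known_discrepancy <- merged$variant_id == "p.D194Y"
  # 27 of 28 totals match the printed table exactly
  expect_equal(merged$total[!known_discrepancy],
               merged$printed_total[!known_discrepancy])
  # all 28 final categories (and VUS subranges) match
  expect_equal(merged$category, printed_cat)
  expect_equal(merged$vus_sub, printed_sub)
  # p.D194Y: the written PM5 rule admits only the one co-located variant
  # whose score (0.84) does not exceed 0.93, a P, giving +2 not the printed
  # +4; the total differs (7 vs 9) but the LP call is unchanged
  expect_equal(merged$pm5_points[known_discrepancy], 2)
  expect_equal(merged$total[known_discrepancy], 7)
  expect_equal(merged$category[known_discrepancy], "LP")
})

test_that("colocated field parsing round-trips triplets", {
  co <- parse_colocated("W308C:LP:0.73;W308L:LP:0.84")
  expect_equal(co$variant_id, c("W308C", "W308L"))
  expect_equal(co$revel, c(0.73, 0.84))
  expect_equal(nrow(parse_colocated(NA)), 0)
  expect_error(parse_colocated("oops"), class = "stk11vep_validation_error")
})
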