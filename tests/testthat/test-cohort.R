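test_that("GOLD staging follows the spirometric cut-points", {
  expect_identical(as.character(classify_gold(75, 95)), "non-COPD")
  expect_identical(as.character(classify_gold(60, 55)), "GOLD-II")
  expect_identical(as.character(classify_gold(50, 25)), "GOLD-IV")
  # boundaries: ratio 70 is still non-COPD; pct-predicted cuts at 80/50/30
  expect_identical(as.character(classify_gold(70, 20)), "non-COPD")
  expect_identical(as.character(classify_gold(69.9, 80)), "GOLD-I")
  expect_identical(as.character(classify_gold(69.9, 79.9)), "GOLD-II")
  expect_identical(as.character(classify_gold(69.9, 50)), "GOLD-II")
  expect_identical(as.character(classify_gold(69.9, 49.9)), "GOLD-III")
  expect_identical(as.character(classify_gold(69.9, 30)), "GOLD-III")
  expect_identical(as.character(classify_gold(69.9, 29.9)), "GOLD-IV")
  expect_error(classify_gold(0, 50), "positive")
})

test_that("group summaries report sample means and SDs", {
  rec <- data.frame(gold = factor(rep("GOLD-I", 2), levels = fissint:::GOLD_LEVELS),
                    rof = c(80, 84))
  s <- group_summary(rec, measures = "rof")
  row <- s[s$group == "GOLD-I", ]
  expect_equal(row$mean, 82)
  expect_equal(round(row$sd, 1), 2.8)
  # single-subject group: mean is the value, SD undefined
  rec1 <- data.frame(gold = factor("GOLD-IV", levels = fissint:::GOLD_LEVELS),
                     rof = 77)
  s1 <- group_summary(rec1, measures = "rof")
  expect_equal(s1$mean[s1$group == "GOLD-IV"], 77)
  expect_true(is.na(s1$sd[s1$group == "GOLD-IV"]))
})

test_that("simulated cohorts recover their generating means", {
  rec <- truth_records(500, seed = 42,
                       integrity_dist = list(ROF = c(82, 5), RHF = c(62, 22),
                                             LOF = c(82, 12)))
  s <- group_summary(rec, measures = "rof")
  means <- s$mean[s$group != "all" & s$n > 0]
  expect_true(all(abs(means - 82) < 2.5))
  expect_lt(abs(s$mean[s$group == "all"] - 82), 1.0)
})

test_that("distribution tables match brute-force filtering", {
  rec <- truth_records(300, seed = 7)
  dt <- distribution_table(rec, "rhf")
  bins <- bin_integrity(rec$rhf)
  for (g in fissint:::GOLD_LEVELS) {
    for (b in levels(bins)) {
      expect_equal(unname(dt$counts[b, g]),
                   sum(rec$gold == g & bins == b))
    }
  }
  # percentages recompute from counts; group counts sum to group n
  expect_equal(colSums(dt$counts[, 1:5]), unname(dt$group_n),
               ignore_attr = TRUE)
  expect_equal(dt$pct[, "all"],
               100 * dt$counts[, "all"] / dt$total, ignore_attr = TRUE)
  expect_equal(sum(dt$counts[, "all"]), nrow(rec))

  # degenerate cohort: a single populated bin at 100%
  rec2 <- data.frame(gold = factor(rep("GOLD-II", 10),
                                   levels = fissint:::GOLD_LEVELS),
                     rof = rep(100, 10))
  dt2 <- distribution_table(rec2, "rof")
  expect_equal(unname(dt2$pct["(90%, 100%]", "all"]), 100)
  expect_equal(sum(dt2$counts[, "all"] > 0), 1)
})

test_that("the published cohort counts reproduce their aggregate column", {
  cts <- reported_bin_counts()
  res <- distribution_percentages(cts$rof)
  expect_identical(unname(res$counts["(90%, 100%]", "all"]), 149)
  expect_equal(unname(round(res$pct["(90%, 100%]", "all"], 1)), 26.0)
  expect_equal(res$total, 573)
  expect_equal(unname(res$group_n), c(222, 83, 141, 63, 64))
})

test_that("pearson_r equals the direct-formula oracle", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(31)
  for (i in 1:5) {
    a <- rnorm(50)
    b <- 0.3 * a + rnorm(50)
    got <- pearson_r(a, b)
    bf <- pearson_bf(a, b)
    expect_equal(got$r, bf$r, tolerance = 1e-12)
    expect_equal(got$p, bf$p, tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("spearman_rho equals the exhaustive mid-rank oracle under ties", {
  x <- 1:10
  expect_equal(spearman_rho(x, x^3)$rho, 1)
  expect_equal(spearman_rho(x, rev(x))$rho, -1)
  set.seed(17)
  for (i in 1:5) {
    a <- sample(1:5, 50, replace = TRUE)        # heavily tied, GOLD-like
    b <- rnorm(50) + 0.1 * a
    got <- spearman_rho(a, b)
    bf <- spearman_bf(a, b)
    expect_equal(got$rho, bf$rho, tolerance = 1e-12)
    expect_equal(got$p, bf$p, tolerance = 1e-12)
  }
  # Pearson and Spearman coincide when both variables equal their own ranks
  a <- sample(30); b <- sample(30)
  expect_equal(spearman_rho(a, b)$rho, pearson_r(a, b)$r, tolerance = 1e-12)
})

test_that("severity-independent integrity yields null Spearman association", {
  hits <- 0L
  n <- 200
  reps <- 20
  for (k in seq_len(reps)) {
    rec <- truth_records(n, seed = 1000 + k)
    rho <- spearman_rho(rec$elf, rec$gold)$rho
    tcrit <- stats::qt(0.975, df = n - 2)
    rcrit <- tcrit / sqrt(n - 2 + tcrit^2)
    if (abs(rho) < rcrit) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("cohort_summary bundles tables and stages from spirometry", {
  rec <- truth_records(120, seed = 12)
  rec$gold <- NULL
  cs <- cohort_summary(rec)
  expect_s3_class(cs, "fissure_cohort")
  expect_identical(cs$n, 120L)
  expect_identical(sum(cs$group_n), 120L)
  expect_setequal(names(cs$distributions), c("rof", "rhf", "lof", "elf"))
  expect_identical(nrow(cs$correlations), 12L)
  # plot method runs headless
  pdf(NULL)
  on.exit(dev.off())
  pct <- plot(cs)
  expect_equal(colSums(pct), rep(100, 4), ignore_attr = TRUE,
               tolerance = 1e-9)
})
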