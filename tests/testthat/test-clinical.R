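test_that("delta-Ct relative expression follows 2^-(target - reference)", {
  expect_equal(relative_expression(20, c(20, 20)), 1)
  expect_equal(relative_expression(21, 20), 0.5)
  # worked dilution-series values: target 25.38 vs housekeeping 15.52
  expect_equal(relative_expression(25.38, 15.52), 2^-9.86)
  expect_lt(abs(relative_expression(25.38, 15.52) - 1.077e-3), 1e-5)
  # shift consistency: adding c to every Ct changes nothing
  expect_equal(relative_expression(25 + 3, matrix(c(15, 17) + 3, 1)),
               relative_expression(25, matrix(c(15, 17), 1)))
  expect_error(relative_expression(NA, 15), class = "uromark_validation_error")
})

test_that("fold of medians reproduces printed verification ratios", {
  # group medians from the printed stage-1 marker table
  expect_equal(fold_of_medians(rep(0.016, 3), rep(0.0017, 3)), 9.4)
  expect_equal(fold_of_medians(rep(0.014, 3), rep(0.0023, 3)), 6.1)
  expect_equal(fold_of_medians(rep(0.085, 3), rep(0.039, 3)), 2.2)
  expect_equal(fold_of_medians(1:9, 1:9), 1)
  # invariant under common positive rescaling
  set.seed(61)
  x <- rlnorm(20); y <- rlnorm(30)
  expect_equal(fold_of_medians(7 * x, 7 * y, 3), fold_of_medians(x, y, 3))
  expect_error(fold_of_medians(1:3, c(-1, 0, 1)), class = "uromark_validation_error")
})

test_that("Kruskal-Wallis wraps the rank test with a degenerate convention", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # hand-ranked: R1 = 6, R2 = 15 -> H = 12/(6*7) * (12 + 75) - 21
  expect_equal(kw$H, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-12)
  expect_equal(kw$p, stats::pchisq(kw$H, 1, lower.tail = FALSE))
  expect_identical(kruskal_wallis(list(rep(2, 4), rep(2, 5))), list(H = 0, p = 1, df = 1L))
  expect_error(kruskal_wallis(list(1:3)), class = "uromark_precondition_error")
})

test_that("Kruskal-Wallis type-I error sits at the nominal level", {
  set.seed(67)
  rejections <- vapply(1:1000, function(i) {
    kruskal_wallis(list(rnorm(20), rnorm(20), rnorm(20)))$p < 0.05
  }, TRUE)
  # binomial 3-sigma band around 0.05 at 1000 replicates
  expect_lt(abs(mean(rejections) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("pairwise rank-sum tests adjust across the pair family", {
  same <- list(a = 1:20, b = 1:20)
  expect_gte(pairwise_tests(same)$p, 0.9)
  sep <- pairwise_tests(list(lo = 1:10, hi = 11:20))
  expect_true(sep$U %in% c(0, 100))
  expect_lt(sep$p, 0.001)

  set.seed(71)
  groups <- split(rnorm(60), rep(1:4, each = 15))
  pw <- pairwise_tests(groups)
  expect_identical(nrow(pw), 6L)
  expect_equal(pw$padj, bh_adjust(pw$p), tolerance = 1e-12)
})

test_that("Spearman correlation recovers planted cohort association", {
  expect_equal(spearman_cor(1:10, exp(1:10))$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  # cohort generator at the verification-study regime: rho 0.47, n = 80;
  # averaged over replicate cohorts to damp the per-cohort sampling noise
  ests <- vapply(1:10, function(seed) {
    cfg <- cohort_config(
      groups = c(G = 80), marker_median = c(G = 0.01), marker_sdlog = 1.2,
      covariates = list(acr = list(median = c(G = 50), sdlog = 1.5, spearman = 0.47)),
      seed = seed)
    co <- simulate_cohort(cfg)
    spearman_cor(co$relexpr, co$acr)$rho
  }, 0)
  expect_lt(abs(mean(ests) - 0.47), 0.15)
  expect_error(spearman_cor(1:2, 1:2), class = "uromark_precondition_error")
})

test_that("ROC analysis satisfies its rank-statistic identities", {
  # perfect separation
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_identical(r$band, "excellent")

  # trapezoid AUC == U/(n1*n2) on random tied and untied instances
  set.seed(79)
  for (i in 1:200) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    digits <- sample(c(0, 1, 3), 1)   # coarse rounding induces ties
    pos <- round(rnorm(n1, 0.5), digits); neg <- round(rnorm(n2), digits)
    r <- roc_analysis(c(pos, neg), rep(c(TRUE, FALSE), c(n1, n2)))
    u <- sum(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(r$auc, u / (n1 * n2), tolerance = 1e-12)
  }

  # AUC invariant under strictly monotone score transforms
  set.seed(83)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.4)
  expect_equal(roc_analysis(exp(sc), lb)$auc, roc_analysis(sc, lb)$auc)
  expect_equal(roc_analysis(sc^3, lb)$auc, roc_analysis(sc, lb)$auc)

  # null scores give AUC near one half
  set.seed(89)
  expect_lt(abs(roc_analysis(rnorm(500), rbinom(500, 1, 0.5))$auc - 0.5), 0.05)

  expect_error(roc_analysis(1:5, rep(1, 5)), class = "uromark_validation_error")
})

test_that("Youden cutoff matches an exhaustive scan and the reference ROC", {
  set.seed(97)
  sc <- round(c(rnorm(40, 1), rnorm(40)), 1)
  lb <- rep(c(TRUE, FALSE), each = 40)
  r <- roc_analysis(sc, lb)
  scan <- vapply(sort(unique(sc)), function(cc) {
    mean(sc[lb] >= cc) + mean(sc[!lb] < cc)
  }, 0)
  expect_equal(r$sensitivity + r$specificity, max(scan), tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- pROC::roc(lb, sc, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("ROC orientation flag handles markers low in the positive class", {
  sc <- c(1, 2, 3, 10, 11, 12)
  lb <- c(1, 1, 1, 0, 0, 0)    # positives have LOW scores
  r <- roc_analysis(sc, lb, positive_is_high = FALSE)
  expect_equal(r$auc, 1)
  expect_true(all(sc[lb == 1] <= r$cutoff))
})

test_that("CV report reproduces the printed reproducibility table", {
  cv <- cv_report(dilution_table_fixture())
  cells <- cv$cells
  pick <- function(g, a) cells$cv_pct[cells$gene == g & cells$amount_ng == a]
  # the six printed cells reproducible under the population-SD convention
  expect_identical(pick("BBOX1", 50), 0.10)
  expect_identical(pick("BBOX1", 5), 0.19)
  expect_identical(pick("BBOX1", 0.5), 0.27)
  expect_identical(pick("B2M", 50), 0.09)
  expect_identical(pick("B2M", 5), 0.17)
  expect_identical(pick("B2M", 0.5), 0.05)
  # the 500 ng housekeeping cell matches only under the sample-SD convention
  cv_s <- cv_report(dilution_table_fixture(), sd_mode = "sample")
  expect_identical(cv_s$cells$cv_pct[cv_s$cells$gene == "B2M" &
                                       cv_s$cells$amount_ng == 500], 0.24)
  # identical replicates: zero CV
  flat <- data.frame(gene = "g", amount_ng = 5, replicate = 1:3, ct = rep(30, 3))
  expect_identical(cv_report(flat)$cells$cv_pct, 0)
  # per-gene averages of the printed per-dilution values
  expect_identical(average_cv(c(0.49, 0.10, 0.19, 0.27)), 0.26)
  expect_identical(average_cv(c(0.24, 0.09, 0.17, 0.05)), 0.14)
})
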