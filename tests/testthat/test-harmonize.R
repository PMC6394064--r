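test_that("feature intersection pools platforms on the shared sorted set", {
  v1 <- matrix(as.numeric(1:6), 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  v2 <- matrix(as.numeric(7:12), 3, 2, dimnames = list(c("B", "C", "D"), c("s3", "s4")))
  m1 <- make_matrix(v1, c("x", "x"), platform = "p1")
  m2 <- make_matrix(v2, c("y", "y"), platform = "p2")
  pooled <- intersect_platform_features(list(m1, m2))
  expect_identical(rownames(pooled$values), c("B", "C"))
  expect_identical(pooled$values["B", ], c(s1 = 2, s2 = 5, s3 = 7, s4 = 10))
  expect_identical(pooled$samples$platform, c("p1", "p1", "p2", "p2"))

  # identical feature sets: identity up to sorting
  v1b <- v1[c(3, 1, 2), ]
  colnames(v1b) <- c("s7", "s8")
  same <- intersect_platform_features(list(m1, make_matrix(v1b, c("x", "x"))))
  expect_identical(rownames(same$values), c("A", "B", "C"))

  # disjoint sets: harmonization error reporting pairwise overlaps
  v3 <- matrix(1:2, 1, 2, dimnames = list("Z", c("s5", "s6")))
  m3 <- make_matrix(v3, c("z", "z"))
  expect_error(intersect_platform_features(list(m1, m3)),
               "overlap", class = "uromark_harmonization_error")
})

test_that("feature intersection matches a set oracle on random subsets", {
  set.seed(42)
  universe <- sprintf("f%04d", 1:1500)
  subsets <- lapply(1:3, function(i) sample(universe, 1000))
  mats <- lapply(seq_along(subsets), function(i) {
    v <- matrix(rnorm(2000), 1000, 2,
                dimnames = list(subsets[[i]], sprintf("s%d_%d", i, 1:2)))
    make_matrix(v, c("x", "x"), platform = sprintf("p%d", i))
  })
  pooled <- intersect_platform_features(mats)
  oracle <- sum(universe %in% subsets[[1]] & universe %in% subsets[[2]] &
                  universe %in% subsets[[3]])
  expect_identical(nrow(pooled$values), oracle)
})

test_that("quantile normalization forces the common distribution", {
  # forced two-sample case
  v <- cbind(s1 = c(1, 2, 3), s2 = c(3, 4, 5))
  rownames(v) <- c("A", "B", "C")
  qn <- quantile_normalize(make_matrix(v, c("x", "y")))
  expect_equal(unname(qn$values), cbind(c(2, 3, 4), c(2, 3, 4)))

  # identical samples are a fixed point
  v2 <- matrix(rnorm(30), 10, 3, dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:3)))
  v2[, 2] <- v2[, 1]; v2[, 3] <- v2[, 1]
  m2 <- make_matrix(v2, rep("x", 3))
  expect_equal(quantile_normalize(m2)$values, v2)

  # random matrix: identical sorted columns, ranks preserved, idempotent
  set.seed(7)
  v3 <- matrix(rnorm(300), 50, 6,
               dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
  m3 <- make_matrix(v3, rep("x", 6))
  qn3 <- quantile_normalize(m3)
  sorted <- apply(qn3$values, 2, sort)
  expect_true(all(sorted == sorted[, 1]))
  for (j in 1:6) {
    expect_equal(cor(v3[, j], qn3$values[, j], method = "spearman"), 1)
  }
  expect_equal(quantile_normalize(qn3)$values, qn3$values)

  v3[1, 1] <- NA
  expect_error(quantile_normalize(make_matrix(v3, rep("x", 6))),
               class = "uromark_precondition_error")
})

test_that("quantile normalization matches the reference method without ties", {
  skip_if_not_installed("limma")
  set.seed(13)
  v <- matrix(rnorm(60), 20, 3,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:3)))
  qn <- quantile_normalize(make_matrix(v, rep("x", 3)))
  ref <- limma::normalizeQuantiles(v, ties = TRUE)
  expect_equal(unname(qn$values), unname(ref), tolerance = 1e-12)
})

test_that("tied values receive the mean reference quantile over their ranks", {
  # col1 ties at ranks 1-2; reference = (3, 3.5, 5)
  v <- cbind(s1 = c(5, 5, 7), s2 = c(1, 2, 3))
  rownames(v) <- c("A", "B", "C")
  qn <- quantile_normalize(make_matrix(v, c("x", "y")))
  expect_equal(unname(qn$values),
               cbind(c(3.25, 3.25, 5), c(3, 3.5, 5)))
})

test_that("median polish recovers additive structure and resists outliers", {
  row_eff <- c(0, 1, 2, 3)
  col_eff <- c(5, 6, 7)
  clean <- outer(row_eff, col_eff, `+`)
  colnames(clean) <- sprintf("s%d", 1:3)
  sm <- median_polish_summarize(clean, rep("g1", 4), tol = 1e-9)
  expect_equal(unname(sm["g1", ]), col_eff + mean(range(row_eff)), tolerance = 1e-6)

  # single-probe gene passes through
  single <- matrix(c(1.5, 2.5, 3.5), 1, dimnames = list(NULL, sprintf("s%d", 1:3)))
  expect_equal(unname(median_polish_summarize(single, "g2")["g2", ]), c(1.5, 2.5, 3.5))

  # one +10 outlier cell barely moves the summaries
  dirty <- clean
  dirty[2, 2] <- dirty[2, 2] + 10
  sm_clean <- median_polish_summarize(clean, rep("g1", 4), tol = 1e-9)
  sm_dirty <- median_polish_summarize(dirty, rep("g1", 4), tol = 1e-9)
  expect_equal(unname(sm_dirty), unname(sm_clean), tolerance = 0.01)

  clean[1, 1] <- Inf
  expect_error(median_polish_summarize(clean, rep("g1", 4)),
               class = "uromark_precondition_error")
})

test_that("RLE screen flags globally shifted datasets", {
  set.seed(3)
  v <- matrix(rnorm(100 * 12, 8, 0.2), 100, 12,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:12)))
  datasets <- rep(c("d1", "d2", "d3"), each = 4)
  v[, datasets == "d2"] <- v[, datasets == "d2"] + 1.0
  m <- make_matrix(v, rep("x", 12), datasets = datasets)
  rr <- rle_screen(m, bias_threshold = 0.15)
  expect_identical(rr$dataset$flagged[rr$dataset$dataset_id == "d2"], TRUE)
  expect_identical(sum(rr$dataset$flagged), 1L)
  # vacuous threshold flags nothing
  expect_false(any(rle_screen(m, bias_threshold = Inf)$dataset$flagged))

  # identical samples: all RLE medians zero, no flags
  vi <- matrix(rep(rnorm(50, 8), 4), 50, 4,
               dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:4)))
  ri <- rle_screen(make_matrix(vi, rep("x", 4)), 0.15)
  expect_identical(ri$sample$rle_median, rep(0, 4))
  expect_false(any(ri$dataset$flagged))
})

test_that("array QC metrics report scale factors and detection fractions", {
  base <- matrix(rep(seq(4, 10, length.out = 50), 5), 50, 5,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:5)))
  m <- make_matrix(base, rep("x", 5))
  qc <- array_qc_metrics(m, detect_threshold = 3)
  expect_equal(qc$scale_factor, rep(1, 5))
  expect_equal(qc$fraction_detected, rep(1, 5))

  # doubling one sample on the linear scale halves its scale factor
  doubled <- base
  doubled[, 5] <- doubled[, 5] + 1   # log2 + 1 = linear x2
  qc2 <- array_qc_metrics(make_matrix(doubled, rep("x", 5)))
  expect_equal(qc2$scale_factor[5], 0.5)
  expect_equal(qc2$scale_factor[1], 1)
})

test_that("PCA batch score separates batch structure from biology", {
  base_cfg <- function(shift) compendium_config(
    n_genes = 300, tissue_classes = c("a", "b"), datasets_per_class = 2,
    samples_per_dataset = 5, platforms = c(p1 = 1), batch_shift_sd = shift,
    prior_d0 = 10, prior_s0sq = 0.05,
    planted_sets = list(sig = list(n = 60, up_classes = "a", lfc = 2)),
    seed = 21)
  clean <- simulate_compendium(base_cfg(0))$matrix
  expect_false(pca_batch_score(clean)$flagged)

  noisy <- simulate_compendium(base_cfg(3))$matrix
  expect_true(pca_batch_score(noisy)$flagged)

  # flag invariant under gene and sample permutations
  set.seed(5)
  perm_g <- sample(nrow(noisy$values))
  perm_s <- sample(ncol(noisy$values))
  shuffled <- expression_matrix(noisy$values[perm_g, perm_s],
                                noisy$samples[perm_s, ])
  expect_identical(pca_batch_score(shuffled)$flagged,
                   pca_batch_score(noisy)$flagged)

  # single dataset: batch R^2 degenerates to 0, no flag
  one <- make_matrix(
    matrix(rnorm(200), 50, 4, dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:4))),
    rep("x", 4), datasets = rep("d1", 4))
  sc <- pca_batch_score(one)
  expect_identical(sc$pcs$batch_r2, rep(0, 2))
  expect_false(sc$flagged)

  expect_error(pca_batch_score(one, n_pcs = 10), class = "uromark_precondition_error")
})
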