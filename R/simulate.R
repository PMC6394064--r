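#' Configure a synthetic multi-tissue expression compendium
#'
#' Describes a compendium emulating pooled microarray series: several tissue
#' classes, multiple datasets (batches) per class, two platforms sharing a
#' feature subset, gene-wise variances drawn from a scaled inverse-chi-square
#' prior, and planted tissue-specific gene signatures.
#'
#' Each element of `planted_sets` is a list with fields `n` (gene count),
#' `up_classes` (classes where the signature is elevated), `lfc` (log2 effect
#' added in those classes), and optional `down_classes`/`down_lfc` (classes
#' where the signature is depleted below baseline — how a kidney-specific
#' transcript behaves in bladder or leukocytes). Planted sets are disjoint
#' and drawn from the feature subset shared by every platform.
#'
#' @param n_genes number of features.
#' @param tissue_classes character vector of class labels.
#' @param datasets_per_class datasets (batches) simulated per class.
#' @param samples_per_dataset samples per dataset.
#' @param platforms named numeric vector: fraction of features carried by
#'   each platform, in (0, 1]. Datasets cycle through platforms.
#' @param batch_shift_sd SD (log2) of the additive per-dataset shift.
#' @param prior_d0,prior_s0sq parameters of the scaled inverse-chi-square
#'   variance prior: gene variance = `prior_s0sq * prior_d0 / chisq(prior_d0)`.
#' @param planted_sets named list of planted signatures (see Details).
#' @param baseline_mean baseline log2 expression common to all genes.
#' @param seed integer seed; expanded into independent substreams per
#'   component so parts can be regenerated in isolation.
#' @return a `compendium_config` list.
#' @export
compendium_config <- function(n_genes = 2000,
                              tissue_classes = c("dkd_glom", "normal_glom",
                                                 "dkd_tub", "normal_tub",
                                                 "bladder", "bladder_cancer",
                                                 "uti"),
                              datasets_per_class = 2,
                              samples_per_dataset = 6,
                              platforms = c(u133plus2 = 1.0, u133a = 0.6),
                              batch_shift_sd = 0.3,
                              prior_d0 = 4,
                              prior_s0sq = 0.05,
                              planted_sets = list(),
                              baseline_mean = 8,
                              seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  if (length(tissue_classes) < 1 || anyDuplicated(tissue_classes)) {
    config_error("field 'tissue_classes' must be non-empty and unique")
  }
  datasets_per_class <- assert_count(datasets_per_class, "datasets_per_class")
  samples_per_dataset <- assert_count(samples_per_dataset, "samples_per_dataset")
  if (length(platforms) < 1 || is.null(names(platforms)) ||
      any(!is.finite(platforms)) || any(platforms <= 0) || any(platforms > 1)) {
    config_error("field 'platforms' must be a named vector of fractions in (0, 1]")
  }
  batch_shift_sd <- assert_number(batch_shift_sd, "batch_shift_sd", lower = 0)
  prior_d0 <- assert_number(prior_d0, "prior_d0")
  if (prior_d0 <= 0) config_error("field 'prior_d0' must be > 0")
  prior_s0sq <- assert_number(prior_s0sq, "prior_s0sq")
  if (prior_s0sq < 0) config_error("field 'prior_s0sq' must be >= 0 (0 = noiseless limit)")
  baseline_mean <- assert_number(baseline_mean, "baseline_mean")
  total_planted <- 0L
  for (nm in names(planted_sets)) {
    ps <- planted_sets[[nm]]
    ps$n <- assert_count(ps$n, sprintf("planted_sets$%s$n", nm))
    ps$lfc <- assert_number(ps$lfc, sprintf("planted_sets$%s$lfc", nm))
    if (!all(ps$up_classes %in% tissue_classes)) {
      config_error(sprintf("planted_sets$%s$up_classes: unknown tissue class", nm))
    }
    if (is.null(ps$down_classes)) ps$down_classes <- character(0)
    if (!all(ps$down_classes %in% tissue_classes)) {
      config_error(sprintf("planted_sets$%s$down_classes: unknown tissue class", nm))
    }
    if (is.null(ps$down_lfc)) ps$down_lfc <- abs(ps$lfc)
    ps$down_lfc <- assert_number(ps$down_lfc, sprintf("planted_sets$%s$down_lfc", nm), lower = 0)
    planted_sets[[nm]] <- ps
    total_planted <- total_planted + ps$n
  }
  if (total_planted > n_genes) config_error("planted_sets exceed 'n_genes'")
  structure(list(n_genes = n_genes, tissue_classes = tissue_classes,
                 datasets_per_class = datasets_per_class,
                 samples_per_dataset = samples_per_dataset,
                 platforms = platforms, batch_shift_sd = batch_shift_sd,
                 prior_d0 = prior_d0, prior_s0sq = prior_s0sq,
                 planted_sets = planted_sets, baseline_mean = baseline_mean,
                 seed = as.integer(seed)),
            class = "compendium_config")
}

#' Simulate a multi-tissue expression compendium with planted truth
#'
#' Generates log2 values as baseline + planted signature effects + additive
#' per-dataset batch shift + Normal(0, gene SD) noise, where each gene's
#' variance is drawn once from `s0sq * d0 / chisq(d0)`. Features absent from
#' a sample's platform are `NA`. The returned truth records every draw.
#'
#' @param cfg a [compendium_config()].
#' @return list with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (class `planted_truth`: `signatures`, `batch_shifts`,
#'   `gene_variance`, `platform_features`).
#' @export
simulate_compendium <- function(cfg) {
  if (!inherits(cfg, "compendium_config")) config_error("'cfg' must be a compendium_config")
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))

  # platform membership: gene carried by platform p iff u <= fraction(p);
  # the shared core (u <= min fraction) hosts the planted signatures
  set.seed(substream_seed(cfg$seed, "platform"))
  u <- stats::runif(cfg$n_genes)
  platform_features <- lapply(cfg$platforms, function(f) genes[u <= f])
  shared <- genes[u <= min(cfg$platforms)]

  set.seed(substream_seed(cfg$seed, "planted"))
  total_planted <- sum(vapply(cfg$planted_sets, `[[`, 0L, "n"))
  if (total_planted > length(shared)) {
    config_error("planted_sets exceed the cross-platform shared feature set")
  }
  pool <- sample(shared, total_planted)
  signatures <- list()
  taken <- 0L
  for (nm in names(cfg$planted_sets)) {
    n_set <- cfg$planted_sets[[nm]]$n
    signatures[[nm]] <- sort(pool[taken + seq_len(n_set)])
    taken <- taken + n_set
  }

  set.seed(substream_seed(cfg$seed, "variance"))
  gene_var <- cfg$prior_s0sq * cfg$prior_d0 / stats::rchisq(cfg$n_genes, df = cfg$prior_d0)
  names(gene_var) <- genes

  classes <- rep(cfg$tissue_classes, each = cfg$datasets_per_class)
  dataset_ids <- sprintf("%s_ds%d", classes,
                         rep(seq_len(cfg$datasets_per_class), length(cfg$tissue_classes)))
  set.seed(substream_seed(cfg$seed, "batch"))
  batch_shift <- stats::rnorm(length(dataset_ids), 0, cfg$batch_shift_sd)
  names(batch_shift) <- dataset_ids
  platform_of_dataset <- names(cfg$platforms)[
    ((seq_along(dataset_ids) - 1L) %% length(cfg$platforms)) + 1L]

  n_samples <- length(dataset_ids) * cfg$samples_per_dataset
  samples <- data.frame(
    sample_id = sprintf("s%04d", seq_len(n_samples)),
    tissue_class = rep(classes, each = cfg$samples_per_dataset),
    dataset_id = rep(dataset_ids, each = cfg$samples_per_dataset),
    platform = rep(platform_of_dataset, each = cfg$samples_per_dataset),
    stringsAsFactors = FALSE)

  # per-class signal profile: baseline + planted up/down effects
  signal <- matrix(cfg$baseline_mean, nrow = cfg$n_genes,
                   ncol = length(cfg$tissue_classes),
                   dimnames = list(genes, cfg$tissue_classes))
  for (nm in names(cfg$planted_sets)) {
    ps <- cfg$planted_sets[[nm]]
    idx <- signatures[[nm]]
    if (length(ps$up_classes)) signal[idx, ps$up_classes] <- cfg$baseline_mean + ps$lfc
    if (length(ps$down_classes)) signal[idx, ps$down_classes] <- cfg$baseline_mean - ps$down_lfc
  }

  set.seed(substream_seed(cfg$seed, "noise"))
  vals <- signal[, samples$tissue_class, drop = FALSE]
  vals <- vals + rep(batch_shift[samples$dataset_id], each = cfg$n_genes)
  vals <- vals + matrix(stats::rnorm(cfg$n_genes * n_samples, 0, sqrt(gene_var)),
                        nrow = cfg$n_genes)
  dimnames(vals) <- list(genes, samples$sample_id)

  for (p in names(cfg$platforms)) {
    absent <- setdiff(genes, platform_features[[p]])
    if (length(absent)) vals[absent, samples$platform == p] <- NA_real_
  }

  truth <- structure(list(signatures = signatures,
                          batch_shifts = batch_shift,
                          gene_variance = gene_var,
                          platform_features = platform_features),
                     class = "planted_truth")
  list(matrix = expression_matrix(vals, samples), truth = truth)
}

#' Configure a synthetic clinical cohort
#'
#' Groups with log-normal marker distributions (configured median and log-SD
#' dispersion), clinical covariates coupled to the marker through a Gaussian
#' copula that targets given Spearman rank correlations (rho is mapped to the
#' latent correlation by `2*sin(pi*rho/6)`). Covariate-covariate correlation
#' follows a single-factor model (product of their marker correlations),
#' which keeps the latent matrix positive semi-definite for any feasible
#' targets.
#'
#' @param groups named integer vector of group sizes (e.g. `c(HC = 20, ...)`).
#' @param marker_median named vector (one entry per group): group-wise median
#'   of marker relative expression, linear scale.
#' @param marker_sdlog dispersion of the marker on the natural-log scale.
#' @param covariates named list; each element a list with `median` (named per
#'   group), `sdlog`, and `spearman` (target rank correlation with the
#'   marker, in \[-1, 1\]).
#' @param housekeeping_ct mean housekeeping Ct used to synthesize target Ct
#'   values consistent with the marker's relative expression.
#' @param seed integer seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(groups, marker_median, marker_sdlog = 1,
                          covariates = list(), housekeeping_ct = 16,
                          seed = 1L) {
  if (length(groups) < 1 || is.null(names(groups))) {
    config_error("field 'groups' must be a named vector of sizes")
  }
  for (g in names(groups)) assert_count(groups[[g]], sprintf("groups$%s", g))
  if (!all(names(groups) %in% names(marker_median))) {
    config_error("field 'marker_median' must name every group")
  }
  if (any(marker_median[names(groups)] <= 0)) {
    config_error("field 'marker_median' must be > 0")
  }
  marker_sdlog <- assert_number(marker_sdlog, "marker_sdlog", lower = 0)
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (!all(names(groups) %in% names(cv$median)) || any(cv$median[names(groups)] <= 0)) {
      config_error(sprintf("covariates$%s$median must be > 0 and name every group", nm))
    }
    assert_number(cv$sdlog, sprintf("covariates$%s$sdlog", nm), lower = 0)
    assert_number(cv$spearman, sprintf("covariates$%s$spearman", nm), lower = -1, upper = 1)
  }
  structure(list(groups = groups, marker_median = marker_median,
                 marker_sdlog = marker_sdlog, covariates = covariates,
                 housekeeping_ct = assert_number(housekeeping_ct, "housekeeping_ct"),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Draw from N(0, R) where R may be rank-deficient (e.g. a comonotone pair).
rmvnorm_psd <- function(n, R) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    config_error("latent correlation matrix is not positive semi-definite after the Spearman mapping")
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(R))
  matrix(stats::rnorm(n * nrow(R)), nrow = n) %*% t(L)
}

#' Simulate a clinical cohort table
#'
#' @param cfg a [cohort_config()].
#' @return data.frame with `subject_id`, `group`, `target_ct`,
#'   `housekeeping_ct`, `relexpr` (the delta-Ct relative expression,
#'   linear), and one column per configured covariate.
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) config_error("'cfg' must be a cohort_config")
  set.seed(substream_seed(cfg$seed, "cohort"))
  rho <- vapply(cfg$covariates, `[[`, 0, "spearman")
  r <- 2 * sin(pi * rho / 6)          # Spearman -> latent Gaussian correlation
  k <- length(r)
  R <- diag(k + 1)
  if (k > 0) {
    R[1, -1] <- r
    R[-1, 1] <- r
    R[-1, -1][row(diag(k)) != col(diag(k))] <- outer(r, r)[row(diag(k)) != col(diag(k))]
  }
  out <- list()
  for (g in names(cfg$groups)) {
    n <- cfg$groups[[g]]
    Z <- rmvnorm_psd(n, R)
    marker <- cfg$marker_median[[g]] * exp(cfg$marker_sdlog * Z[, 1])
    row <- data.frame(group = rep(g, n), relexpr = marker,
                      stringsAsFactors = FALSE)
    for (j in seq_along(cfg$covariates)) {
      cv <- cfg$covariates[[j]]
      row[[names(cfg$covariates)[j]]] <- cv$median[[g]] * exp(cv$sdlog * Z[, j + 1])
    }
    out[[g]] <- row
  }
  out <- do.call(rbind, out)
  out$subject_id <- sprintf("p%04d", seq_len(nrow(out)))
  out$housekeeping_ct <- cfg$housekeeping_ct
  out$target_ct <- out$housekeeping_ct - log2(out$relexpr)
  rownames(out) <- NULL
  out[, c("subject_id", "group", "target_ct", "housekeeping_ct", "relexpr",
          names(cfg$covariates))]
}

#' Configure / simulate a qPCR dilution series
#'
#' Replicate Ct values follow the linear dilution response
#' `Ct = intercept - slope * log10(amount_ng)` plus Normal replicate noise.
#'
#' @param amounts_ng input RNA amounts (ng), strictly positive and distinct.
#' @param replicates replicates per amount (>= 2).
#' @param intercept_ct named vector: per-gene Ct at 1 ng.
#' @param slope_ct Ct change per log10(ng) (positive = fewer cycles with more
#'   input).
#' @param noise_sd replicate noise SD in Ct units.
#' @param seed integer seed.
#' @return a `dilution_config` list.
#' @export
dilution_config <- function(amounts_ng = c(500, 50, 5, 0.5), replicates = 3,
                            intercept_ct = c(BBOX1 = 34, B2M = 25),
                            slope_ct = 3.32, noise_sd = 0.1, seed = 1L) {
  if (any(!is.finite(amounts_ng)) || any(amounts_ng <= 0)) {
    config_error("field 'amounts_ng' must be strictly positive")
  }
  if (anyDuplicated(amounts_ng)) config_error("field 'amounts_ng' must be distinct")
  replicates <- assert_count(replicates, "replicates")
  if (replicates < 2) config_error("field 'replicates' must be >= 2")
  if (is.null(names(intercept_ct)) || any(!is.finite(intercept_ct))) {
    config_error("field 'intercept_ct' must be a named finite vector")
  }
  structure(list(amounts_ng = amounts_ng, replicates = replicates,
                 intercept_ct = intercept_ct,
                 slope_ct = assert_number(slope_ct, "slope_ct"),
                 noise_sd = assert_number(noise_sd, "noise_sd", lower = 0),
                 seed = as.integer(seed)),
            class = "dilution_config")
}

#' @rdname dilution_config
#' @param cfg a `dilution_config`.
#' @return `simulate_dilution_series` returns a long data.frame with columns
#'   `gene`, `amount_ng`, `replicate`, `ct`.
#' @export
simulate_dilution_series <- function(cfg) {
  if (!inherits(cfg, "dilution_config")) config_error("'cfg' must be a dilution_config")
  set.seed(substream_seed(cfg$seed, "dilution"))
  grid <- expand.grid(replicate = seq_len(cfg$replicates),
                      amount_ng = cfg$amounts_ng,
                      gene = names(cfg$intercept_ct),
                      stringsAsFactors = FALSE)
  grid$ct <- cfg$intercept_ct[grid$gene] - cfg$slope_ct * log10(grid$amount_ng) +
    stats::rnorm(nrow(grid), 0, cfg$noise_sd)
  grid[, c("gene", "amount_ng", "replicate", "ct")]
}
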