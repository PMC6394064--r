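#' Default screening fixture configuration
#'
#' The packaged study-shaped simulation: 2000 genes across the seven tissue
#' classes (diseased and normal glomeruli and tubules, bladder, bladder
#' cancer, UTI leukocytes), two datasets per class on two platforms sharing
#' 60% of features, gene variances from the scaled inverse-chi-square prior
#' (d0 = 4, s0sq = 0.05), and three planted signatures: 20 kidney-disease
#' genes (+2 log2 in diseased compartments, depleted -2 log2 in confounder
#' tissues — the profile of a urinary kidney-specific marker), 30
#' bladder/bladder-cancer-high genes and 30 leukocyte-high genes (+3 log2).
#'
#' @param seed integer seed.
#' @return a [compendium_config()].
#' @export
default_compendium_config <- function(seed = 1L) {
  compendium_config(
    n_genes = 2000,
    datasets_per_class = 2,
    samples_per_dataset = 6,
    batch_shift_sd = 0.3,
    prior_d0 = 4, prior_s0sq = 0.05,
    baseline_mean = 8,
    planted_sets = list(
      kidney_disease = list(n = 20, up_classes = c("dkd_glom", "dkd_tub"),
                            lfc = 2,
                            down_classes = c("bladder", "bladder_cancer", "uti"),
                            down_lfc = 2),
      bladder_high = list(n = 30, up_classes = c("bladder", "bladder_cancer"),
                          lfc = 3),
      leukocyte_high = list(n = 30, up_classes = "uti", lfc = 3)),
    seed = seed)
}

#' Screening run configuration
#'
#' Thresholds of the screening pipeline with their defaults: DEG call at
#' BH-adjusted p < `alpha` with linear fold change > `fc_min`; RLE dataset
#' bias flag at `rle_bias_threshold` log2; PCA batch flag at
#' `batch_r2_threshold` over `n_pcs` components; low-expression confounder
#' filter at `percentile`; `top_k` candidates per rule and compartment.
#'
#' @param alpha adjusted-p threshold for DEG calls.
#' @param fc_min minimum linear fold change for DEG calls.
#' @param rle_bias_threshold dataset RLE bias flag threshold (log2).
#' @param n_pcs,batch_r2_threshold PCA batch-detection settings.
#' @param percentile low-expression filter percentile.
#' @param top_k candidates retained per rule per compartment.
#' @return a `screen_config` list.
#' @export
screen_config <- function(alpha = 0.05, fc_min = 2, rle_bias_threshold = 0.15,
                          n_pcs = 2, batch_r2_threshold = 0.5,
                          percentile = 25, top_k = 8) {
  if (alpha < 0 || alpha > 1) config_error("field 'alpha' must be in [0, 1]")
  if (fc_min < 1) config_error("field 'fc_min' must be >= 1")
  structure(list(alpha = alpha, fc_min = fc_min,
                 rle_bias_threshold = assert_number(rle_bias_threshold, "rle_bias_threshold", lower = 0),
                 n_pcs = assert_count(n_pcs, "n_pcs"),
                 batch_r2_threshold = assert_number(batch_r2_threshold, "batch_r2_threshold", lower = 0, upper = 1),
                 percentile = percentile,
                 top_k = assert_count(top_k, "top_k")),
            class = "screen_config")
}

#' Split a compendium by platform
#'
#' Splits a matrix with platform-dependent missing features into complete
#' per-platform matrices (dropping features absent from that platform),
#' ready for [intersect_platform_features()].
#'
#' @param m an [expression_matrix()].
#' @return named list of complete [expression_matrix()] objects, one per
#'   platform.
#' @export
split_by_platform <- function(m) {
  lapply(split(seq_len(ncol(m$values)), m$samples$platform), function(idx) {
    sub <- subset_samples(m, idx)
    complete <- rowSums(is.na(sub$values)) == 0
    expression_matrix(sub$values[complete, , drop = FALSE], sub$samples)
  })
}

# The per-compartment contrast set of the two-rule screen.
compartment_contrasts <- function(disease, normal,
                                  confounders = c("bladder", "bladder_cancer", "uti")) {
  specs <- c(list(contrast_spec(disease, normal)),
             lapply(confounders, function(cc) contrast_spec(disease, cc)))
  names(specs) <- c(sprintf("%s_vs_%s", disease, normal),
                    sprintf("%s_vs_%s", disease, confounders))
  specs
}

#' Run the candidate-screening pipeline end to end
#'
#' Harmonizes (platform split, shared-feature intersection, quantile
#' normalization), runs QC (RLE screen, array metrics, PCA batch score),
#' fits every per-compartment contrast with the empirical-Bayes moderated t,
#' and applies the type 1 and type 2 screening rules per compartment.
#' Thresholds and per-stage feature/sample counts are recorded in the
#' returned `log`; with `out_dir` set, candidates, QC and per-contrast
#' tables are written as TSV/JSON.
#'
#' @param m an [expression_matrix()] compendium (missing values allowed for
#'   platform-absent features), or a list of per-platform matrices.
#' @param config a [screen_config()].
#' @param compartments named list mapping a compartment label to
#'   `c(disease, normal)` tissue classes.
#' @param confounder_classes the three confounder tissue classes, in the
#'   order bladder, bladder-cancer, UTI.
#' @param out_dir optional output directory.
#' @return list with `candidates` (combined candidate table), `qc`,
#'   `contrasts` (per-compartment result lists), `priors`, and `log`.
#' @export
run_screen <- function(m, config = screen_config(),
                       compartments = list(glomeruli = c("dkd_glom", "normal_glom"),
                                           tubules = c("dkd_tub", "normal_tub")),
                       confounder_classes = c("bladder", "bladder_cancer", "uti"),
                       out_dir = NULL) {
  if (!inherits(config, "screen_config")) config_error("'config' must be a screen_config")
  log_lines <- sprintf(
    "thresholds: alpha=%g fc_min=%g rle_bias=%g n_pcs=%d batch_r2=%g percentile=%g top_k=%d",
    config$alpha, config$fc_min, config$rle_bias_threshold, config$n_pcs,
    config$batch_r2_threshold, config$percentile, config$top_k)

  mats <- if (inherits(m, "expression_matrix")) split_by_platform(m) else m
  log_lines <- c(log_lines, sprintf(
    "platform inputs: %s",
    paste(vapply(mats, function(x) sprintf("%dx%d", nrow(x$values), ncol(x$values)),
                 ""), collapse = ", ")))
  pooled <- intersect_platform_features(mats)
  log_lines <- c(log_lines, sprintf("pooled shared features: %d genes x %d samples",
                                    nrow(pooled$values), ncol(pooled$values)))
  norm <- quantile_normalize(pooled)

  qc <- list(rle = rle_screen(norm, config$rle_bias_threshold),
             metrics = array_qc_metrics(norm),
             pca = pca_batch_score(norm, config$n_pcs, config$batch_r2_threshold))
  log_lines <- c(log_lines,
                 sprintf("RLE-flagged datasets: %d", sum(qc$rle$dataset$flagged)),
                 sprintf("PCA batch flag: %s", qc$pca$flagged))

  contrasts <- list()
  candidates <- list()
  priors <- list()
  for (comp in names(compartments)) {
    disease <- compartments[[comp]][1]
    normal <- compartments[[comp]][2]
    specs <- compartment_contrasts(disease, normal, confounder_classes)
    results <- lapply(specs, function(cs) {
      run_contrast(norm, cs, alpha = config$alpha, fc_min = config$fc_min)
    })
    contrasts[[comp]] <- results
    priors[[comp]] <- lapply(results, attr, "prior")
    vs_normal <- sprintf("%s_vs_%s", disease, normal)
    vs_bladder <- sprintf("%s_vs_%s", disease, confounder_classes[1])
    rule1 <- screen_rule("type1", comp, required_up = names(specs),
                         ranking = vs_normal, low_classes = confounder_classes,
                         percentile = config$percentile, top_k = config$top_k)
    rule2 <- screen_rule("type2", comp,
                         required_up = setdiff(names(specs), vs_normal),
                         ranking = vs_bladder,
                         low_classes = confounder_classes[-1],
                         percentile = config$percentile, top_k = config$top_k)
    for (rule in list(rule1, rule2)) {
      tab <- select_candidates(results, norm, rule)
      key <- sprintf("%s_%s", rule$rule_type, comp)
      log_lines <- c(log_lines, sprintf("%s: %d candidates", key, nrow(tab)))
      candidates[[key]] <- tab
    }
  }
  common_cols <- c("gene", "rule_type", "compartment", "rank_fc")
  cand_all <- do.call(rbind, c(lapply(candidates, function(d) d[common_cols]),
                               make.row.names = FALSE))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_tsv(cand_all, file.path(out_dir, "candidates.tsv"))
    jsonlite::write_json(
      list(rle = qc$rle, metrics = qc$metrics,
           pca = list(pcs = qc$pca$pcs, flagged = qc$pca$flagged),
           log = log_lines),
      file.path(out_dir, "qc.json"), dataframe = "columns", digits = NA,
      auto_unbox = TRUE, pretty = TRUE)
    for (comp in names(contrasts)) {
      for (cn in names(contrasts[[comp]])) {
        write_table_tsv(contrasts[[comp]][[cn]],
                        file.path(out_dir, sprintf("contrast_%s.tsv", cn)))
      }
    }
    writeLines(log_lines, file.path(out_dir, "screen.log"))
  }
  list(candidates = cand_all, per_rule = candidates, qc = qc,
       contrasts = contrasts, priors = priors, log = log_lines)
}

#' Run the clinical verification report
#'
#' Per marker: group medians with IQR, fold of medians versus the control
#' group, Kruskal-Wallis across groups, pairwise rank-sum tests with BH
#' adjustment, Spearman correlation against each covariate, ROC analysis
#' for each configured test-versus-control grouping, and the replicate CV
#' report when a dilution series is supplied.
#'
#' @param cohort cohort data.frame (as from [simulate_cohort()] or
#'   [read_cohort_tsv()]): `group` column plus marker and covariate columns.
#' @param marker_cols names of marker (relative expression) columns.
#' @param covariate_cols names of clinical covariate columns.
#' @param roc_groupings named list; each element a list with `test` and
#'   `control` vectors of group labels.
#' @param control_group reference group for fold-of-medians.
#' @param dilution optional dilution-series data.frame for [cv_report()].
#' @param out optional path of a JSON report.
#' @return nested list report (one element per marker, plus `cv`).
#' @export
run_clinical <- function(cohort, marker_cols = "relexpr",
                         covariate_cols = character(0),
                         roc_groupings = list(),
                         control_group = "HC",
                         dilution = NULL, out = NULL) {
  known <- unique(cohort$group)
  for (rg in roc_groupings) {
    bad <- setdiff(c(rg$test, rg$control), known)
    if (length(bad)) {
      validation_error(sprintf("unknown group label: %s", paste(bad, collapse = ", ")))
    }
  }
  report <- list()
  for (mk in marker_cols) {
    vals <- split(cohort[[mk]], cohort$group)
    med <- lapply(vals, function(v) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      list(median = q[2], iqr_low = q[1], iqr_high = q[3], n = length(v))
    })
    entry <- list(groups = med)
    if (control_group %in% names(vals) && length(vals) > 1) {
      others <- setdiff(names(vals), control_group)
      entry$fold_of_medians <- lapply(
        structure(others, names = others),
        function(g) fold_of_medians(vals[[g]], vals[[control_group]]))
    }
    if (length(vals) > 1) {
      entry$kruskal_wallis <- kruskal_wallis(vals)
      entry$pairwise <- pairwise_tests(vals)
    }
    if (length(covariate_cols)) {
      entry$spearman <- lapply(
        structure(covariate_cols, names = covariate_cols),
        function(cv) spearman_cor(cohort[[mk]], cohort[[cv]]))
    }
    if (length(roc_groupings)) {
      entry$roc <- lapply(roc_groupings, function(rg) {
        keep <- cohort$group %in% c(rg$test, rg$control)
        r <- roc_analysis(cohort[[mk]][keep], cohort$group[keep] %in% rg$test)
        r$curve <- NULL
        unclass(r)
      })
    }
    report[[mk]] <- entry
  }
  if (!is.null(dilution)) report$cv <- cv_report(dilution)
  if (!is.null(out)) {
    jsonlite::write_json(report, out, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}
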