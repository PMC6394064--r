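#' Pool matrices onto the feature set shared by all platforms
#'
#' Mirrors the shared-identifier step of pooling series from different array
#' generations: output features are the set intersection of all inputs'
#' feature sets (lexicographically sorted, for deterministic output), and
#' samples are concatenated in input order with annotations preserved.
#'
#' @param matrices list of [expression_matrix()] objects.
#' @return an [expression_matrix()] on the shared features.
#' @export
intersect_platform_features <- function(matrices) {
  if (!length(matrices)) precondition_error("need at least one input matrix")
  feats <- lapply(matrices, function(m) rownames(m$values))
  if (any(lengths(feats) == 0)) precondition_error("each input needs >= 1 feature")
  shared <- sort(Reduce(intersect, feats))
  if (!length(shared)) {
    pairs <- utils::combn(length(feats), 2)
    overlaps <- apply(pairs, 2, function(ij) {
      sprintf("%d~%d:%d", ij[1], ij[2],
              length(intersect(feats[[ij[1]]], feats[[ij[2]]])))
    })
    harmonization_error(sprintf(
      "no features shared by all inputs (pairwise overlaps: %s)",
      paste(overlaps, collapse = ", ")))
  }
  vals <- do.call(cbind, lapply(matrices, function(m) m$values[shared, , drop = FALSE]))
  samples <- do.call(rbind, lapply(matrices, `[[`, "samples"))
  rownames(samples) <- NULL
  expression_matrix(vals, samples)
}

#' Quantile normalization
#'
#' Forces every sample to the same distribution: after normalization each
#' sample's sorted values equal the across-sample mean of sorted values.
#' Tied values within a sample receive the mean of the reference quantiles
#' across their tied ranks, so the result is deterministic and invariant to
#' input order; within-sample rank order is preserved.
#'
#' @param m an [expression_matrix()] with no missing values and >= 2 samples.
#' @return the normalized [expression_matrix()].
#' @export
quantile_normalize <- function(m) {
  vals <- m$values
  if (anyNA(vals)) precondition_error("quantile normalization requires a complete matrix; harmonize platforms first")
  if (ncol(vals) < 2) precondition_error("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(vals, 2, sort, method = "radix"))
  out <- vals
  for (j in seq_len(ncol(vals))) {
    o <- order(vals[, j])
    runs <- rle(vals[o, j])
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    # mean of reference quantiles over each tie run
    repl <- rep(vapply(seq_along(runs$lengths),
                       function(k) mean(ref[starts[k]:ends[k]]), 0),
                runs$lengths)
    out[o, j] <- repl
  }
  expression_matrix(out, m$samples)
}

#' Median-polish summarization of probe-level values
#'
#' Tukey median polish per gene over its probe rows (alternating row/column
#' median sweeps via [stats::medpolish()] until the maximum absolute change
#' drops below `tol` or `max_iter` sweeps); the per-sample summary is the
#' overall effect plus the column effect. Single-probe genes pass through
#' unchanged.
#'
#' @param probe_matrix numeric matrix, probes x samples, finite values.
#' @param probe_gene character vector mapping each probe row to a gene.
#' @param max_iter maximum polish sweeps.
#' @param tol convergence threshold on the absolute change.
#' @return genes x samples summary matrix (genes in first-appearance order).
#' @export
median_polish_summarize <- function(probe_matrix, probe_gene,
                                    max_iter = 10, tol = 0.01) {
  if (!is.matrix(probe_matrix) || any(!is.finite(probe_matrix))) {
    precondition_error("probe matrix must be numeric and finite")
  }
  if (length(probe_gene) != nrow(probe_matrix)) {
    precondition_error("'probe_gene' must map every probe row")
  }
  genes <- unique(probe_gene)
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(probe_matrix),
                dimnames = list(genes, colnames(probe_matrix)))
  for (g in genes) {
    sub <- probe_matrix[probe_gene == g, , drop = FALSE]
    if (nrow(sub) == 1) {
      out[g, ] <- sub[1, ]
    } else {
      mp <- stats::medpolish(sub, eps = tol, maxiter = max_iter,
                             trace.iter = FALSE)
      out[g, ] <- mp$overall + mp$col
    }
  }
  out
}

#' Relative log expression (RLE) screening
#'
#' RLE(gene, sample) = value minus the across-sample median of that gene.
#' Reports each sample's RLE median and IQR and flags a dataset when the
#' median of its samples' absolute RLE medians exceeds `bias_threshold`
#' (log2). Datasets flagged here are the "significant bias" batches to drop
#' before pooling.
#'
#' @param m an [expression_matrix()] with >= 2 samples.
#' @param bias_threshold flagging threshold on the dataset-level median
#'   absolute RLE median, log2 units.
#' @return list with `sample` (per-sample `rle_median`, `rle_iqr`) and
#'   `dataset` (per-dataset `bias`, `flagged`) data.frames.
#' @export
rle_screen <- function(m, bias_threshold = 0.15) {
  vals <- m$values
  if (ncol(vals) < 2) precondition_error("RLE needs >= 2 samples")
  if (anyNA(vals)) precondition_error("RLE requires a complete matrix")
  rle_vals <- vals - apply(vals, 1, stats::median)
  med <- apply(rle_vals, 2, stats::median)
  iqr <- apply(rle_vals, 2, stats::IQR)
  sample_df <- data.frame(sample_id = colnames(vals), rle_median = med,
                          rle_iqr = iqr, row.names = NULL,
                          stringsAsFactors = FALSE)
  ds <- m$samples$dataset_id
  bias <- tapply(abs(med), ds, stats::median)
  dataset_df <- data.frame(dataset_id = names(bias),
                           bias = as.numeric(bias),
                           flagged = as.numeric(bias) > bias_threshold,
                           row.names = NULL, stringsAsFactors = FALSE)
  list(sample = sample_df, dataset = dataset_df)
}

#' Matrix-level array QC metrics
#'
#' Proxies for probe-level QC statistics: a per-sample scale factor (the
#' median across samples of 2%-trimmed linear-scale means, divided by the
#' sample's own trimmed mean) and the fraction of features detected above a
#' log2 threshold.
#'
#' @param m an [expression_matrix()].
#' @param detect_threshold log2 intensity above which a feature counts as
#'   detected.
#' @return data.frame with `sample_id`, `scale_factor`, `fraction_detected`.
#' @export
array_qc_metrics <- function(m, detect_threshold = 5) {
  vals <- m$values
  if (ncol(vals) < 1) precondition_error("need >= 1 sample")
  if (anyNA(vals)) precondition_error("QC metrics require a complete matrix")
  lin <- 2^vals
  tm <- apply(lin, 2, mean, trim = 0.02)
  target <- stats::median(tm)
  data.frame(sample_id = colnames(vals),
             scale_factor = target / tm,
             fraction_detected = colMeans(vals > detect_threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Between-group R^2 of a score vector given a grouping (between-group SS over
# total SS); 0 when the grouping has a single level or the score is constant.
group_r2 <- function(score, grouping) {
  grouping <- as.factor(grouping)
  tot <- sum((score - mean(score))^2)
  if (nlevels(grouping) < 2 || tot < .Machine$double.eps) return(0)
  gm <- tapply(score, grouping, mean)
  between <- sum(tabulate(grouping) * (gm - mean(score))^2)
  as.numeric(between / tot)
}

#' PCA-based batch-effect score
#'
#' Gene-centered SVD of the sample space; for each of the first `n_pcs`
#' principal components, the share of score variance explained by
#' tissue-class labels (biology R^2) and the *incremental* share explained
#' by dataset labels beyond tissue class (batch R^2). Datasets are nested
#' within tissue classes, so the raw dataset R^2 always contains the biology
#' signal; the increment isolates genuine batch structure. The batch flag is
#' raised when any PC has batch R^2 above `batch_r2_threshold` and above
#' that PC's biology R^2 — batch structure dominating biology.
#'
#' @param m an [expression_matrix()] with >= 3 samples and >= `n_pcs`
#'   features.
#' @param n_pcs number of leading PCs to inspect.
#' @param batch_r2_threshold flagging threshold on batch R^2.
#' @return list with `pcs` (per-PC `batch_r2`, `biology_r2`,
#'   `var_explained`) and `flagged` (logical).
#' @export
pca_batch_score <- function(m, n_pcs = 2, batch_r2_threshold = 0.5) {
  vals <- m$values
  if (anyNA(vals)) precondition_error("PCA requires a complete matrix")
  if (ncol(vals) < 3) precondition_error("PCA needs >= 3 samples")
  if (n_pcs > ncol(vals)) precondition_error("'n_pcs' exceeds the sample count")
  if (nrow(vals) < n_pcs) precondition_error("fewer features than 'n_pcs'")
  centered <- vals - rowMeans(vals)
  sv <- svd(t(centered), nu = n_pcs, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  dataset_r2 <- apply(scores, 2, group_r2, grouping = m$samples$dataset_id)
  biology_r2 <- apply(scores, 2, group_r2, grouping = m$samples$tissue_class)
  pcs <- data.frame(
    pc = seq_len(n_pcs),
    batch_r2 = pmax(dataset_r2 - biology_r2, 0),
    biology_r2 = biology_r2,
    var_explained = sv$d[seq_len(n_pcs)]^2 / sum(sv$d^2))
  flagged <- any(pcs$batch_r2 > batch_r2_threshold & pcs$batch_r2 > pcs$biology_r2)
  list(pcs = pcs, flagged = flagged)
}
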