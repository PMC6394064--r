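# Small in-code fixtures shared across test files.

# Minimal annotated matrix: one dataset per class, one platform.
make_matrix <- function(values, classes, datasets = NULL, platform = "p1") {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", seq_len(n))
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(datasets)) datasets <- paste0(classes, "_ds1")
  expression_matrix(values, data.frame(
    sample_id = colnames(values), tissue_class = classes,
    dataset_id = datasets, platform = platform,
    stringsAsFactors = FALSE))
}

# Two-class matrix with iid normal noise (null unless delta given).
make_two_class <- function(n_genes, n_per_class, sd = 0.3, delta = 0,
                           delta_genes = integer(0), seed = 1,
                           classes = c("caseA", "caseB")) {
  set.seed(seed)
  vals <- matrix(stats::rnorm(n_genes * 2 * n_per_class, 8, sd),
                 nrow = n_genes)
  if (length(delta_genes)) {
    vals[delta_genes, seq_len(n_per_class)] <-
      vals[delta_genes, seq_len(n_per_class)] + delta
  }
  make_matrix(vals, rep(classes, each = n_per_class))
}

# Printed replicate Ct values of the dilution-series reproducibility table
# (target gene and housekeeping gene at 500/50/5/0.5 ng input RNA).
dilution_table_fixture <- function() {
  data.frame(
    gene = rep(c("BBOX1", "B2M"), each = 12),
    amount_ng = rep(rep(c(500, 50, 5, 0.5), each = 3), 2),
    replicate = rep(1:3, 8),
    ct = c(25.29, 25.54, 25.38, 28.19, 28.26, 28.24,
           31.55, 31.43, 31.42, 33.87, 33.86, 34.06,
           15.51, 15.58, 15.52, 18.84, 18.81, 18.85,
           22.25, 22.29, 22.20, 25.74, 25.73, 25.71),
    stringsAsFactors = FALSE)
}

# Brute-force BH oracle: q_i = min over j with p_j >= p_i of p_j * m / rank_j.
bh_bruteforce <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min(p[p >= p[i]] * m / r[p >= p[i]]))
  }, 0)
}
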