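#' Construct an annotated expression matrix
#'
#' Container for a log2-scale genes x samples matrix plus per-sample
#' annotations (tissue class, dataset, platform). Missing values are allowed
#' before harmonization (features absent from a platform) and forbidden
#' afterwards.
#'
#' @param values numeric matrix, features in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample IDs), log2 scale.
#' @param samples data.frame with columns `sample_id`, `tissue_class`,
#'   `dataset_id`, `platform`; one row per column of `values`, same order.
#' @return an object of class `expression_matrix`: a list with elements
#'   `values` and `samples`.
#' @export
expression_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    validation_error("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    validation_error("'values' must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) validation_error("duplicate gene IDs")
  if (anyDuplicated(colnames(values))) validation_error("duplicate sample IDs")
  required <- c("sample_id", "tissue_class", "dataset_id", "platform")
  if (!is.data.frame(samples) || !all(required %in% names(samples))) {
    validation_error(sprintf("sample sheet must contain columns: %s",
                             paste(required, collapse = ", ")))
  }
  if (nrow(samples) != ncol(values) ||
      !identical(as.character(samples$sample_id), colnames(values))) {
    validation_error("sample sheet rows must match matrix columns (same IDs, same order)")
  }
  samples <- as.data.frame(lapply(samples, as.character),
                           stringsAsFactors = FALSE)
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  tissue classes: %s\n",
              paste(unique(x$samples$tissue_class), collapse = ", ")))
  cat(sprintf("  datasets: %d; platforms: %s; missing values: %d\n",
              length(unique(x$samples$dataset_id)),
              paste(unique(x$samples$platform), collapse = ", "),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Column subset keeping annotations in sync.
subset_samples <- function(m, keep) {
  expression_matrix(m$values[, keep, drop = FALSE],
                    m$samples[keep, , drop = FALSE])
}

#' Write / read an expression matrix as TSV
#'
#' The matrix file is tab-delimited with a `gene_id` first column and one
#' column per sample; the paired sample sheet holds the annotations.
#' Round-tripping reproduces values to better than 1e-12 and annotations
#' exactly.
#'
#' @param m an `expression_matrix`.
#' @param path path of the matrix TSV.
#' @param sample_sheet_path path of the sample sheet TSV.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an `expression_matrix`.
#' @export
write_expression_tsv <- function(m, path, sample_sheet_path) {
  vals <- m$values
  header <- paste(c("gene_id", colnames(vals)), collapse = "\t")
  body <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(rownames(vals)[i],
            ifelse(is.na(vals[i, ]), "", sprintf("%.17g", vals[i, ]))),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  utils::write.table(m$samples, sample_sheet_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, sample_sheet_path) {
  lines <- readLines(path)
  if (length(lines) < 2) parse_error(sprintf("'%s': empty or header-only file", path))
  # sentinel keeps strsplit from dropping trailing empty (missing-value) cells
  fields <- lapply(strsplit(paste0(lines, "\t."), "\t", fixed = TRUE),
                   function(x) x[-length(x)])
  header <- fields[[1]]
  if (header[1] != "gene_id") parse_error(sprintf("'%s' line 1: first column must be 'gene_id'", path))
  ncol_expected <- length(header)
  sample_ids <- header[-1]
  n <- length(lines) - 1L
  gene_ids <- character(n)
  vals <- matrix(NA_real_, nrow = n, ncol = length(sample_ids))
  for (i in seq_len(n)) {
    row <- fields[[i + 1L]]
    if (length(row) != ncol_expected) {
      parse_error(sprintf("'%s' line %d: expected %d fields, got %d",
                          path, i + 1L, ncol_expected, length(row)))
    }
    gene_ids[i] <- row[1]
    cells <- row[-1]
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & cells != "")
    if (length(bad)) {
      parse_error(sprintf("'%s' line %d: non-numeric cell '%s'",
                          path, i + 1L, cells[bad[1]]))
    }
    vals[i, ] <- num
  }
  if (anyDuplicated(gene_ids)) {
    parse_error(sprintf("'%s': duplicate gene ID '%s'",
                        path, gene_ids[anyDuplicated(gene_ids)]))
  }
  rownames(vals) <- gene_ids
  colnames(vals) <- sample_ids
  samples <- utils::read.delim(sample_sheet_path, colClasses = "character")
  expression_matrix(vals, samples)
}

#' Read / write cohort and dilution tables
#'
#' Cohort tables are subject-level TSVs (columns: `subject_id`, `group`,
#' marker/Ct columns, covariates); dilution tables are long-format TSVs with
#' columns `gene`, `amount_ng`, `replicate`, `ct`.
#'
#' @param x data.frame to write.
#' @param path TSV path.
#' @return the data.frame (readers) or `path` invisibly (writers).
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_cohort_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(x))) {
    parse_error(sprintf("'%s': cohort table needs 'subject_id' and 'group' columns", path))
  }
  x
}

#' @rdname write_table_tsv
#' @export
read_dilution_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "amount_ng", "replicate", "ct")
  if (!all(need %in% names(x))) {
    parse_error(sprintf("'%s': dilution table needs columns %s",
                        path, paste(need, collapse = ", ")))
  }
  x
}
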