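#' Define a two-group contrast
#'
#' @param test tissue-class label of the test (disease) group; log2 fold
#'   changes are oriented test minus reference.
#' @param reference tissue-class label of the reference group.
#' @param min_n minimum samples required on each side.
#' @return a `contrast_spec` list.
#' @export
contrast_spec <- function(test, reference, min_n = 2) {
  if (identical(test, reference)) config_error("contrast labels must be distinct")
  structure(list(test = test, reference = reference,
                 min_n = assert_count(min_n, "min_n")),
            class = "contrast_spec")
}

#' Per-gene two-group summaries
#'
#' Group means on the log2 scale, log2 fold change (test minus reference),
#' and the pooled residual variance with `n1 + n2 - 2` degrees of freedom —
#' the raw ingredients of the moderated test.
#'
#' @param m an [expression_matrix()] (complete, harmonized).
#' @param contrast a [contrast_spec()].
#' @return data.frame with `gene`, `mean_test`, `mean_ref`, `lfc`, `s2`,
#'   `df`; attributes `n1`, `n2` carry the group sizes.
#' @export
fit_gene_stats <- function(m, contrast) {
  cls <- m$samples$tissue_class
  for (side in c("test", "reference")) {
    if (!contrast[[side]] %in% cls) {
      contrast_error(sprintf("class '%s' absent from the sample sheet", contrast[[side]]))
    }
  }
  x1 <- m$values[, cls == contrast$test, drop = FALSE]
  x2 <- m$values[, cls == contrast$reference, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < max(2, contrast$min_n) || n2 < max(2, contrast$min_n)) {
    contrast_error(sprintf("contrast %s vs %s needs >= %d samples per side (got %d, %d)",
                           contrast$test, contrast$reference,
                           max(2, contrast$min_n), n1, n2))
  }
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2L
  out <- data.frame(gene = rownames(m$values), mean_test = m1, mean_ref = m2,
                    lfc = m1 - m2, s2 = (ss1 + ss2) / df, df = df,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  out
}

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(x) = y` to relative tolerance 1e-8
#' (at most 50 iterations), with asymptotic starts for extreme `y`.
#'
#' @param y positive target value(s).
#' @return x such that `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) estimation_error("trigamma_inverse needs y > 0")
    # asymptotic starting values, then Newton in all regimes
    x <- if (yi > 1e7) 1 / sqrt(yi) else if (yi < 1e-6) 1 / yi else 0.5 + 1 / yi
    for (iter in seq_len(50)) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif) / x < 1e-8) break
    }
    x
  }, 0)
}

#' Estimate the variance-shrinkage prior
#'
#' Fits the scaled inverse-chi-square prior (`d0`, `s0sq`) to the observed
#' gene-wise residual variances by the log-F moment method: with
#' `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`, the prior degrees of
#' freedom solve `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` via the
#' trigamma inverse, and `s0sq = exp(mean(e) + digamma(d0/2) - log(d0/2))`.
#' When the moment right-hand side is non-positive the variances are
#' consistent with a common value and `d0 = Inf`, `s0sq = exp(mean(e))`.
#'
#' @param s2 per-gene residual variances (floored at 1e-8).
#' @param df per-gene residual degrees of freedom (scalar or vector).
#' @return a `shrinkage_prior` list with `d0` and `s0sq`.
#' @export
estimate_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  s2 <- pmax(s2, 1e-8)
  usable <- is.finite(s2) & df >= 1
  if (sum(usable) < 10) estimation_error("need >= 10 genes with df >= 1 to estimate the prior")
  s2 <- s2[usable]; df <- df[usable]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (!is.finite(evar) || evar <= 0) {
    prior <- list(d0 = Inf, s0sq = exp(emean))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    prior <- list(d0 = d0, s0sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
  structure(prior, class = "shrinkage_prior")
}

#' Moderated t-statistics
#'
#' Shrinks each gene's variance toward the prior,
#' `s2_post = (d0*s0sq + df*s2) / (d0 + df)` (with `d0 = Inf` giving
#' `s0sq`), and tests the log2 fold change with
#' `t = lfc / sqrt(s2_post * (1/n1 + 1/n2))` on `d0 + df` degrees of
#' freedom (normal when infinite). `d0 = 0` recovers the ordinary pooled
#' two-sample t.
#'
#' @param stats output of [fit_gene_stats()].
#' @param prior a `shrinkage_prior` (or any list with `d0 >= 0`, `s0sq > 0`).
#' @param n1,n2 group sizes; default taken from `stats` attributes.
#' @return `stats` with added columns `s2_post`, `t`, `p`.
#' @export
moderated_t <- function(stats, prior, n1 = attr(stats, "n1"),
                        n2 = attr(stats, "n2")) {
  if (is.null(prior$d0) || is.null(prior$s0sq) || prior$d0 < 0 || prior$s0sq <= 0) {
    validation_error("prior must have d0 >= 0 and s0sq > 0")
  }
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) {
    rep(prior$s0sq, nrow(stats))
  } else {
    (d0 * prior$s0sq + stats$df * stats$s2) / (d0 + stats$df)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tval <- stats$lfc / se
  df_total <- d0 + stats$df
  p <- if (is.infinite(d0)) {
    2 * stats::pnorm(-abs(tval))
  } else {
    2 * stats::pt(-abs(tval), df = df_total)
  }
  stats$s2_post <- s2_post
  stats$t <- tval
  stats$p <- p
  attr(stats, "df_total") <- df_total
  stats
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper over [stats::p.adjust()] with `method = "BH"`:
#' ascending p-values are scaled by `m/rank`, made monotone from the largest
#' rank downward, capped at 1, and returned in input order.
#'
#' @param p raw p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    validation_error("p-values must be finite and within [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' The screening call: `up` when adjusted p < `alpha` and linear fold change
#' exceeds `fc_min` (log2FC > log2(fc_min)); `down` for the mirrored rule;
#' `none` otherwise.
#'
#' @param lfc log2 fold changes.
#' @param padj BH-adjusted p-values.
#' @param alpha significance threshold on adjusted p.
#' @param fc_min minimum linear fold change.
#' @return character vector in `c("up", "down", "none")`.
#' @export
call_degs <- function(lfc, padj, alpha = 0.05, fc_min = 2) {
  lthr <- log2(fc_min)
  ifelse(padj < alpha & lfc > lthr, "up",
         ifelse(padj < alpha & lfc < -lthr, "down", "none"))
}

#' Run one full contrast
#'
#' Convenience wrapper chaining [fit_gene_stats()], [estimate_prior()],
#' [moderated_t()], [bh_adjust()] and [call_degs()] into a per-gene result
#' table for one contrast.
#'
#' @inheritParams fit_gene_stats
#' @inheritParams call_degs
#' @param prior optional pre-estimated `shrinkage_prior`; estimated from
#'   this contrast's variances when `NULL`.
#' @return data.frame with per-gene means, `lfc`, `s2`, `df`, `s2_post`,
#'   `t`, `p`, `padj`, `call`; the prior used is attached as attribute
#'   `prior`.
#' @export
run_contrast <- function(m, contrast, alpha = 0.05, fc_min = 2, prior = NULL) {
  st <- fit_gene_stats(m, contrast)
  if (is.null(prior)) prior <- estimate_prior(st$s2, st$df)
  st <- moderated_t(st, prior)
  st$padj <- bh_adjust(st$p)
  st$call <- call_degs(st$lfc, st$padj, alpha = alpha, fc_min = fc_min)
  attr(st, "prior") <- prior
  attr(st, "contrast") <- contrast
  st
}

#' Single-gene relative expression across contrasts
#'
#' For one gene, reports per contrast the linear relative expression
#' (`2^lfc`, reference = 1) and the adjusted p-value taken from the
#' full-transcriptome BH adjustment of that contrast — the single-gene view
#' used when summarizing a marker's behavior across disease types.
#'
#' @param m an [expression_matrix()].
#' @param gene gene ID present in `m`.
#' @param contrasts list of [contrast_spec()] objects.
#' @inheritParams call_degs
#' @return data.frame with `contrast`, `relative_expression`, `padj`.
#' @export
gene_contrast_report <- function(m, gene, contrasts, alpha = 0.05, fc_min = 2) {
  if (!gene %in% rownames(m$values)) {
    lookup_error(sprintf("gene '%s' not present in the matrix", gene))
  }
  rows <- lapply(contrasts, function(cs) {
    res <- run_contrast(m, cs, alpha = alpha, fc_min = fc_min)
    row <- res[res$gene == gene, ]
    data.frame(contrast = sprintf("%s_vs_%s", cs$test, cs$reference),
               relative_expression = 2^row$lfc, padj = row$padj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
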