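#' Delta-Ct relative expression
#'
#' `2^-(target - reference)` where the reference is the arithmetic mean of
#' the housekeeping Ct values (equivalently their geometric mean on the
#' linear scale). Adding a constant to both target and housekeeping Cts
#' leaves the result unchanged.
#'
#' @param target_ct numeric vector of target-gene Ct values.
#' @param housekeeping_ct housekeeping Ct values: a vector (recycled against
#'   `target_ct`, or averaged when `target_ct` is scalar) or a matrix with
#'   one row per element of `target_ct` and one column per housekeeping
#'   gene.
#' @return linear relative expression (reference = 1).
#' @export
relative_expression <- function(target_ct, housekeeping_ct) {
  if (is.matrix(housekeeping_ct)) {
    if (nrow(housekeeping_ct) != length(target_ct)) {
      validation_error("housekeeping matrix must have one row per target Ct")
    }
    ref <- rowMeans(housekeeping_ct)
  } else if (length(target_ct) == 1) {
    ref <- mean(housekeeping_ct)
  } else {
    ref <- housekeeping_ct
  }
  if (any(!is.finite(target_ct)) || any(!is.finite(ref))) {
    validation_error("Ct values must be finite")
  }
  2^-(target_ct - ref)
}

#' Fold change of group medians
#'
#' `median(test) / median(control)`, rounded half-up to `decimals` places —
#' the fold change printed alongside group medians in verification tables.
#' Invariant under a common positive rescaling of both samples.
#'
#' @param test,control numeric vectors of marker values.
#' @param decimals decimal places of the reported ratio.
#' @return the rounded ratio.
#' @export
fold_of_medians <- function(test, control, decimals = 1) {
  if (!length(test) || !length(control)) validation_error("both samples must be non-empty")
  mc <- stats::median(control)
  if (!is.finite(mc) || mc <= 0) validation_error("control median must be > 0")
  round_half_up(stats::median(test) / mc, decimals)
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H with tie correction via [stats::kruskal.test()]; p-value
#' from chi-square with `k - 1` degrees of freedom. When every value is
#' identical the tie correction degenerates; by convention this returns
#' `H = 0`, `p = 1` instead of failing.
#'
#' @param groups list (>= 2) of numeric vectors, each non-empty.
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    precondition_error("need >= 2 non-empty groups")
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1) {
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Pairwise rank-sum comparisons with family adjustment
#'
#' Two-sided Wilcoxon rank-sum test for every pair of groups (normal
#' approximation with tie and continuity correction), with the p-values
#' adjusted across the tested pair family (BH by default).
#'
#' @param groups named list (>= 2) of numeric vectors.
#' @param family_adjust adjustment method passed to [stats::p.adjust()].
#' @return data.frame with `group1`, `group2`, `U`, `p`, `padj`.
#' @export
pairwise_tests <- function(groups, family_adjust = "BH") {
  if (length(groups) < 2) precondition_error("need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  pairs <- utils::combn(names(groups), 2)
  rows <- apply(pairs, 2, function(pr) {
    wt <- suppressWarnings(stats::wilcox.test(groups[[pr[1]]], groups[[pr[2]]],
                                              exact = FALSE, correct = TRUE))
    data.frame(group1 = pr[1], group2 = pr[2],
               U = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = family_adjust)
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks; two-sided p-value from the
#' asymptotic t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom (via [stats::cor.test()] with `exact = FALSE`).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    precondition_error("need equal-length vectors with n >= 3")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# AUC discriminative-power band per the conventional ranges.
auc_band <- function(auc) {
  if (auc > 0.9) "excellent"
  else if (auc > 0.8) "good"
  else if (auc > 0.7) "moderate"
  else if (auc > 0.6) "poor"
  else "below-poor"
}

#' ROC analysis with Youden-index optimal cutoff
#'
#' Empirical ROC over all observed thresholds. The trapezoid AUC equals the
#' rank-sum statistic `U/(n1*n2)` with ties counted one half. The optimal
#' cutoff maximizes sensitivity + specificity over observed score values
#' (ties broken by higher sensitivity, then by the lower cutoff); the AUC
#' p-value comes from the two-sided rank-sum normal approximation, and the
#' discriminative band follows the conventional AUC ranges (poor 0.6-0.7,
#' moderate 0.7-0.8, good 0.8-0.9, excellent > 0.9, else below-poor).
#'
#' @param scores numeric marker values.
#' @param labels logical (or 0/1) vector; `TRUE` = positive class.
#' @param positive_is_high if `TRUE` (default), positives are predicted at
#'   scores at or above the cutoff; if `FALSE`, at or below.
#' @return a `roc_result` list: `auc`, `auc_p`, `cutoff`, `sensitivity`,
#'   `specificity`, `band`, and the ROC `curve` (data.frame of cutoff,
#'   sensitivity, specificity).
#' @export
roc_analysis <- function(scores, labels, positive_is_high = TRUE) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    validation_error("scores and labels must be complete and of equal length")
  }
  if (!any(labels) || all(labels)) validation_error("both classes must be present")
  s <- if (positive_is_high) scores else -scores
  pos <- s[labels]; neg <- s[!labels]
  n1 <- length(pos); n2 <- length(neg)
  cuts <- sort(unique(s), decreasing = TRUE)
  sens <- vapply(cuts, function(cc) mean(pos >= cc), 0)
  spec <- vapply(cuts, function(cc) mean(neg < cc), 0)
  # trapezoid over the step curve, anchored at (0,0) and (1,1)
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  youden <- sens + spec
  best <- which(youden == max(youden))
  if (length(best) > 1) best <- best[order(-sens[best], cuts[best])][1]
  wt <- suppressWarnings(stats::wilcox.test(pos, neg, exact = FALSE, correct = FALSE))
  cutoff <- if (positive_is_high) cuts[best] else -cuts[best]
  curve <- data.frame(cutoff = if (positive_is_high) cuts else -cuts,
                      sensitivity = sens, specificity = spec)
  structure(list(auc = auc, auc_p = wt$p.value, cutoff = cutoff,
                 sensitivity = sens[best], specificity = spec[best],
                 band = auc_band(auc), curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%s), p = %.3g\n", x$auc, x$band, x$auc_p))
  cat(sprintf("optimal cutoff %.4g: sensitivity %.1f%%, specificity %.1f%%\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Replicate coefficient-of-variation report
#'
#' Per gene and input amount: mean, SD and CV = SD/mean of the replicate Ct
#' values, as a percentage rounded half-up to 2 decimals. The SD uses the
#' n-denominator (population) by default, matching how replicate assay
#' reproducibility is conventionally tabulated; `sd_mode = "sample"` gives
#' the n-1 denominator. The per-gene average CV is the arithmetic mean of
#' the per-amount CVs.
#'
#' @param dilution long data.frame with columns `gene`, `amount_ng`,
#'   `replicate`, `ct` (>= 2 replicates per cell).
#' @param sd_mode `"population"` (default) or `"sample"`.
#' @return list with `cells` (per gene x amount: `n`, `mean_ct`, `sd_ct`,
#'   `cv_pct`) and `per_gene` (`gene`, `average_cv_pct`).
#' @export
cv_report <- function(dilution, sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  need <- c("gene", "amount_ng", "replicate", "ct")
  if (!all(need %in% names(dilution))) {
    validation_error(sprintf("dilution table needs columns %s", paste(need, collapse = ", ")))
  }
  sd_fun <- function(x) {
    if (sd_mode == "population") sqrt(mean((x - mean(x))^2)) else stats::sd(x)
  }
  key <- interaction(dilution$gene, dilution$amount_ng, drop = TRUE)
  cells <- do.call(rbind, lapply(split(dilution, key), function(d) {
    if (nrow(d) < 2) precondition_error("each gene x amount cell needs >= 2 replicates")
    mu <- mean(d$ct)
    sdv <- sd_fun(d$ct)
    data.frame(gene = d$gene[1], amount_ng = d$amount_ng[1], n = nrow(d),
               mean_ct = mu, sd_ct = sdv,
               cv_pct = round_half_up(100 * sdv / mu, 2),
               stringsAsFactors = FALSE)
  }))
  cells <- cells[order(cells$gene, -cells$amount_ng), ]
  rownames(cells) <- NULL
  per_gene <- do.call(rbind, lapply(split(cells, cells$gene), function(d) {
    data.frame(gene = d$gene[1], average_cv_pct = average_cv(d$cv_pct),
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  list(cells = cells, per_gene = per_gene)
}

#' Average of per-dilution CV percentages
#'
#' Arithmetic mean of per-amount CV values, rounded half-up — the per-gene
#' summary reported next to a dilution-series table.
#'
#' @param cv_pct numeric vector of CV percentages.
#' @param decimals decimal places of the reported mean.
#' @return rounded mean CV.
#' @export
average_cv <- function(cv_pct, decimals = 2) {
  round_half_up(mean(cv_pct), decimals)
}
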