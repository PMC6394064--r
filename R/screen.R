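#' Venn regions of co-differential gene sets
#'
#' Exact set arithmetic over up-regulated DEG sets from several contrasts:
#' the full intersection (genes up in every contrast) and the count of every
#' Venn region (each non-empty membership pattern over the sets).
#'
#' @param deg_sets named list (>= 2) of character vectors of gene IDs.
#' @return list with `intersection` (sorted gene IDs present in all sets)
#'   and `regions` (named integer vector; names join member set names with
#'   `&`, covering all `2^n - 1` patterns).
#' @export
venn_codifferential <- function(deg_sets) {
  if (length(deg_sets) < 2) precondition_error("need >= 2 DEG sets")
  if (is.null(names(deg_sets))) names(deg_sets) <- paste0("S", seq_along(deg_sets))
  universe <- unique(unlist(deg_sets, use.names = FALSE))
  membership <- vapply(deg_sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  n <- length(deg_sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1, , drop = FALSE]
  regions <- integer(nrow(patterns))
  names(regions) <- apply(patterns, 1, function(pat) {
    paste(names(deg_sets)[as.logical(pat)], collapse = "&")
  })
  if (length(universe)) {
    key <- apply(membership, 1, function(row) paste(names(deg_sets)[row], collapse = "&"))
    tab <- table(key)
    regions[names(regions) %in% names(tab)] <-
      as.integer(tab[names(regions)[names(regions) %in% names(tab)]])
  }
  list(intersection = sort(universe[rowSums(membership) == n]),
       regions = regions)
}

#' Low-expression confounder filter
#'
#' A candidate must be lowly expressed in confounder tissues (bladder,
#' bladder cancer, UTI leukocytes) so that its urinary signal can be
#' attributed to the kidney. A gene passes for a confounder class when its
#' mean log2 expression there falls below the given percentile of all genes'
#' class means; the overall pass requires passing every listed class.
#'
#' @param m an [expression_matrix()].
#' @param genes character vector of gene IDs to test.
#' @param confounder_classes tissue-class labels to filter on.
#' @param percentile percentile threshold in (0, 100]; 100 disables the
#'   filter (every gene passes).
#' @return data.frame with `gene`, one logical `pass_<class>` column per
#'   class, and `pass` (all classes).
#' @export
low_expression_filter <- function(m, genes, confounder_classes, percentile = 25) {
  if (percentile <= 0 || percentile > 100) {
    validation_error("'percentile' must be in (0, 100]")
  }
  missing_cls <- setdiff(confounder_classes, m$samples$tissue_class)
  if (length(missing_cls)) {
    validation_error(sprintf("unknown tissue class: %s",
                             paste(missing_cls, collapse = ", ")))
  }
  unknown <- setdiff(genes, rownames(m$values))
  if (length(unknown)) {
    lookup_error(sprintf("unknown gene: %s", paste(utils::head(unknown, 5), collapse = ", ")))
  }
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (cls in confounder_classes) {
    cls_means <- rowMeans(m$values[, m$samples$tissue_class == cls, drop = FALSE])
    thr <- stats::quantile(cls_means, percentile / 100, names = FALSE)
    out[[paste0("pass_", cls)]] <- if (percentile == 100) {
      rep(TRUE, length(genes))
    } else {
      cls_means[genes] < thr
    }
  }
  out$pass <- Reduce(`&`, out[grep("^pass_", names(out))], rep(TRUE, length(genes)))
  out
}

#' Define a candidate-screening rule
#'
#' Type 1 selects genes up-regulated in the diseased kidney compartment
#' versus normal kidney *and* versus every confounder tissue, passing the
#' low-expression filter in all confounder classes, ranked by the
#' disease-vs-normal-kidney fold change. Type 2 drops the normal-kidney
#' requirement: up versus bladder, bladder cancer and UTI leukocytes,
#' filtered on bladder cancer and UTI, ranked by the disease-vs-bladder
#' fold change.
#'
#' @param rule_type `"type1"` or `"type2"`.
#' @param compartment label of the kidney compartment screened (e.g.
#'   `"glomeruli"`, `"tubules"`).
#' @param required_up character vector naming the contrasts (keys into the
#'   results list) in which a candidate must be called up.
#' @param ranking name of the contrast whose fold change ranks candidates.
#' @param low_classes confounder tissue classes for the expression filter.
#' @param percentile filter percentile, in (0, 100).
#' @param top_k maximum number of candidates retained.
#' @return a `screen_rule` list.
#' @export
screen_rule <- function(rule_type = c("type1", "type2"), compartment,
                        required_up, ranking, low_classes,
                        percentile = 25, top_k = 8) {
  rule_type <- match.arg(rule_type)
  top_k <- assert_count(top_k, "top_k")
  if (percentile <= 0 || percentile > 100) {
    config_error("field 'percentile' must be in (0, 100]")
  }
  if (!ranking %in% required_up) {
    config_error("'ranking' must be one of the required contrasts")
  }
  structure(list(rule_type = rule_type, compartment = compartment,
                 required_up = required_up, ranking = ranking,
                 low_classes = low_classes, percentile = percentile,
                 top_k = top_k),
            class = "screen_rule")
}

#' Select biomarker candidates under a screening rule
#'
#' Intersects the rule's required up-DEG sets, applies the low-expression
#' confounder filter, ranks by the rule's ranking fold change (descending,
#' ties broken lexicographically by gene ID), and truncates to `top_k`.
#'
#' @param results named list of [run_contrast()] results; must cover every
#'   contrast the rule requires.
#' @param m the harmonized [expression_matrix()] (for the expression filter).
#' @param rule a [screen_rule()].
#' @return data.frame with `gene`, `rule_type`, `compartment`, `rank_fc`
#'   (linear fold change in the ranking contrast), one logical `up_<contrast>`
#'   column per required contrast, and the filter pass flags.
#' @export
select_candidates <- function(results, m, rule) {
  missing_res <- setdiff(rule$required_up, names(results))
  if (length(missing_res)) {
    screening_error(sprintf("missing contrast result: %s",
                            paste(missing_res, collapse = ", ")))
  }
  up_sets <- lapply(results[rule$required_up],
                    function(r) r$gene[r$call == "up"])
  shared <- sort(Reduce(intersect, up_sets))
  empty <- data.frame(gene = character(0), rule_type = character(0),
                      compartment = character(0), rank_fc = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(shared)) return(empty)
  filt <- low_expression_filter(m, shared, rule$low_classes, rule$percentile)
  keep <- filt$gene[filt$pass]
  if (!length(keep)) return(empty)
  ranking_res <- results[[rule$ranking]]
  lfc <- ranking_res$lfc[match(keep, ranking_res$gene)]
  ord <- order(-lfc, keep)
  keep <- keep[ord][seq_len(min(rule$top_k, length(keep)))]
  out <- data.frame(gene = keep, rule_type = rule$rule_type,
                    compartment = rule$compartment,
                    rank_fc = 2^ranking_res$lfc[match(keep, ranking_res$gene)],
                    stringsAsFactors = FALSE)
  for (cn in rule$required_up) {
    out[[paste0("up_", cn)]] <- out$gene %in% up_sets[[cn]]
  }
  out <- merge(out, filt, by = "gene", sort = FALSE)
  out[order(-out$rank_fc, out$gene), , drop = FALSE]
}
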