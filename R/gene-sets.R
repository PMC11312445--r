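#' Differential expression between cell types by Wilcoxon rank-sum test
#'
#' For every gene and every unordered pair of cell types, a two-sided
#' Wilcoxon rank-sum test on the posterior-mean expression of the cells of
#' the two types. P-values are adjusted jointly across all genes and type
#' pairs (Benjamini-Hochberg); genes with adjusted p < `alpha` in a pair are
#' flagged significant there.
#'
#' @param expr an [expression_posterior()].
#' @param assignment named character vector cell -> type (defaults to the
#'   `cell_type` metadata column).
#' @param alpha significance level on the adjusted p-value (default 0.01).
#' @return data.frame with columns `gene`, `type_a`, `type_b`, `p`, `p_adj`,
#'   `significant`.
#' @export
wilcoxon_de <- function(expr, assignment = NULL, alpha = 0.01) {
  if (is.null(assignment)) {
    assignment <- expr$cells$cell_type
    names(assignment) <- expr$cells$cell_id
  }
  assignment <- assignment[rownames(expr$X)]
  abort_if(anyNA(assignment), "every cell needs a type assignment")
  types <- sort(unique(assignment))
  abort_if(length(types) < 2, "need at least 2 cell types")
  sizes <- table(assignment)
  pairs <- utils::combn(types, 2, simplify = FALSE)
  res <- list()
  for (pr in pairs) {
    if (sizes[[pr[1]]] < 2 || sizes[[pr[2]]] < 2) {
      warning(sprintf("type pair %s/%s skipped: fewer than 2 cells",
                      pr[1], pr[2]))
      next
    }
    ia <- which(assignment == pr[1])
    ib <- which(assignment == pr[2])
    p <- vapply(seq_len(ncol(expr$X)), function(g) {
      xa <- expr$X[ia, g]; xb <- expr$X[ib, g]
      if (all(xa == xa[1]) && all(xb == xb[1]) && xa[1] == xb[1]) return(1)
      suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
    }, numeric(1))
    res[[paste(pr, collapse = "|")]] <-
      data.frame(gene = expr$gene_ids, type_a = pr[1], type_b = pr[2], p = p,
                 stringsAsFactors = FALSE)
  }
  abort_if(length(res) == 0, "no testable type pair")
  de <- do.call(rbind, res)
  rownames(de) <- NULL
  de$p_adj <- stats::p.adjust(de$p, method = "BH")
  de$significant <- de$p_adj < alpha
  de
}

de_significant_genes <- function(de) unique(de$gene[de$significant])

#' Classify purely zygotic genes at a stage
#'
#' A gene is purely zygotic at stage k when it has fewer than 10 reads in
#' every cell at the baseline (4-cell) stage, more than 100 reads in some
#' cell at stage k, and is differentially expressed across cell types at
#' stage k. The count filters use strict inequalities; the DE requirement
#' drops genes expressed embryo-wide in some embryos and nowhere in others.
#'
#' @param counts_baseline [count_matrix()] at the baseline (4-cell) stage.
#' @param counts_stage [count_matrix()] at stage k.
#' @param de de_table from [wilcoxon_de()] at stage k.
#' @param baseline_max,stage_min read-count thresholds (defaults 10, 100).
#' @return character vector of zygotic gene ids.
#' @export
classify_zygotic <- function(counts_baseline, counts_stage, de,
                             baseline_max = 10, stage_min = 100) {
  abort_if(is.null(counts_baseline), "baseline counts required")
  shared <- intersect(counts_baseline$gene_ids, counts_stage$gene_ids)
  base_hi <- apply(counts_baseline$counts[, shared, drop = FALSE], 2, max)
  stage_hi <- apply(counts_stage$counts[, shared, drop = FALSE], 2, max)
  keep <- shared[base_hi < baseline_max & stage_hi > stage_min]
  sort(intersect(keep, de_significant_genes(de)))
}

#' Classify purely maternal genes
#'
#' A gene is purely maternal when it has more than 500 reads in some cell at
#' the baseline (4-cell) stage and is not differentially expressed across
#' cell types at any subsequent stage. Maternal transcripts known to be
#' localized (e.g. germ-lineage factors at the posterior pole) can be removed
#' with an explicit `exclude` list.
#'
#' @param counts_baseline [count_matrix()] at the baseline stage.
#' @param de_list list of de_tables from [wilcoxon_de()], one per later stage.
#' @param baseline_min read-count threshold (default 500).
#' @param exclude character vector of gene ids to drop regardless.
#' @return character vector of maternal gene ids.
#' @export
classify_maternal <- function(counts_baseline, de_list, baseline_min = 500,
                              exclude = character(0)) {
  base_hi <- apply(counts_baseline$counts, 2, max)
  cand <- counts_baseline$gene_ids[base_hi > baseline_min]
  ever_de <- unique(unlist(lapply(de_list, de_significant_genes)))
  sort(setdiff(setdiff(cand, ever_de), exclude))
}
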