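#' Construct a gene panel
#'
#' An ordered list of signature genes with per-gene regulation direction.
#'
#' @param gene_ids character vector, unique.
#' @param direction per-gene direction, `"up"` or `"down"` (recycled).
#' @param provenance free-text origin note.
#' @return list of class `"gene_panel"` with `gene_ids`, `direction`,
#'   `provenance`.
#' @export
gene_panel <- function(gene_ids, direction = "down", provenance = "") {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in panel")
  direction <- rep_len(as.character(direction), length(gene_ids))
  if (length(gene_ids) && !all(direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  structure(list(gene_ids = gene_ids, direction = direction,
                 provenance = provenance), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene panel: %d genes (%d down, %d up)%s\n",
              length(x$gene_ids), sum(x$direction == "down"),
              sum(x$direction == "up"),
              if (nzchar(x$provenance)) paste0(" — ", x$provenance) else ""))
  invisible(x)
}

#' @export
length.gene_panel <- function(x) length(x$gene_ids)

#' Select genes changing monotonically across two transitions
#'
#' A gene enters the progression panel iff in BOTH contrasts (adjacent
#' normal vs primary tumour, and primary tumour vs metastasis) its absolute
#' log2 fold change reaches `lfc_thresh`, its FDR is below `fdr_thresh`,
#' and the sign of the fold change is the same — i.e. it keeps moving in the
#' same direction as disease progresses. The threshold comparison is
#' inclusive (|log2FC| >= lfc_thresh).
#'
#' @param de_an_can `"de_table"` for the AN vs CAN contrast (log2fc of CAN
#'   over AN).
#' @param de_can_met `"de_table"` for the CAN vs MET contrast.
#' @param lfc_thresh absolute log2-fold-change threshold per transition
#'   (default 2).
#' @param fdr_thresh FDR threshold, strict (default 0.05).
#' @return a [gene_panel()] with direction from the shared sign.
#' @export
select_monotone <- function(de_an_can, de_can_met, lfc_thresh = 2, fdr_thresh = 0.05) {
  shared <- intersect(de_an_can$gene_id, de_can_met$gene_id)
  if (!length(shared) && (nrow(de_an_can) || nrow(de_can_met)))
    stop("the two DE tables share no genes")
  a <- de_an_can[match(shared, de_an_can$gene_id), ]
  b <- de_can_met[match(shared, de_can_met$gene_id), ]
  hit <- abs(a$log2fc) >= lfc_thresh & abs(b$log2fc) >= lfc_thresh &
    a$fdr < fdr_thresh & b$fdr < fdr_thresh &
    sign(a$log2fc) == sign(b$log2fc) & a$log2fc != 0
  ids <- shared[hit]
  gene_panel(ids, ifelse(a$log2fc[hit] > 0, "up", "down"),
             provenance = sprintf("monotone selection |lfc|>=%g, fdr<%g",
                                  lfc_thresh, fdr_thresh))
}

#' Per-sample progression score
#'
#' The summed expression of the panel genes, log2-transformed:
#' `log2(sum(expr[panel]) + pseudocount)`. For panels of downregulated
#' genes a lower score means a more progressed (tumour-like) profile.
#' Panel genes absent from the matrix are dropped with the coverage logged.
#'
#' @param expr [expression_matrix()] (FPKM or counts).
#' @param panel a [gene_panel()].
#' @param pseudocount added to the gene sum before the log (default 1).
#' @param aggregate `"sum"` (default) or `"mean"` over panel genes.
#' @return named numeric score vector, one entry per sample.
#' @export
progression_score <- function(expr, panel, pseudocount = 1,
                              aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  present <- intersect(panel$gene_ids, rownames(expr))
  if (!length(present))
    stop("no panel gene present in this cohort's expression matrix")
  message(sprintf("progression_score: %d of %d panel genes present (%.1f%%)",
                  length(present), length(panel$gene_ids),
                  100 * length(present) / length(panel$gene_ids)))
  v <- unclass(expr)[present, , drop = FALSE]
  agg <- if (aggregate == "sum") colSums(v) else colMeans(v)
  log2(agg + pseudocount)
}

#' Compare score distributions between sample groups
#'
#' Two-sided Welch t-test for every pair of groups, the comparison used to
#' check that scores order adjacent-normal above primary tumour above
#' metastasis.
#'
#' @param scores named score vector.
#' @param groups group label per score entry.
#' @return data.frame with `group1`, `group2`, `t`, `df`, `p`,
#'   `mean1`, `mean2`.
#' @export
compare_score_groups <- function(scores, groups) {
  groups <- as.character(groups)
  if (length(groups) != length(scores)) stop("one group label per score required")
  tab <- table(groups)
  if (any(tab < 2)) stop("every group needs at least two samples")
  gs <- names(tab)
  pairs <- utils::combn(gs, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    x <- scores[groups == g1]; y <- scores[groups == g2]
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      tt <- list(statistic = 0, parameter = length(x) + length(y) - 2, p.value = 1)
    } else tt <- stats::t.test(x, y)
    data.frame(group1 = g1, group2 = g2, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean1 = mean(x), mean2 = mean(y), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
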