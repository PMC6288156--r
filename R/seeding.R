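#' Most variable genes
#'
#' The `k` genes with the largest variance across the included samples;
#' ties are broken by gene-id lexical order.
#'
#' @param expr log2 [expression_matrix()].
#' @param k number of genes, 1..nrow(expr).
#' @return character vector of gene ids, ordered by decreasing variance.
#' @export
top_variable <- function(expr, k) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(expr)) stop("k exceeds the number of genes")
  v <- apply(unclass(expr), 1, stats::var)
  ord <- order(-v, rownames(expr), method = "radix")
  rownames(expr)[ord][seq_len(k)]
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the matrix columns with the heatmap
#' defaults — Euclidean distance on log2 values, complete linkage —
#' configurable to correlation distance and average or Ward linkage.
#' Deterministic given the input column order.
#'
#' @param expr log2 [expression_matrix()] (or any numeric matrix), samples
#'   in columns.
#' @param distance `"euclidean"` or `"pearson"` (1 - Pearson correlation).
#' @param linkage `"complete"`, `"average"` or `"ward"`.
#' @return an [stats::hclust] tree over the samples.
#' @export
hcluster <- function(expr, distance = c("euclidean", "pearson"),
                     linkage = c("complete", "average", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  x <- t(unclass(expr))
  if (nrow(x) < 2) stop("need at least two samples to cluster")
  d <- if (distance == "euclidean") stats::dist(x)
       else stats::as.dist(1 - stats::cor(t(x)))
  stats::hclust(d, method = c(complete = "complete", average = "average",
                              ward = "ward.D2")[linkage])
}

# ids of the leaves below each internal node of an hclust tree
hclust_clusters <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) hc$labels[-j] else members[[j]]
    members[[i]] <- c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2]))
  }
  members
}

# the partner of sample `met` = the single CAN sample in the smallest
# cluster containing `met` that holds at least one CAN; NA when that
# cluster holds several CANs (ambiguous)
cluster_partner <- function(hc, met, can_ids) {
  for (cl in hclust_clusters(hc)) {
    if (!(met %in% cl)) next
    cans <- intersect(cl, can_ids)
    if (length(cans) == 1) return(cans)
    if (length(cans) > 1) return(NA_character_)
  }
  NA_character_
}

#' Call the metastasis-seeding primary focus for one patient
#'
#' For each gene-set size in `k_list`, the patient's primary-focus (CAN)
#' and metastasis (MET) samples are clustered on the top-k most variable
#' transcripts (variance computed within the patient's own samples, or
#' cohort-wide when `cohort_variance = TRUE`). At each k, the candidate
#' partner is the CAN sample sharing the smallest dendrogram cluster with
#' the MET sample. The call is `resolved` only when every k — and, with
#' several MET samples, every MET — points to the same focus; patients with
#' fewer than two CAN or no MET sample are `ineligible`, everything else is
#' `unresolved`.
#'
#' @param expr log2 [expression_matrix()] over at least the patient's
#'   samples.
#' @param annotation sample annotation (`sample_id`, `patient_id`,
#'   `tissue_type`, `focus_label`).
#' @param patient_id the patient to call.
#' @param k_list gene-set sizes (default 500, 100, 50), each capped at the
#'   number of genes.
#' @param distance,linkage passed to [hcluster()].
#' @param cohort_variance rank gene variance over all samples in `expr`
#'   instead of the patient's only.
#' @return list of class `"seeding_call"`: `patient_id`, `status`
#'   (`resolved` / `unresolved` / `ineligible`), `seeding_focus` (focus
#'   label or NA), `support` (per-k, per-MET partner table).
#' @export
call_seeding_focus <- function(expr, annotation, patient_id,
                               k_list = c(500, 100, 50),
                               distance = "euclidean", linkage = "complete",
                               cohort_variance = FALSE) {
  validate_annotation(annotation)
  pat <- annotation[annotation$patient_id == patient_id, , drop = FALSE]
  if (!nrow(pat)) stop("unknown patient: ", patient_id)
  can <- pat[pat$tissue_type == "CAN", , drop = FALSE]
  met <- pat[pat$tissue_type == "MET", , drop = FALSE]
  res <- structure(list(patient_id = patient_id, status = "ineligible",
                        seeding_focus = NA_character_, support = NULL),
                   class = "seeding_call")
  if (nrow(can) < 2 || nrow(met) < 1) return(res)

  ids <- c(can$sample_id, met$sample_id)
  miss <- setdiff(ids, colnames(expr))
  if (length(miss)) stop("sample(s) absent from expression matrix: ",
                         paste(miss, collapse = ", "))
  sub_all <- expr[, ids, drop = FALSE]
  var_space <- if (cohort_variance) expr else sub_all

  support <- do.call(rbind, lapply(k_list, function(k) {
    kk <- min(k, nrow(expr))
    genes <- top_variable(var_space, kk)
    hc <- hcluster(sub_all[genes, , drop = FALSE], distance, linkage)
    partners <- vapply(met$sample_id, function(m)
      cluster_partner(hc, m, can$sample_id), character(1))
    data.frame(k = k, met_sample = met$sample_id,
               partner_sample = unname(partners), stringsAsFactors = FALSE)
  }))
  support$partner_focus <- can$focus_label[match(support$partner_sample, can$sample_id)]
  res$support <- support

  partners <- unique(support$partner_focus)
  if (length(partners) == 1 && !is.na(partners)) {
    res$status <- "resolved"
    res$seeding_focus <- partners
  } else {
    res$status <- "unresolved"
  }
  res
}

#' @export
print.seeding_call <- function(x, ...) {
  cat(sprintf("seeding call for %s: %s%s\n", x$patient_id, x$status,
              if (x$status == "resolved") paste0(" (focus ", x$seeding_focus, ")") else ""))
  if (!is.null(x$support)) print(x$support)
  invisible(x)
}

#' Call seeding foci for every eligible patient
#'
#' @param expr log2 [expression_matrix()].
#' @param annotation sample annotation.
#' @param ... passed to [call_seeding_focus()].
#' @return data.frame with one row per patient: `patient_id`, `status`,
#'   `seeding_focus`.
#' @export
call_seeding_all <- function(expr, annotation, ...) {
  pts <- unique(annotation$patient_id)
  out <- do.call(rbind, lapply(pts, function(p) {
    cl <- call_seeding_focus(expr, annotation, p, ...)
    data.frame(patient_id = p, status = cl$status,
               seeding_focus = cl$seeding_focus, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Differential expression between seeding and non-seeding foci
#'
#' Runs the count-based DE pipeline on the two focus groups and derives two
#' nested panels: a broad panel at `fdr_broad` and a strict panel at
#' `fdr_panel` (strict is always a subset of broad).
#'
#' @param counts count [expression_matrix()] restricted or not; only the
#'   named samples are used.
#' @param seeding_samples,nonseeding_samples sample-id vectors for the two
#'   sides (the discovery analysis used 2 vs 4).
#' @param fdr_panel strict FDR cutoff (default 0.01).
#' @param fdr_broad broad FDR cutoff (default 0.05).
#' @param dispersion optional dispersion passed through to
#'   [nb_exact_test()].
#' @return list with `de` (the `"de_table"`), `broad` and `strict`
#'   ([gene_panel()]s).
#' @export
seeding_de <- function(counts, seeding_samples, nonseeding_samples,
                       fdr_panel = 0.01, fdr_broad = 0.05, dispersion = NULL) {
  if (!length(seeding_samples) || !length(nonseeding_samples))
    stop("both focus groups need at least one sample")
  if (fdr_panel > fdr_broad) stop("fdr_panel must not exceed fdr_broad")
  ids <- c(nonseeding_samples, seeding_samples)
  sub <- counts[, ids, drop = FALSE]
  groups <- factor(rep(c("nonseeding", "seeding"),
                       c(length(nonseeding_samples), length(seeding_samples))),
                   levels = c("nonseeding", "seeding"))
  de <- nb_exact_test(sub, groups, dispersion = dispersion)
  mk <- function(thr, label) {
    hit <- de$fdr < thr
    gene_panel(de$gene_id[hit], ifelse(de$log2fc[hit] > 0, "up", "down"),
               provenance = sprintf("seeding DE, fdr<%g (%s)", thr, label))
  }
  list(de = de, broad = mk(fdr_broad, "broad"), strict = mk(fdr_panel, "strict"))
}
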