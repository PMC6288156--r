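#' @title Sample annotation and cohort preparation
#' @description Readers and row filters for the sample annotation and clinical
#'   tables: sequencing-QC filtering, cohort eligibility rules, collapsing the
#'   two adjacent-normal groups, and the FPKM expression filter.
#' @name prep
NULL

TISSUE_TYPES <- c("DAN", "PAN", "CAN", "MET", "LYMPH", "AN")

#' Validate a sample annotation table
#'
#' Required columns: `sample_id`, `patient_id`, `tissue_type` (one of DAN,
#' PAN, CAN, MET, LYMPH, or AN after collapsing), optional `focus_label`,
#' and logical `qc_pass`.
#'
#' @param annotation data.frame.
#' @return the validated data.frame, invisibly unchanged.
#' @export
validate_annotation <- function(annotation) {
  need <- c("sample_id", "patient_id", "tissue_type")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(annotation$tissue_type), TISSUE_TYPES)
  if (length(bad)) stop("unknown tissue type(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(annotation$sample_id)) stop("duplicate sample ids in annotation")
  invisible(annotation)
}

#' Read a sample annotation or clinical table from TSV
#' @param path tab-separated file with a header row.
#' @return data.frame (strings kept as character, logicals parsed).
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a table to TSV
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop samples failing sequencing QC
#'
#' Pure row selection on the logical `qc_pass` column; retained rows are
#' never altered and keep their order. The number removed is reported via
#' `message()`.
#'
#' @param annotation sample annotation with a `qc_pass` column.
#' @return the annotation restricted to `qc_pass` samples.
#' @export
qc_filter <- function(annotation) {
  if (!"qc_pass" %in% names(annotation)) stop("annotation has no qc_pass column")
  if (any(is.na(annotation$qc_pass))) stop("qc_pass contains NA")
  keep <- annotation$qc_pass
  message(sprintf("qc_filter: removed %d of %d samples", sum(!keep), length(keep)))
  out <- annotation[keep, , drop = FALSE]
  if (!nrow(out)) warning("qc_filter removed every sample")
  out
}

#' Apply cohort-eligibility exclusion rules
#'
#' Removes every patient row with any of the named exclusion flags set, the
#' way validation cohorts are trimmed before survival analysis (for example
#' post-endocrine-treated patients, duplicated profiles, or zero days to
#' biochemical recurrence). Retained rows are untouched; per-rule removal
#' counts are reported.
#'
#' @param clinical clinical table (one row per patient).
#' @param exclude_flags character vector of logical column names; a row is
#'   dropped when any flag is TRUE.
#' @return the clinical table restricted to eligible patients.
#' @export
apply_eligibility <- function(clinical, exclude_flags) {
  miss <- setdiff(exclude_flags, names(clinical))
  if (length(miss)) stop("eligibility rule column(s) missing: ", paste(miss, collapse = ", "))
  drop <- rep(FALSE, nrow(clinical))
  for (fl in exclude_flags) {
    v <- clinical[[fl]]
    if (!is.logical(v)) v <- as.logical(v)
    if (any(is.na(v))) stop("eligibility column ", fl, " has NA/unparseable values")
    message(sprintf("apply_eligibility: %s flags %d patients", fl, sum(v)))
    drop <- drop | v
  }
  message(sprintf("apply_eligibility: %d of %d patients retained", sum(!drop), nrow(clinical)))
  clinical[!drop, , drop = FALSE]
}

#' Collapse the two adjacent-normal groups
#'
#' Relabels distant (DAN) and proximal (PAN) adjacent-normal samples to a
#' single adjacent-normal (AN) group; every other tissue label is untouched.
#' Idempotent.
#'
#' @param annotation sample annotation.
#' @return annotation with `tissue_type` DAN/PAN replaced by AN.
#' @export
collapse_an <- function(annotation) {
  validate_annotation(annotation)
  annotation$tissue_type[annotation$tissue_type %in% c("DAN", "PAN")] <- "AN"
  annotation
}

#' Filter genes by minimum expression per subgroup
#'
#' A gene is kept iff, in every subgroup, the fraction of samples with
#' expression strictly above `min_fpkm` is at least `min_frac`. This is the
#' usual "expressed at >1 FPKM in at least 50% of each subgroup" rule.
#'
#' @param expr expression matrix in FPKM.
#' @param groups vector of subgroup labels, one per column of `expr` (or a
#'   sample annotation data.frame, in which case `tissue_type` is used for
#'   the columns of `expr` matched by `sample_id`).
#' @param min_fpkm expression threshold (strict inequality); default 1.
#' @param min_frac minimum within-group fraction of samples above the
#'   threshold; default 0.5.
#' @return the filtered expression matrix.
#' @export
filter_expressed <- function(expr, groups, min_fpkm = 1, min_frac = 0.5) {
  if (expr_unit(expr) != "fpkm")
    stop("filter_expressed expects FPKM values (unit_kind = 'fpkm')")
  if (is.data.frame(groups)) {
    idx <- match(colnames(expr), groups$sample_id)
    if (any(is.na(idx))) stop("samples missing from annotation: ",
                              paste(colnames(expr)[is.na(idx)], collapse = ", "))
    groups <- groups$tissue_type[idx]
  }
  if (length(groups) != ncol(expr)) stop("one group label per sample required")
  if (any(is.na(groups))) stop("every sample must be assigned a subgroup")
  tabs <- table(groups)
  if (any(tabs == 0)) stop("empty subgroup")
  keep <- rep(TRUE, nrow(expr))
  for (g in names(tabs)) {
    frac <- rowMeans(unclass(expr)[, groups == g, drop = FALSE] > min_fpkm)
    keep <- keep & (frac >= min_frac)
  }
  message(sprintf("filter_expressed: %d of %d genes retained", sum(keep), nrow(expr)))
  expr[keep, , drop = FALSE]
}

#' FPKM from raw counts
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `count / (library_size/1e6) / (length/1e3)`. Validation cohorts usually
#' arrive pre-normalised; this supports recomputation when raw counts and
#' gene lengths are available.
#'
#' @param counts count [expression_matrix()].
#' @param gene_lengths named vector of transcript lengths in bases,
#'   covering every gene in `counts`.
#' @return FPKM [expression_matrix()].
#' @export
fpkm_from_counts <- function(counts, gene_lengths) {
  miss <- setdiff(rownames(counts), names(gene_lengths))
  if (length(miss)) stop("gene length(s) missing for: ", paste(utils::head(miss, 5), collapse = ", "))
  len <- gene_lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be positive")
  lib <- colSums(unclass(counts))
  if (any(lib == 0)) stop("sample(s) with zero total counts")
  vals <- sweep(sweep(unclass(counts), 2, lib / 1e6, `/`), 1, len / 1e3, `/`)
  expression_matrix(vals, "fpkm")
}

#' Match a gene panel to a cohort's expression matrix
#'
#' Cross-platform cohorts rarely measure every panel gene; unmatched genes
#' are dropped and the coverage fraction reported (both numerator and
#' denominator, since conventions differ).
#'
#' @param panel a [gene_panel()].
#' @param expr expression matrix.
#' @param alias optional two-column data.frame (`from`, `to`) mapping panel
#'   ids to the cohort's ids before matching.
#' @return the panel restricted to genes present in `expr`.
#' @export
match_panel <- function(panel, expr, alias = NULL) {
  ids <- panel$gene_ids
  if (!is.null(alias)) {
    m <- match(ids, alias[[1]])
    ids[!is.na(m)] <- alias[[2]][m[!is.na(m)]]
  }
  present <- ids %in% rownames(expr)
  message(sprintf("panel coverage: %d of %d genes (%.1f%%)",
                  sum(present), length(ids), 100 * sum(present) / length(ids)))
  gene_panel(ids[present], panel$direction[present],
             provenance = paste0(panel$provenance, " [matched]"))
}
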