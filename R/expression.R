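#' Construct an expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes in rows, samples in
#' columns) carrying a `unit_kind` attribute that records what the values are:
#' raw counts, FPKM, or log2-transformed FPKM. All downstream functions check
#' the unit where it matters (the differential-expression machinery wants
#' counts, the expression filter wants FPKM, clustering wants log2 values).
#'
#' @param values numeric matrix, genes x samples, non-negative and finite
#'   (negative values are allowed only for `"log2fpkm"`).
#' @param unit_kind one of `"counts"`, `"fpkm"`, `"log2fpkm"`.
#' @return the matrix with class `"expr_matrix"` and attribute `unit_kind`.
#' @export
expression_matrix <- function(values, unit_kind = c("counts", "fpkm", "log2fpkm")) {
  unit_kind <- match.arg(unit_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ", paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite entries")
  if (unit_kind != "log2fpkm" && any(values < 0))
    stop("negative values not allowed for unit ", unit_kind)
  structure(values, unit_kind = unit_kind, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x), expr_unit(x)))
  invisible(x)
}

#' Unit of an expression matrix
#' @param x an expression matrix.
#' @return the `unit_kind` string.
#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit_kind")
  if (is.null(u)) "counts" else u
}

# subsetting keeps the class and unit; drop is forced off so a one-gene
# subset stays a matrix
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  u <- expr_unit(x)
  y <- NextMethod(drop = FALSE)
  structure(y, unit_kind = u, class = class(x))
}

#' Read an expression matrix from TSV
#'
#' Expects gene identifiers in the first column and a header of sample ids.
#' Duplicate gene ids and non-numeric cells are rejected with the offending
#' id or cell location named.
#'
#' @param path path to a tab-separated file.
#' @param unit_kind declared unit of the stored values.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, unit_kind = c("counts", "fpkm", "log2fpkm")) {
  unit_kind <- match.arg(unit_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("expected a gene-id column plus at least one sample column")
  gene_ids <- tab[[1]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(gene_ids, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at gene '%s', sample '%s' (value '%s')",
                 gene_ids[bad[1, 1]], colnames(vals)[bad[1, 2]], vals[bad[1, 1], bad[1, 2]]))
  expression_matrix(num, unit_kind)
}

#' Write an expression matrix to TSV
#'
#' @param expr an expression matrix.
#' @param path output path; the first column is named `gene_id`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), as.data.frame(unclass(expr)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform an expression matrix
#'
#' @param expr expression matrix in counts or FPKM.
#' @param pseudocount non-negative value added before the log; default 1.
#' @return expression matrix of entrywise `log2(x + pseudocount)` with unit
#'   `"log2fpkm"`.
#' @export
to_log2 <- function(expr, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  expression_matrix(log2(unclass(expr) + pseudocount), "log2fpkm")
}
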