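#' Per-sample scale factors by trimmed mean of M-values
#'
#' Computes TMM composition factors against a reference column (the sample
#' whose upper-quartile count fraction is closest to the mean), then returns
#' effective scale factors — library size times composition factor —
#' normalised to geometric mean 1, so that `counts / factor` are directly
#' comparable across samples. A column whose counts are doubled therefore
#' gets a factor about twice its reference's. The raw TMM composition
#' factors are kept in the `"tmm"` attribute.
#'
#' @param counts count [expression_matrix()] (>= 2 samples).
#' @param trim_m,trim_a two-sided trim fractions on log-ratios and
#'   log-abundances (TMM defaults 0.3 and 0.05).
#' @return named numeric vector of scale factors, geometric mean 1, with
#'   attributes `"tmm"` (composition factors) and `"lib_size"`.
#' @export
norm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  y <- unclass(counts)
  if (ncol(y) < 2) stop("need at least two samples")
  lib <- colSums(y)
  if (any(lib == 0)) stop("sample(s) with zero total counts: ",
                          paste(colnames(y)[lib == 0], collapse = ", "))
  # reference: upper quartile of count fractions closest to the mean UQ
  uq <- apply(sweep(y, 2, lib, `/`), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))

  tmm <- vapply(seq_len(ncol(y)), function(k) {
    if (k == ref) return(1)
    ok <- y[, k] > 0 & y[, ref] > 0
    if (!any(ok)) return(1)
    nk <- lib[k]; nr <- lib[ref]
    m <- log2((y[ok, k] / nk) / (y[ok, ref] / nr))
    a <- 0.5 * log2((y[ok, k] / nk) * (y[ok, ref] / nr))
    w <- (nk - y[ok, k]) / (nk * y[ok, k]) + (nr - y[ok, ref]) / (nr * y[ok, ref])
    keep <- m >= stats::quantile(m, trim_m) & m <= stats::quantile(m, 1 - trim_m) &
      a >= stats::quantile(a, trim_a) & a <= stats::quantile(a, 1 - trim_a)
    if (!any(keep)) keep <- rep(TRUE, length(m))
    if (any(w[keep] > 0)) 2^stats::weighted.mean(m[keep], 1 / pmax(w[keep], 1e-12))
    else 2^mean(m[keep])
  }, numeric(1))
  tmm <- tmm / exp(mean(log(tmm)))

  f <- lib * tmm
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(y)
  structure(f, tmm = tmm, lib_size = lib)
}

# counts scaled to a common effective library (geometric-mean scale)
equalize_counts <- function(counts, factors = NULL) {
  if (is.null(factors)) factors <- norm_factors(counts)
  sweep(unclass(counts), 2, factors, `/`)
}

#' Normalise counts to a common effective library
#'
#' Divides each sample's counts by its [norm_factors()] scale factor,
#' removing library-size and composition differences so samples are
#' directly comparable (for clustering, scoring, visualisation).
#'
#' @param counts count [expression_matrix()].
#' @param factors optional precomputed [norm_factors()].
#' @return normalised [expression_matrix()] with unit `"fpkm"` (per-library
#'   scale, not length-corrected).
#' @export
normalize_counts <- function(counts, factors = NULL) {
  expression_matrix(equalize_counts(counts, factors), "fpkm")
}

# exact conditional (given the group total) NB log-likelihood for one
# group's counts at dispersion alpha; mean parameter is conditioned out,
# valid for equalised libraries; continuous in y via lgamma
cond_loglik_group <- function(y, alpha) {
  n <- length(y)
  if (n < 2) return(0)
  r <- 1 / alpha
  z <- sum(y)
  lgamma(z + 1) + sum(lgamma(y + r)) + lgamma(n * r) -
    lgamma(z + n * r) - sum(lgamma(y + 1)) - n * lgamma(r)
}

#' Estimate negative-binomial dispersion
#'
#' Common dispersion maximises the exact conditional likelihood (given each
#' gene's group total, removing the group means) summed over genes, on
#' library-equalised counts. Tagwise dispersions maximise a weighted
#' likelihood: each gene's own conditional likelihood plus `prior_df` times
#' the average per-gene likelihood, shrinking gene-level estimates toward
#' the common value. All estimates are floored at 1e-6.
#'
#' @param counts count [expression_matrix()].
#' @param groups two-or-more-level grouping vector, one label per sample.
#' @param prior_df prior degrees of freedom for tagwise shrinkage
#'   (default 10); `Inf` returns the common value for every gene.
#' @param factors optional precomputed [norm_factors()].
#' @return list with `common` (scalar) and `tagwise` (per-gene vector).
#' @export
estimate_dispersion <- function(counts, groups, prior_df = 10, factors = NULL) {
  y <- equalize_counts(counts, factors)
  groups <- as.character(groups)
  if (length(groups) != ncol(y)) stop("one group label per sample required")
  sizes <- table(groups)
  if (any(sizes < 2))
    warning("group(s) with a single sample contribute nothing to dispersion estimation")

  glist <- lapply(unique(groups), function(g) which(groups == g))
  use <- rowSums(y) > 0
  if (!any(use)) stop("all genes have zero counts")

  grid <- 10^seq(-6, 1, length.out = 43)
  # per-gene conditional log-likelihood at every grid alpha
  ll <- matrix(0, nrow = nrow(y), ncol = length(grid))
  for (j in seq_along(grid)) {
    a <- grid[j]
    for (idx in glist) {
      if (length(idx) < 2) next
      yy <- y[, idx, drop = FALSE]
      n <- length(idx); r <- 1 / a
      z <- rowSums(yy)
      ll[, j] <- ll[, j] + lgamma(z + 1) + rowSums(lgamma(yy + r)) + lgamma(n * r) -
        lgamma(z + n * r) - rowSums(lgamma(yy + 1)) - n * lgamma(r)
    }
  }
  tot <- colSums(ll[use, , drop = FALSE])
  common <- grid[which.max(tot)]
  # refine the common estimate between the neighbouring grid points
  lo <- grid[max(1, which.max(tot) - 1)]; hi <- grid[min(length(grid), which.max(tot) + 1)]
  opt <- stats::optimize(function(la) {
    a <- exp(la)
    s <- 0
    for (idx in glist) {
      if (length(idx) < 2) next
      s <- s + sum(apply(y[use, idx, drop = FALSE], 1, cond_loglik_group, alpha = a))
    }
    s
  }, interval = log(c(lo, hi)), maximum = TRUE, tol = 1e-4)
  common <- max(exp(opt$maximum), 1e-6)

  if (is.infinite(prior_df)) {
    tag <- rep(common, nrow(y))
  } else {
    avg <- colMeans(ll[use, , drop = FALSE])
    obj <- ll + matrix(prior_df * avg, nrow = nrow(y), ncol = length(grid), byrow = TRUE)
    tag <- grid[max.col(obj, ties.method = "first")]
    tag[!use] <- common
    tag <- pmax(tag, 1e-6)
  }
  names(tag) <- rownames(y)
  list(common = common, tagwise = tag)
}

# two-sided conditional exact p for group totals (za, zb) with na, nb
# samples at dispersion alpha: sum of all conditional outcomes no more
# probable than the observed one ("doubletail over the full support")
nb_exact_p <- function(za, zb, na, nb, alpha, max_enum = 2e5) {
  z <- za + zb
  if (z == 0) return(1)
  mu <- z / (na + nb)          # per-sample common mean under H0
  r <- 1 / alpha
  if (z <= max_enum) {
    a <- 0:z
    lp <- stats::dnbinom(a, size = na * r, mu = na * mu, log = TRUE) +
      stats::dnbinom(z - a, size = nb * r, mu = nb * mu, log = TRUE)
    lp <- lp - max(lp)
    p <- exp(lp) / sum(exp(lp))
    pobs <- p[za + 1]
    sel <- p <= pobs * (1 + 1e-12)
    if (all(sel)) 1 else min(1, sum(p[sel]))
  } else {
    # normal approximation to the conditional distribution of za
    m <- z * na / (na + nb)
    v1 <- na * mu * (1 + mu / r); v2 <- nb * mu * (1 + mu / r)
    v <- v1 * v2 / (v1 + v2)
    min(1, 2 * stats::pnorm(-abs(za - m) / sqrt(v)))
  }
}

#' Negative-binomial exact test for two groups
#'
#' Library sizes are equalised by the TMM scale factors, group totals of the
#' pseudo-counts are rounded, and a conditional exact test compares the two
#' NB group sums given their total: the two-sided p-value is the probability
#' of all outcomes no more likely than the observed split. Log2 fold changes
#' are group2 over group1 means of normalised counts with a pseudocount;
#' p-values are Benjamini-Hochberg adjusted.
#'
#' @param counts count [expression_matrix()].
#' @param groups grouping with exactly two levels; the first level in sort
#'   order (or factor-level order) is group1.
#' @param dispersion result of [estimate_dispersion()], a per-gene vector,
#'   or a scalar; NULL estimates tagwise dispersion first.
#' @param factors optional precomputed [norm_factors()].
#' @param lfc_pseudocount pseudocount on normalised group means for the fold
#'   change (default 0.5).
#' @return data.frame of class `"de_table"`: `gene_id`, `log2fc`, `pvalue`,
#'   `fdr`, `mean_expr`, ordered as the input genes.
#' @export
nb_exact_test <- function(counts, groups, dispersion = NULL, factors = NULL,
                          lfc_pseudocount = 0.5) {
  y <- unclass(counts)
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (is.null(factors)) factors <- norm_factors(counts)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(counts, groups, factors = factors)
  disp <- if (is.list(dispersion)) dispersion$tagwise else dispersion
  disp <- rep_len(disp, nrow(y))

  ye <- sweep(y, 2, factors, `/`)
  i1 <- which(groups == levels(groups)[1]); i2 <- which(groups == levels(groups)[2])
  n1 <- length(i1); n2 <- length(i2)
  z1 <- round(rowSums(ye[, i1, drop = FALSE]))
  z2 <- round(rowSums(ye[, i2, drop = FALSE]))
  m1 <- rowMeans(ye[, i1, drop = FALSE]); m2 <- rowMeans(ye[, i2, drop = FALSE])

  p <- vapply(seq_len(nrow(y)), function(g) {
    if (z1[g] + z2[g] == 0) return(1)
    nb_exact_p(z1[g], z2[g], n1, n2, max(disp[g], 1e-10))
  }, numeric(1))
  lfc <- ifelse(z1 + z2 == 0, 0,
                log2((m2 + lfc_pseudocount) / (m1 + lfc_pseudocount)))

  out <- data.frame(gene_id = rownames(y), log2fc = lfc, pvalue = p,
                    fdr = bh_adjust(p), mean_expr = (m1 * n1 + m2 * n2) / (n1 + n2),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; order-preserving, output in
#' [0, 1].
#'
#' @param pvalues numeric vector in [0, 1].
#' @return FDR vector of the same length.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Welch t-test differential expression for FPKM cohorts
#'
#' Documented fallback for cohorts without raw counts: per-gene two-sided
#' Welch t-test on log2(FPKM + pseudocount), BH-adjusted.
#'
#' @param expr FPKM [expression_matrix()].
#' @param groups two-level grouping.
#' @param pseudocount log pseudocount (default 1).
#' @return a `"de_table"` data.frame as in [nb_exact_test()].
#' @export
welch_de <- function(expr, groups, pseudocount = 1) {
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  x <- log2(unclass(expr) + pseudocount)
  i1 <- groups == levels(groups)[1]; i2 <- groups == levels(groups)[2]
  res <- t(apply(x, 1, function(v) {
    if (stats::sd(v[i1]) == 0 && stats::sd(v[i2]) == 0)
      return(c(mean(v[i2]) - mean(v[i1]), if (mean(v[i1]) == mean(v[i2])) 1 else 0))
    tt <- stats::t.test(v[i2], v[i1])
    c(unname(tt$estimate[1] - tt$estimate[2]), tt$p.value)
  }))
  out <- data.frame(gene_id = rownames(x), log2fc = res[, 1], pvalue = res[, 2],
                    fdr = bh_adjust(res[, 2]), mean_expr = rowMeans(unclass(expr)),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}
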