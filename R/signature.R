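#' Fit a Cox-weighted signature model
#'
#' Gene-expression values of the panel genes are weighted by their joint
#' (multivariate) Cox regression coefficients against the survival
#' endpoint; the weighted sum is a raw risk score whose standard deviation
#' in the fitting cohort becomes the model's scale, so standardised scores
#' have SD 1 there. The model is refit per cohort in the original design;
#' freeze the returned object and [score_patients()] a new cohort for an
#' external validation instead.
#'
#' @param expr [expression_matrix()] for the fitting cohort (samples =
#'   patients).
#' @param panel a [gene_panel()]; genes absent from `expr` are dropped with
#'   the coverage logged.
#' @param clinical clinical data.frame with `patient_id`, `time`, `event`;
#'   patients are matched to `expr` columns by `patient_id`.
#' @param log2_expr log2-transform (pseudocount 1) the expression before
#'   the Cox fit; default TRUE.
#' @param ridge optional L2 penalty forwarded to [fit_cox()] when the
#'   unpenalised multivariate fit fails to converge.
#' @param reference_cohort name recorded on the model.
#' @return object of class `"signature_model"`: `panel`, `weights` (named
#'   per-gene beta), `score_sd`, `score_center`, `cutoff_fraction` (NA until
#'   [choose_cutoff_fraction()]), `log2_expr`, `reference_cohort`, `cox`
#'   (the underlying `"cox_ph"` fit).
#' @export
fit_weighted_model <- function(expr, panel, clinical, log2_expr = TRUE,
                               ridge = 0, reference_cohort = "reference") {
  genes <- intersect(panel$gene_ids, rownames(expr))
  if (!length(genes)) stop("no panel gene present in the expression matrix")
  message(sprintf("fit_weighted_model: %d of %d panel genes available (%.1f%%)",
                  length(genes), length(panel$gene_ids),
                  100 * length(genes) / length(panel$gene_ids)))
  idx <- match(clinical$patient_id, colnames(expr))
  if (any(is.na(idx))) stop("patient(s) missing from expression matrix: ",
                            paste(clinical$patient_id[is.na(idx)], collapse = ", "))
  x <- t(unclass(expr)[genes, idx, drop = FALSE])
  if (log2_expr) x <- log2(x + 1)
  fit <- fit_cox(clinical, x, ridge = ridge)
  if (!fit$converged)
    stop("multivariate Cox fit did not converge; retry with the ridge argument (e.g. ridge = 1)")
  raw <- as.numeric(x %*% fit$coef)
  sdv <- stats::sd(raw)
  if (!is.finite(sdv) || sdv <= 0) stop("degenerate score: zero variance in fitting cohort")
  structure(list(panel = panel, weights = fit$coef, score_sd = sdv,
                 score_center = mean(raw), cutoff_fraction = NA_real_,
                 log2_expr = log2_expr, reference_cohort = reference_cohort,
                 cox = fit),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature model (%d weighted genes, reference cohort '%s')\n",
              length(x$weights), x$reference_cohort))
  cat(sprintf("  score SD = %.4f; cutoff fraction = %s\n", x$score_sd,
              if (is.na(x$cutoff_fraction)) "unset" else format(x$cutoff_fraction)))
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
coef.signature_model <- function(object, ...) object$weights

#' Standardised signature scores for a cohort
#'
#' Per patient, the weighted sum of the model genes' expression divided by
#' the model's score SD (the standardisation the weighted models use).
#' Genes missing from the cohort are dropped with the overlap logged.
#'
#' @param model a `"signature_model"`.
#' @param expr cohort [expression_matrix()].
#' @return named score vector (higher = higher predicted hazard).
#' @export
score_patients <- function(model, expr) {
  genes <- intersect(names(model$weights), rownames(expr))
  if (!length(genes)) stop("no model gene present in this cohort")
  message(sprintf("score_patients: %d of %d model genes used (%.1f%%)",
                  length(genes), length(model$weights),
                  100 * length(genes) / length(model$weights)))
  x <- t(unclass(expr)[genes, , drop = FALSE])
  if (model$log2_expr) x <- log2(x + 1)
  raw <- as.numeric(x %*% model$weights[genes])
  stats::setNames(raw / model$score_sd, colnames(expr))
}

#' @export
predict.signature_model <- function(object, expr, ...) score_patients(object, expr)

#' Split a cohort into high and low risk by a transferred cutoff fraction
#'
#' The top `fraction` of patients by score are labelled high risk — the
#' same quantile split in every cohort, so a cutoff fraction defined in a
#' reference cohort transfers to others. Ties at the boundary are broken
#' by patient-id order with a warning.
#'
#' @param scores named standardised score vector.
#' @param fraction fraction labelled high, in (0, 1); usually the model's
#'   `cutoff_fraction`.
#' @return character vector (`"high"`/`"low"`) named by patient.
#' @export
transfer_cutoff <- function(scores, fraction) {
  if (is.na(fraction) || fraction <= 0 || fraction >= 1)
    stop("cutoff fraction must lie strictly between 0 and 1")
  n <- length(scores)
  n_high <- max(1L, min(n - 1L, as.integer(round(fraction * n))))
  ids <- names(scores) %||% as.character(seq_len(n))
  ord <- order(-scores, ids, method = "radix")
  boundary <- scores[ord][n_high]
  if (sum(scores == boundary) > 1 &&
      any(scores[ord][-seq_len(n_high)] == boundary))
    warning("score ties at the cutoff boundary broken by patient-id order")
  labels <- rep("low", n)
  labels[ord[seq_len(n_high)]] <- "high"
  stats::setNames(labels, ids)
}

#' Choose the risk-group cutoff fraction in a reference cohort
#'
#' Scans a grid of fractions and keeps the one whose high/low split
#' minimises the log-rank p-value in the reference cohort. The search is
#' exploratory — the winning p-value is optimistic and is flagged when not
#' significant — but the fraction itself is then transferred unchanged to
#' other cohorts.
#'
#' @param scores named score vector for the reference cohort.
#' @param clinical clinical table aligned by `patient_id`.
#' @param grid candidate fractions (default 0.25 to 0.75 by 0.05).
#' @return list with `fraction`, `p` (best log-rank p), `grid_p` (per
#'   candidate), `significant`.
#' @export
choose_cutoff_fraction <- function(scores, clinical,
                                   grid = seq(0.25, 0.75, by = 0.05)) {
  if (!length(grid)) stop("empty cutoff grid")
  idx <- match(names(scores), clinical$patient_id)
  if (any(is.na(idx))) stop("scored patients missing from clinical table")
  cl <- clinical[idx, ]
  if (!any(as.logical(cl$event))) stop("no events in reference cohort")
  ps <- vapply(grid, function(f) {
    lab <- transfer_cutoff(scores, f)
    if (length(unique(lab)) < 2) return(1)
    km_logrank(cl$time, cl$event, lab)$p
  }, numeric(1))
  best <- which.min(ps)
  if (ps[best] >= 0.05)
    message(sprintf("choose_cutoff_fraction: best split not significant (p = %.3g)", ps[best]))
  list(fraction = grid[best], p = ps[best],
       grid_p = stats::setNames(ps, grid), significant = ps[best] < 0.05)
}

#' Full prognostic evaluation of a signature model in a cohort
#'
#' Reproduces the validation battery: (1) univariate Cox per
#' clinicopathological covariate and for the standardised score; (2) a
#' multivariate model seeded with the univariate-significant covariates
#' (p < 0.05) plus the score, pruned by stepwise backward elimination of
#' the largest-p covariate at or above 0.05 — the score itself is exempt
#' and always reported; (3) Harrell's C-index of the final model with and
#' without the score, on the identical patient set; (4) Kaplan-Meier and
#' log-rank on the transferred high/low risk groups; (5) Wilcoxon rank-sum
#' of the score against each binary covariate.
#'
#' @param model a `"signature_model"` (with `cutoff_fraction` set, or
#'   `cutoff` supplied).
#' @param expr cohort [expression_matrix()].
#' @param clinical clinical table (`patient_id`, `time`, `event`, plus
#'   covariates).
#' @param covariates clinicopathological covariate column names.
#' @param cutoff cutoff fraction override; default the model's.
#' @return object of class `"signature_eval"`: `univariate` (data.frame),
#'   `multivariate` (`"cox_ph"`), `kept_covariates`, `cindex_with`,
#'   `cindex_without`, `logrank`, `km`, `risk_labels`, `wilcoxon`
#'   (data.frame), `scores`.
#' @export
evaluate_model <- function(model, expr, clinical, covariates,
                           cutoff = model$cutoff_fraction) {
  miss <- setdiff(covariates, names(clinical))
  if (length(miss)) stop("covariate column(s) missing: ", paste(miss, collapse = ", "))
  scores <- score_patients(model, expr)
  idx <- match(names(scores), clinical$patient_id)
  if (any(is.na(idx))) stop("scored patients missing from clinical table")
  cl <- clinical[idx, , drop = FALSE]
  cl$score <- unname(scores)

  vars <- c(covariates, "score")
  uni <- do.call(rbind, lapply(vars, function(v) {
    if (stats::sd(as.numeric(cl[[v]])) == 0)   # constant in this cohort
      return(data.frame(variable = v, hr = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p = NA_real_, cindex = NA_real_,
                        stringsAsFactors = FALSE))
    f <- fit_cox(cl, v)
    data.frame(variable = v, hr = f$hr, ci_lower = f$ci_lower,
               ci_upper = f$ci_upper, p = f$wald_p,
               cindex = harrell_c(predict(f), cl$time, cl$event),
               stringsAsFactors = FALSE)
  }))
  rownames(uni) <- NULL

  sig_cov <- uni$variable[!is.na(uni$p) & uni$p < 0.05 & uni$variable != "score"]
  if (!length(sig_cov))
    warning("no univariate-significant covariates; multivariate model contains the score only")
  # backward elimination: drop the worst covariate at p >= 0.05, keep the score
  kept <- sig_cov
  repeat {
    mfit <- fit_cox(cl, c(kept, "score"))
    pc <- mfit$wald_p[kept]
    if (!length(pc) || max(pc) < 0.05) break
    kept <- setdiff(kept, names(which.max(pc)))
  }

  with_lp <- predict(mfit)
  c_with <- harrell_c(with_lp, cl$time, cl$event)
  c_without <- if (length(kept)) {
    f0 <- fit_cox(cl, kept)
    harrell_c(predict(f0), cl$time, cl$event)
  } else 0.5  # intercept-only model ranks nobody
  stopifnot(length(with_lp) == nrow(cl))  # identical patient set for both C-indices

  risk <- logrank <- NULL
  if (!is.na(cutoff)) {
    risk <- transfer_cutoff(scores, cutoff)
    logrank <- km_logrank(cl$time, cl$event, risk[cl$patient_id])
  }

  wil <- do.call(rbind, lapply(covariates, function(v) {
    x <- cl[[v]]
    if (!is.logical(x) && !all(x %in% c(0, 1, NA))) return(NULL)
    x <- as.logical(x)
    if (length(unique(x[!is.na(x)])) < 2) return(NULL)
    w <- wilcoxon_ranksum(cl$score[x], cl$score[!x])
    data.frame(variable = v, U = w$U, p = w$p, stringsAsFactors = FALSE)
  }))

  structure(list(univariate = uni, multivariate = mfit,
                 kept_covariates = kept,
                 cindex_with = c_with, cindex_without = c_without,
                 logrank = logrank, km = if (!is.null(logrank)) logrank$km,
                 risk_labels = risk, wilcoxon = wil, scores = scores,
                 cutoff = cutoff),
            class = "signature_eval")
}

#' @export
print.signature_eval <- function(x, digits = 3, ...) {
  cat("univariate Cox:\n")
  print(cbind(x$univariate[1], round(x$univariate[-1], digits)))
  cat(sprintf("\nfinal multivariate model: %s + score\n",
              if (length(x$kept_covariates)) paste(x$kept_covariates, collapse = " + ")
              else "(none)"))
  print(x$multivariate)
  cat(sprintf("\nC-index with score %.3f, without %.3f (gain %.3f)\n",
              x$cindex_with, x$cindex_without, x$cindex_with - x$cindex_without))
  if (!is.null(x$logrank))
    cat(sprintf("risk groups (top %.0f%% high): log-rank p = %.4g\n",
                100 * x$cutoff, x$logrank$p))
  if (!is.null(x$wilcoxon)) {
    cat("\nscore vs clinicopathological variables (Wilcoxon):\n")
    print(cbind(x$wilcoxon[1], round(x$wilcoxon[-1], digits)))
  }
  invisible(x)
}

#' Serialise a signature model to JSON
#' @param model a `"signature_model"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_model <- function(model, path) {
  obj <- list(panel = list(gene_ids = model$panel$gene_ids,
                           direction = model$panel$direction,
                           provenance = model$panel$provenance),
              weights = as.list(model$weights),
              score_sd = model$score_sd,
              cutoff_fraction = model$cutoff_fraction,
              log2_expr = model$log2_expr,
              reference_cohort = model$reference_cohort)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialised signature model
#' @param path JSON path written by [write_signature_model()].
#' @return a `"signature_model"` (without the underlying Cox fit).
#' @export
read_signature_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(panel = gene_panel(obj$panel$gene_ids, obj$panel$direction,
                                    obj$panel$provenance %||% ""),
                 weights = unlist(obj$weights),
                 score_sd = obj$score_sd,
                 score_center = obj$score_center %||% 0,
                 cutoff_fraction = obj$cutoff_fraction %||% NA_real_,
                 log2_expr = obj$log2_expr %||% TRUE,
                 reference_cohort = obj$reference_cohort %||% "reference",
                 cox = NULL),
            class = "signature_model")
}
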