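#' Cox proportional-hazards regression
#'
#' Fits the Cox model by Newton-Raphson maximisation of the partial
#' likelihood with Efron (default) or Breslow handling of tied event
#' times. Convergence is declared when the largest absolute component of
#' the score vector drops below `tol` (default 1e-8) within `max_iter`
#' iterations; step-halving guards against overshooting. Standard errors
#' come from the observed information, p-values are two-sided Wald tests,
#' and 95% confidence intervals are Wald intervals on the log-hazard
#' scale. A monotone likelihood (complete separation) is flagged
#' non-converged rather than reported.
#'
#' @param clinical data.frame with columns `time` (> 0), logical or 0/1
#'   `event`, and the covariate columns.
#' @param covariates character vector of covariate column names, or a
#'   numeric matrix/data.frame of covariate values aligned with `clinical`.
#' @param ties `"efron"` or `"breslow"`.
#' @param tol score-convergence tolerance.
#' @param max_iter Newton-Raphson iteration cap.
#' @param ridge optional L2 penalty lambda added to the negative partial
#'   log-likelihood (0 = none); useful when the unpenalised fit separates.
#' @return object of class `"cox_ph"`: `coef`, `se`, `hr`, `ci_lower`,
#'   `ci_upper`, `wald_p`, `loglik` (c(null, final)), `vcov`, `ties`,
#'   `converged`, `iterations`, `n`, `n_event`, `linear_predictor`.
#' @export
fit_cox <- function(clinical, covariates, ties = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 50, ridge = 0) {
  ties <- match.arg(ties)
  if (is.character(covariates)) {
    miss <- setdiff(covariates, names(clinical))
    if (length(miss)) stop("covariate column(s) missing: ", paste(miss, collapse = ", "))
    x <- as.matrix(as.data.frame(lapply(clinical[covariates], as.numeric)))
    colnames(x) <- covariates
  } else {
    x <- as.matrix(covariates)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  time <- clinical$time
  event <- as.logical(clinical$event)
  if (any(is.na(time)) || any(time <= 0)) stop("times must be positive and non-missing")
  if (!any(event)) stop("no events in the data")
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const)) stop("constant covariate(s): ",
                       paste(colnames(x)[const], collapse = ", "))

  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord, , drop = FALSE]
  p <- ncol(x); n <- nrow(x)
  ev_times <- unique(time[event])

  # partial log-likelihood, score and information at beta
  plik <- function(beta) {
    eta <- as.numeric(x %*% beta)
    w <- exp(eta)
    ll <- 0
    U <- numeric(p)
    I <- matrix(0, p, p)
    for (t0 in ev_times) {
      R <- which(time >= t0)           # risk set
      D <- which(time == t0 & event)   # deaths at t0
      d <- length(D)
      sw_R <- sum(w[R]); sx_R <- colSums(w[R] * x[R, , drop = FALSE])
      sxx_R <- crossprod(x[R, , drop = FALSE] * w[R], x[R, , drop = FALSE])
      if (ties == "breslow") {
        ll <- ll + sum(eta[D]) - d * log(sw_R)
        U <- U + colSums(x[D, , drop = FALSE]) - d * sx_R / sw_R
        I <- I + d * (sxx_R / sw_R - tcrossprod(sx_R / sw_R))
      } else {
        sw_D <- sum(w[D]); sx_D <- colSums(w[D] * x[D, , drop = FALSE])
        sxx_D <- crossprod(x[D, , drop = FALSE] * w[D], x[D, , drop = FALSE])
        ll <- ll + sum(eta[D])
        for (l in seq_len(d) - 1) {
          f <- l / d
          sw <- sw_R - f * sw_D
          sx <- sx_R - f * sx_D
          sxx <- sxx_R - f * sxx_D
          ll <- ll - log(sw)
          U <- U + colSums(x[D, , drop = FALSE]) / d - sx / sw
          I <- I + sxx / sw - tcrossprod(sx / sw)
        }
      }
    }
    if (ridge > 0) {
      ll <- ll - ridge * sum(beta^2)
      U <- U - 2 * ridge * beta
      I <- I + diag(2 * ridge, p)
    }
    list(ll = ll, U = U, I = I)
  }

  beta <- numeric(p)
  fit0 <- plik(beta)
  ll0 <- fit0$ll
  cur <- fit0
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    if (max(abs(cur$U)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$I, cur$U), error = function(e) NULL)
    if (is.null(step)) break
    # step halving: never accept a decrease in the partial likelihood
    h <- 1
    repeat {
      cand <- beta + h * step
      new <- plik(cand)
      if (new$ll >= cur$ll - 1e-12 || h < 1e-4) break
      h <- h / 2
    }
    beta <- beta + h * step
    cur <- new
    if (max(abs(beta)) > 50) break  # monotone likelihood / separation
  }
  if (max(abs(cur$U)) < tol) converged <- TRUE
  if (max(abs(beta)) > 50) converged <- FALSE

  vcov <- tryCatch(solve(cur$I), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov), 0))
  z <- beta / se
  out <- list(coef = stats::setNames(beta, colnames(x)),
              se = stats::setNames(se, colnames(x)),
              hr = exp(beta),
              ci_lower = exp(beta - 1.959964 * se),
              ci_upper = exp(beta + 1.959964 * se),
              wald_p = 2 * stats::pnorm(-abs(z)),
              loglik = c(null = ll0, final = cur$ll),
              vcov = vcov, ties = ties, ridge = ridge,
              converged = converged, iterations = iter,
              n = n, n_event = sum(event),
              linear_predictor = stats::setNames(as.numeric(x %*% beta)[order(ord)],
                                                 clinical$patient_id %||% rownames(clinical)))
  class(out) <- "cox_ph"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cox_ph <- function(x, digits = 4, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d%s\n",
              x$ties, x$n, x$n_event,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  tab <- data.frame(coef = x$coef, HR = x$hr,
                    `lower95` = x$ci_lower, `upper95` = x$ci_upper,
                    se = x$se, p = x$wald_p, check.names = FALSE)
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.cox_ph <- function(object, ...) {
  print(object)
  cat(sprintf("partial log-likelihood: %.4f (null %.4f)\n",
              object$loglik["final"], object$loglik["null"]))
  invisible(object)
}

#' @export
coef.cox_ph <- function(object, ...) object$coef

#' @export
vcov.cox_ph <- function(object, ...) object$vcov

#' @export
logLik.cox_ph <- function(object, ...) {
  structure(object$loglik[["final"]], df = length(object$coef), class = "logLik")
}

#' @export
confint.cox_ph <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coef - q * object$se, object$coef + q * object$se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Linear predictor for new data
#' @param object a `"cox_ph"` fit.
#' @param newdata data.frame containing the fitted covariate columns; when
#'   omitted the training linear predictor is returned.
#' @param ... unused.
#' @return numeric linear predictor (log relative hazard).
#' @export
predict.cox_ph <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$linear_predictor)
  x <- as.matrix(as.data.frame(lapply(newdata[names(object$coef)], as.numeric)))
  as.numeric(x %*% object$coef)
}
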