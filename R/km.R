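#' Kaplan-Meier product-limit estimate
#'
#' @param time positive follow-up times.
#' @param event logical event indicator (FALSE = censored).
#' @return object of class `"km_est"`: `time` (distinct event times),
#'   `n_risk`, `n_event`, `surv` (non-increasing, starting below 1 only
#'   after the first event; survival at t = 0 is 1).
#' @export
km_fit <- function(time, event) {
  if (any(time <= 0)) stop("times must be positive")
  event <- as.logical(event)
  ts <- sort(unique(time[event]))
  n_risk <- vapply(ts, function(t0) sum(time >= t0), numeric(1))
  n_event <- vapply(ts, function(t0) sum(time == t0 & event), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = ts, n_risk = n_risk, n_event = n_event, surv = surv,
                 n = length(time)), class = "km_est")
}

#' @export
print.km_est <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, %d event times\n",
              x$n, length(x$time)))
  print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                   surv = round(x$surv, 4)))
  invisible(x)
}

#' Survival probability at given times
#' @param km a `"km_est"`.
#' @param t times at which to evaluate the step function.
#' @return survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(t0) {
    i <- sum(km$time <= t0)
    if (i == 0) 1 else km$surv[i]
  }, numeric(1))
}

#' Log-rank test and per-group Kaplan-Meier curves
#'
#' The standard observed-minus-expected log-rank statistic with the
#' hypergeometric variance, chi-squared with (groups - 1) degrees of
#' freedom; two-sided. Symmetric under group relabelling.
#'
#' @param time,event follow-up times and event indicators.
#' @param group group label per patient (>= 2 nonempty groups).
#' @return object of class `"logrank"`: `chisq`, `df`, `p`, `observed`,
#'   `expected` (per group), `km` (named list of per-group `"km_est"`).
#' @export
km_logrank <- function(time, event, group) {
  group <- as.character(group)
  event <- as.logical(event)
  tab <- table(group)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab == 0)) stop("empty group")
  gs <- names(tab)
  ts <- sort(unique(time[event]))
  O <- stats::setNames(numeric(length(gs)), gs)
  E <- stats::setNames(numeric(length(gs)), gs)
  V <- matrix(0, length(gs), length(gs), dimnames = list(gs, gs))
  for (t0 in ts) {
    at_risk <- time >= t0
    n <- sum(at_risk)
    d <- sum(time == t0 & event)
    if (n < 1 || d < 1) next
    ng <- vapply(gs, function(g) sum(at_risk & group == g), numeric(1))
    dg <- vapply(gs, function(g) sum(time == t0 & event & group == g), numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      mult <- d * (n - d) / (n - 1)
      V <- V + mult * (diag(ng / n, length(gs)) - tcrossprod(ng / n)) # hypergeometric
    }
  }
  k <- length(gs) - 1
  oe <- (O - E)[seq_len(k)]
  Vi <- tryCatch(solve(V[seq_len(k), seq_len(k), drop = FALSE]),
                 error = function(e) NULL)
  chisq <- if (is.null(Vi)) 0 else as.numeric(t(oe) %*% Vi %*% oe)
  km <- lapply(stats::setNames(gs, gs), function(g)
    km_fit(time[group == g], event[group == g]))
  structure(list(chisq = chisq, df = k,
                 p = stats::pchisq(chisq, df = k, lower.tail = FALSE),
                 observed = O, expected = E, km = km),
            class = "logrank")
}

#' @export
print.logrank <- function(x, ...) {
  cat(sprintf("log-rank test: chisq = %.4f on %d df, p = %.4g\n",
              x$chisq, x$df, x$p))
  print(data.frame(observed = x$observed, expected = round(x$expected, 2)))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Over all usable patient pairs — those where the patient with the
#' strictly shorter follow-up time experienced the event — the fraction in
#' which the higher risk score went to the shorter survival. Score ties
#' count 1/2; pairs censored before the other's time, and pairs with tied
#' times, are unusable.
#'
#' @param scores risk score per patient (higher = higher risk).
#' @param time,event follow-up and event indicator, aligned with `scores`.
#' @return concordance in [0, 1].
#' @export
harrell_c <- function(scores, time, event) {
  n <- length(scores)
  if (length(time) != n || length(event) != n) stop("inputs must be aligned")
  event <- as.logical(event)
  conc <- 0; usable <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      s <- if (time[i] < time[j]) i else j   # shorter
      l <- if (time[i] < time[j]) j else i
      if (!event[s]) next                    # censored first: unusable
      usable <- usable + 1
      conc <- conc + if (scores[s] > scores[l]) 1
                     else if (scores[s] == scores[l]) 0.5 else 0
    }
  }
  if (!usable) stop("no usable pairs for concordance")
  conc / usable
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney test: exact when the combined sample size is at
#' most 20 and there are no ties, the tie-corrected normal approximation
#' otherwise.
#'
#' @param x,y the two samples.
#' @return list with `U` (statistic for `x`) and `p`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}
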