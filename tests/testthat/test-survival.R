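test_that("Cox fit maximises the written partial likelihood (brute-force oracle)", {
  df <- cox_fixture()
  fit <- fit_cox(df, "x")
  # independent grid + golden-section maximiser of the partial likelihood
  grid <- seq(-4, 4, by = 0.1)
  ll <- vapply(grid, partial_loglik_1d, numeric(1),
               time = df$time, event = df$event, x = df$x)
  b0 <- grid[which.max(ll)]
  oracle <- golden_max(function(b) partial_loglik_1d(b, df$time, df$event, df$x),
                       b0 - 0.2, b0 + 0.2)
  expect_equal(unname(coef(fit)), oracle, tolerance = 1e-5)
  expect_true(fit$converged)
})

test_that("Efron and Breslow agree exactly without ties and match the survival package", {
  df <- cox_fixture()
  fe <- fit_cox(df, "x", ties = "efron")
  fb <- fit_cox(df, "x", ties = "breslow")
  expect_equal(coef(fe), coef(fb), tolerance = 1e-10)

  skip_if_not_installed("survival")
  # tied event times exercise both corrections
  set.seed(2)
  dft <- data.frame(time = rep(c(3, 5, 8, 11), 5), event = rbinom(20, 1, 0.8) == 1,
                    x1 = rnorm(20), x2 = rbinom(20, 1, 0.5))
  dft$event[1] <- TRUE
  for (ties in c("efron", "breslow")) {
    mine <- fit_cox(dft, c("x1", "x2"), ties = ties)
    ref <- survival::coxph(survival::Surv(time, event) ~ x1 + x2, dft, ties = ties)
    expect_equal(unname(coef(mine)), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-7)
    expect_equal(unname(mine$loglik["final"]), ref$loglik[2], tolerance = 1e-7)
  }
})

test_that("Cox fit is equivariant under affine covariate rescaling", {
  df <- cox_fixture()
  f1 <- fit_cox(df, "x")
  df$xs <- 10 * df$x + 3
  f2 <- fit_cox(df, "xs")
  expect_equal(unname(coef(f1)), 10 * unname(coef(f2)), tolerance = 1e-7)
  expect_equal(unname(f1$wald_p), unname(f2$wald_p), tolerance = 1e-7)
})

test_that("Cox fit rejects degenerate inputs and flags separation", {
  df <- cox_fixture()
  none <- df; none$event <- FALSE
  expect_error(fit_cox(none, "x"), "no events")
  const <- df; const$x <- 1
  expect_error(fit_cox(const, "x"), "constant")
  # perfectly separating covariate: monotone likelihood
  sep <- df
  sep$event <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  sep$x <- c(5, 4.8, 4.6, 4.4, -5, -5.2, -5.4, -5.6)
  fitsep <- suppressWarnings(fit_cox(sep, "x"))
  expect_false(fitsep$converged)
})

test_that("null covariates give nominal Wald coverage", {
  covered <- 0
  for (s in 1:100) {
    set.seed(600 + s)
    d <- data.frame(time = rexp(500, 0.01), event = runif(500) < 0.7, x = rnorm(500))
    f <- fit_cox(d, "x")
    covered <- covered + (abs(coef(f)) < 2 * f$se)
  }
  expect_gte(covered, 93)
})

test_that("Kaplan-Meier curves have the closed-form census properties", {
  # no censoring, distinct times: steps of 1/n
  km <- km_fit(c(3, 1, 7, 5), rep(TRUE, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km_surv_at(km, 0), 1)
  expect_equal(km_surv_at(km, c(1, 4, 100)), c(0.75, 0.5, 0))
  # survival is non-increasing with censoring interleaved
  km2 <- km_fit(c(2, 3, 3, 5, 8, 9), c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_true(all(diff(km2$surv) <= 0))
  expect_error(km_fit(c(0, 1), c(TRUE, TRUE)), "positive")
})

test_that("log-rank matches the hand O-E/V computation and is group-symmetric", {
  time <- c(6, 7, 10, 15, 19, 25, 13, 21, 8, 17)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  grp <- rep(c("ctrl", "trt"), each = 5)
  lr <- km_logrank(time, event, grp)
  expect_equal(lr$chisq, logrank_by_hand(time, event, grp == "ctrl"), tolerance = 1e-10)
  # symmetry under relabelling
  lr2 <- km_logrank(time, event, ifelse(grp == "ctrl", "b", "a"))
  expect_equal(lr$chisq, lr2$chisq, tolerance = 1e-12)
  expect_equal(lr$p, lr2$p, tolerance = 1e-12)

  # identical groups: statistic 0, p = 1
  t2 <- rep(c(4, 9, 13), 2); e2 <- rep(TRUE, 6)
  lr0 <- km_logrank(t2, e2, rep(c("a", "b"), 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  skip_if_not_installed("survival")
  ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(lr$chisq, ref$chisq, tolerance = 1e-10)
})

test_that("Harrell's C enumerates usable pairs correctly", {
  # all events, scores reverse-ordered to times: perfect concordance
  expect_equal(harrell_c(c(5, 4, 3, 2), 1:4, rep(TRUE, 4)), 1)
  # constant score: all ties
  expect_equal(harrell_c(rep(2, 5), 1:5, rep(TRUE, 5)), 0.5)
  # worked enumeration: 3 usable pairs, 2 concordant
  expect_equal(harrell_c(c(3, 1, 2), c(2, 4, 6), rep(TRUE, 3)), 2 / 3)
  # censored-first pairs are unusable
  expect_equal(harrell_c(c(3, 1, 2), c(2, 4, 6), c(FALSE, TRUE, TRUE)), 0)
  expect_error(harrell_c(1:2, c(3, 3), c(TRUE, TRUE)), "no usable pairs")
  # complement identity without score ties
  set.seed(77)
  sc <- rnorm(30); tm <- rexp(30); ev <- runif(30) < 0.6; ev[1] <- TRUE
  expect_equal(harrell_c(sc, tm, ev) + harrell_c(-sc, tm, ev), 1)
})

test_that("Wilcoxon rank-sum switches between exact and approximate correctly", {
  # complete separation at 3 vs 3: exact two-sided p = 2/20
  w <- wilcoxon_ranksum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(w$p, 0.1)
  expect_equal(w$U, 0)
  # identical samples
  expect_gte(wilcoxon_ranksum(as.numeric(1:5), as.numeric(1:5))$p, 0.99)
  expect_gte(wilcoxon_ranksum(1:5 + 0.5, 1:5 + 0.25)$p, 0.42)
  set.seed(10)
  x <- rnorm(15); y <- rnorm(15, 0.5)   # combined n = 30 -> approximation
  approx_p <- wilcoxon_ranksum(x, y)$p
  exact_p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  expect_lt(abs(approx_p - exact_p), 0.01)
  expect_error(wilcoxon_ranksum(numeric(0), 1), "nonempty")
})
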