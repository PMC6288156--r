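test_that("TMM scale factors satisfy the symmetry, scaling and product constraints", {
  em <- toy_counts(G = 400, n = 4, seed = 3, mu = 80)
  same <- unclass(em)[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  f_same <- norm_factors(expression_matrix(same, "counts"))
  expect_equal(unname(as.numeric(f_same)), rep(1, 3), tolerance = 1e-12)

  # doubling a column (no DE) doubles its factor relative to the reference
  y <- unclass(em)[, 1:2]
  y[, 2] <- y[, 1] * 2
  f <- norm_factors(expression_matrix(y, "counts"))
  expect_equal(unname(f[2] / f[1]), 2, tolerance = 0.05)
  expect_equal(prod(f), 1, tolerance = 1e-12)  # two samples: f1*f2 = 1

  zero <- unclass(em); zero[, 2] <- 0
  expect_error(norm_factors(expression_matrix(zero, "counts")), "zero total")
})

test_that("TMM composition factors agree with the established implementation", {
  skip_if_not_installed("edgeR")
  set.seed(1)
  y <- matrix(rnbinom(500 * 6, mu = runif(500, 10, 300), size = 5), nrow = 500,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:6)))
  y[, 3] <- y[, 3] * 3L
  mine <- attr(norm_factors(expression_matrix(y, "counts")), "tmm")
  ref <- edgeR::calcNormFactors(edgeR::DGEList(y))$samples$norm.factors
  expect_equal(unname(mine), ref, tolerance = 1e-8)
})

test_that("dispersion estimation recovers known truth and survives degenerate input", {
  set.seed(21)
  grp <- rep(c("A", "B"), each = 5)
  # Poisson counts: estimated common dispersion near zero
  yp <- matrix(rpois(200 * 10, lambda = 60), nrow = 200,
               dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:10)))
  dp <- estimate_dispersion(expression_matrix(yp, "counts"), grp)
  expect_lt(dp$common, 0.05)

  # NB alpha = 0.4
  yn <- matrix(rnbinom(2000 * 10, mu = 60, size = 1 / 0.4), nrow = 2000,
               dimnames = list(sprintf("g%04d", 1:2000), paste0("s", 1:10)))
  dn <- estimate_dispersion(expression_matrix(yn, "counts"), grp)
  expect_gt(dn$common, 0.25)
  expect_lt(dn$common, 0.6)
  expect_true(all(dn$tagwise > 0))

  # constant counts: floor, no crash
  yc <- matrix(5, nrow = 10, ncol = 6,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  dc <- estimate_dispersion(expression_matrix(yc, "counts"), rep(c("A", "B"), each = 3))
  expect_true(all(dc$tagwise >= 1e-6))
  expect_lt(dc$common, 1e-3)
})

test_that("exact test returns p = 1 for exchangeable groups and honours the zero convention", {
  y <- unclass(toy_counts(G = 15, n = 3))
  same <- cbind(y, y)
  colnames(same) <- paste0("s", 1:6)
  same[3, ] <- 0
  de <- nb_exact_test(expression_matrix(same, "counts"),
                      rep(c("A", "B"), each = 3), dispersion = 0.1,
                      factors = stats::setNames(rep(1, 6), colnames(same)))
  expect_true(all(de$pvalue == 1))
  expect_equal(de$log2fc[3], 0)
  expect_equal(de$fdr, rep(1, 15))
})

test_that("exact test matches the binomial test in the Poisson limit", {
  y <- rbind(a = c(3, 5, 2, 40, 38, 35), b = c(10, 12, 9, 11, 13, 9))
  colnames(y) <- paste0("s", 1:6)
  em <- expression_matrix(y, "counts")
  fac <- stats::setNames(rep(1, 6), colnames(y))
  de <- nb_exact_test(em, rep(c("A", "B"), each = 3), dispersion = 1e-9, factors = fac)
  for (g in 1:2) {
    z1 <- sum(y[g, 1:3]); z2 <- sum(y[g, 4:6])
    pb <- stats::binom.test(z1, z1 + z2, p = 0.5)$p.value
    expect_equal(de$pvalue[g], pb, tolerance = 1e-6)
  }
})

test_that("exact test equals exhaustive enumeration of the conditional distribution", {
  # toy gene: group A total 2, group B total 40, equal library sizes, alpha = 0.1
  za <- 2; zb <- 40; na <- 3; nb <- 3; alpha <- 0.1
  z <- za + zb; mu <- z / (na + nb); r <- 1 / alpha
  pr <- vapply(0:z, function(a)
    dnbinom(a, size = na * r, mu = na * mu) *
      dnbinom(z - a, size = nb * r, mu = nb * mu), numeric(1))
  pr <- pr / sum(pr)
  p_oracle <- sum(pr[pr <= pr[za + 1] * (1 + 1e-12)])

  y <- rbind(g1 = c(1, 1, 0, 14, 13, 13))
  colnames(y) <- paste0("s", 1:6)
  de <- nb_exact_test(expression_matrix(y, "counts"), rep(c("A", "B"), each = 3),
                      dispersion = alpha,
                      factors = stats::setNames(rep(1, 6), colnames(y)))
  expect_equal(de$pvalue[1], p_oracle, tolerance = 1e-10)
})

test_that("swapping group labels negates log2fc and preserves p-values", {
  em <- toy_counts(G = 60, n = 8, seed = 5)
  g <- rep(c("A", "B"), each = 4)
  d1 <- nb_exact_test(em, factor(g, levels = c("A", "B")), dispersion = 0.1)
  d2 <- nb_exact_test(em, factor(g, levels = c("B", "A")), dispersion = 0.1)
  expect_equal(d1$pvalue, d2$pvalue, tolerance = 1e-12)
  expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-12)
  # permutation within groups changes nothing
  perm <- c(4:1, 8:5)
  d3 <- nb_exact_test(em[, perm], factor(g[perm], levels = c("A", "B")), dispersion = 0.1)
  expect_equal(d1$pvalue, d3$pvalue, tolerance = 1e-12)
})

test_that("whole pipeline p-values track the established NB exact test", {
  skip_if_not_installed("edgeR")
  set.seed(42)
  G <- 300; n <- 8
  mu <- runif(G, 20, 200)
  y <- matrix(rnbinom(G * n, mu = mu, size = 10), nrow = G,
              dimnames = list(sprintf("g%03d", 1:G), paste0("s", 1:n)))
  y[1:30, 5:8] <- matrix(rnbinom(30 * 4, mu = mu[1:30] * 4, size = 10), nrow = 30)
  grp <- rep(c("A", "B"), each = 4)
  mine <- nb_exact_test(expression_matrix(y, "counts"), factor(grp), dispersion = 0.1)
  dge <- edgeR::calcNormFactors(edgeR::DGEList(counts = y, group = grp))
  ref <- edgeR::exactTest(dge, dispersion = 0.1)$table
  expect_lt(max(abs(mine$pvalue - ref$PValue)), 0.05)
  expect_identical(mine$fdr < 0.05, stats::p.adjust(ref$PValue, "BH") < 0.05)
})

test_that("BH adjustment equals the direct step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # direct step-up oracle on arbitrary values
  set.seed(9)
  p <- runif(50)
  ord <- order(p)
  stepup <- p[ord] * 50 / seq_len(50)
  stepup <- rev(cummin(rev(stepup)))
  oracle <- numeric(50); oracle[ord] <- pmin(stepup, 1)
  expect_equal(bh_adjust(p), oracle, tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
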