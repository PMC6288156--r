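make_cohort <- function(seed = 5, n = 200, beta = c(gA = 0.8, gB = -0.5), cens = 0.4) {
  panel <- gene_panel(c("gA", "gB", "gC"), "down")
  gen_survival_cohort(n, panel, beta, censoring_rate = cens, seed = seed,
                      n_noise_genes = 5)
}

test_that("a single-gene panel weight equals the univariate Cox coefficient", {
  co <- make_cohort()
  m <- suppressMessages(fit_weighted_model(co$expr, gene_panel("gA"), co$clinical))
  x <- log2(unclass(co$expr)["gA", co$clinical$patient_id] + 1)
  uni <- fit_cox(cbind(co$clinical, gA = x), "gA")
  expect_equal(unname(coef(m)), unname(coef(uni)), tolerance = 1e-8)
})

test_that("standardised scores have SD one in the fitting cohort and are linear", {
  co <- make_cohort()
  panel <- gene_panel(c("gA", "gB", "gC"), "down")
  m <- suppressMessages(fit_weighted_model(co$expr, panel, co$clinical))
  sc <- suppressMessages(score_patients(m, co$expr))
  expect_equal(sd(sc), 1, tolerance = 1e-10)

  # changing one gene's log2 expression by dx moves the score by beta*dx/sd
  e2 <- unclass(co$expr)
  e2["gA", ] <- e2["gA", ] * 4  # +2 log2 units... on x+1 scale approximately
  e2["gA", ] <- 2^(log2(unclass(co$expr)["gA", ] + 1) + 2) - 1  # exactly +2
  sc2 <- suppressMessages(score_patients(m, expression_matrix(e2, "fpkm")))
  expect_equal(unname(sc2 - sc), rep(2 * unname(coef(m)["gA"]) / m$score_sd, length(sc)),
               tolerance = 1e-8)

  # gene order invariance
  m2 <- suppressMessages(fit_weighted_model(co$expr, gene_panel(c("gC", "gB", "gA")),
                                            co$clinical))
  sc3 <- suppressMessages(score_patients(m2, co$expr))
  expect_equal(sort(names(sc)), sort(names(sc3)))
  expect_equal(sc, sc3[names(sc)], tolerance = 1e-8)
})

test_that("recovered weight signs match the generating coefficients", {
  hits <- 0
  for (s in 1:10) {
    co <- make_cohort(seed = 100 + s, n = 500, beta = c(gA = 0.8, gB = -0.6, gC = 0.5))
    m <- suppressMessages(fit_weighted_model(co$expr, gene_panel(c("gA", "gB", "gC")),
                                             co$clinical))
    hits <- hits + all(sign(coef(m)) == sign(c(0.8, -0.6, 0.5)))
  }
  expect_gte(hits, 9)
})

test_that("planted high-risk patients score above low-risk patients", {
  co <- make_cohort(seed = 9, n = 200, beta = c(gA = 1))
  m <- suppressMessages(fit_weighted_model(co$expr, gene_panel("gA"), co$clinical))
  sc <- suppressMessages(score_patients(m, co$expr))
  eta <- co$truth$linear_predictor
  hi <- eta > median(eta)
  w <- wilcoxon_ranksum(sc[hi], sc[!hi])
  expect_lt(w$p, 0.01)
  expect_gt(mean(sc[hi]), mean(sc[!hi]))
})

test_that("cutoff transfer labels the top fraction and ignores monotone rescaling", {
  sc <- stats::setNames(as.numeric(1:10), paste0("p", sprintf("%02d", 1:10)))
  lab <- transfer_cutoff(sc, 0.5)
  expect_setequal(names(lab)[lab == "high"], names(sc)[6:10])
  # idempotent on the reference split
  expect_identical(transfer_cutoff(sc, 0.5), lab)
  # invariant to monotone transformation
  expect_identical(transfer_cutoff(exp(sc / 3), 0.5), lab)
  expect_error(transfer_cutoff(sc, 0), "between 0 and 1")
  expect_warning(transfer_cutoff(stats::setNames(c(1, 2, 2, 3), paste0("p", 1:4)), 0.5),
                 "ties")
})

test_that("the cutoff search finds a planted risk fraction and is deterministic", {
  set.seed(42)
  n <- 300
  hi <- seq_len(n) <= 0.3 * n  # 30% high-risk subpopulation
  haz <- ifelse(hi, 0.02, 0.002)
  time <- rexp(n, haz); cens <- rexp(n, 0.004)
  cl <- data.frame(patient_id = paste0("p", sprintf("%03d", 1:n)),
                   time = pmin(time, cens), event = time <= cens)
  sc <- stats::setNames(ifelse(hi, 1, 0) + rnorm(n, 0, 0.2), cl$patient_id)
  pick <- choose_cutoff_fraction(sc, cl)
  expect_lt(abs(pick$fraction - 0.3), 0.1 + 1e-9)
  expect_true(pick$significant)
  pick2 <- choose_cutoff_fraction(sc, cl)
  expect_identical(pick, pick2)

  # null scores: flagged non-significant most of the time; still returns a fraction
  scn <- stats::setNames(rnorm(n), cl$patient_id)
  pn <- suppressMessages(choose_cutoff_fraction(scn, cl))
  expect_true(pn$fraction %in% seq(0.25, 0.75, by = 0.05))
})

test_that("backward elimination follows the hand-executed path", {
  set.seed(33)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)  # x1 strong, x2 weak, x3 null
  sc <- rnorm(n)
  haz <- 0.01 * exp(0.9 * x1 + 0.12 * x2 + 0.6 * sc)
  time <- rexp(n, haz); cens <- rexp(n, 0.005)
  genes <- matrix(2^(sc + 4), nrow = 1,
                  dimnames = list("gS", paste0("p", sprintf("%03d", 1:n))))
  # model whose single weight reproduces sc up to affine transform
  clin <- data.frame(patient_id = colnames(genes), time = pmin(time, cens),
                     event = time <= cens, x1 = x1, x2 = x2, x3 = x3)
  m <- suppressMessages(fit_weighted_model(expression_matrix(genes, "fpkm"),
                                           gene_panel("gS"), clin))
  ev <- suppressMessages(evaluate_model(m, expression_matrix(genes, "fpkm"),
                                        clin, c("x1", "x2", "x3")))

  # hand-execute the same elimination with the same primitives
  cl2 <- clin
  cl2$score <- unname(ev$scores[cl2$patient_id])
  uni_p <- vapply(c("x1", "x2", "x3"), function(v) fit_cox(cl2, v)$wald_p, numeric(1))
  kept <- names(uni_p)[uni_p < 0.05]
  repeat {
    f <- fit_cox(cl2, c(kept, "score"))
    pc <- f$wald_p[kept]
    if (!length(pc) || max(pc) < 0.05) break
    kept <- setdiff(kept, names(which.max(pc)))
  }
  expect_identical(sort(ev$kept_covariates), sort(kept))
  expect_true("score" %in% names(coef(ev$multivariate)))
  # both C-indices computed on the identical patient set; adding signal helps
  expect_gte(ev$cindex_with, ev$cindex_without - 1e-9)
})

test_that("a score-only signal yields a score-only final model with C-index gain", {
  co <- make_cohort(seed = 19, n = 300, beta = c(gA = 1.2), cens = 0.3)
  m <- suppressMessages(fit_weighted_model(co$expr, gene_panel("gA"), co$clinical))
  ev <- suppressWarnings(suppressMessages(
    evaluate_model(m, co$expr, co$clinical,
                   c("gleason_gt7", "stage_pt3", "margin_pos"), cutoff = 0.5)))
  expect_gt(ev$cindex_with, ev$cindex_without)
  expect_lt(ev$univariate$p[ev$univariate$variable == "score"], 0.001)
  expect_lt(ev$logrank$p, 0.05)
})

test_that("signature models survive a JSON round trip", {
  co <- make_cohort()
  m <- suppressMessages(fit_weighted_model(co$expr, gene_panel(c("gA", "gB")), co$clinical))
  m$cutoff_fraction <- 0.4
  path <- withr::local_tempfile(fileext = ".json")
  write_signature_model(m, path)
  back <- read_signature_model(path)
  expect_equal(back$weights, m$weights, tolerance = 1e-12)
  expect_equal(back$score_sd, m$score_sd, tolerance = 1e-12)
  expect_equal(back$cutoff_fraction, 0.4)
  sc1 <- suppressMessages(score_patients(m, co$expr))
  sc2 <- suppressMessages(score_patients(back, co$expr))
  expect_equal(sc1, sc2, tolerance = 1e-12)
})
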