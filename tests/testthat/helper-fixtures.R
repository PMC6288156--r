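# shared fixtures built in code

# small deterministic count matrix
toy_counts <- function(G = 20, n = 6, seed = 11, mu = 50, size = 10) {
  set.seed(seed)
  y <- matrix(rnbinom(G * n, mu = mu, size = size), nrow = G,
              dimnames = list(sprintf("g%03d", seq_len(G)), paste0("s", seq_len(n))))
  expression_matrix(y, "counts")
}

# minimal de_table for rule tests
de_row <- function(gene, lfc, fdr) {
  out <- data.frame(gene_id = gene, log2fc = lfc, pvalue = fdr, fdr = fdr,
                    mean_expr = rep(10, length(gene)), stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

# 8-patient survival fixture, no tied event times
cox_fixture <- function() {
  data.frame(
    patient_id = paste0("p", 1:8),
    time  = c(5, 8, 12, 16, 23, 27, 30, 34),
    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    x     = c(1.1, 0.4, 0.9, -0.3, -0.8, 0.2, -1.2, -0.5),
    stringsAsFactors = FALSE)
}

# independent partial log-likelihood (Breslow form; fixture has no ties)
partial_loglik_1d <- function(beta, time, event, x) {
  eta <- beta * x
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# golden-section maximiser on [lo, hi]
golden_max <- function(f, lo, hi, tol = 1e-9) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (abs(b - a) > tol) {
    if (f1 < f2) { a <- c1; c1 <- c2; f1 <- f2; c2 <- a + gr * (b - a); f2 <- f(c2) }
    else { b <- c2; c2 <- c1; f2 <- f1; c1 <- b - gr * (b - a); f1 <- f(c1) }
  }
  (a + b) / 2
}

# O(n^3) reference agglomerative clustering (complete linkage, euclidean),
# returns list of merge heights and member sets in merge order
naive_complete_linkage <- function(x) {
  # x: samples in rows
  clusters <- lapply(seq_len(nrow(x)), function(i) rownames(x)[i])
  d <- as.matrix(dist(x))
  heights <- numeric(0); sets <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- max(d[clusters[[i]], clusters[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    heights <- c(heights, bestd)
    sets <- c(sets, list(sort(merged)))
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, sets = sets)
}

# independent two-group log-rank by the scalar O-E / V formula
logrank_by_hand <- function(time, event, g1_mask) {
  ts <- sort(unique(time[event]))
  O1 <- E1 <- V <- 0
  for (t0 in ts) {
    at <- time >= t0
    n <- sum(at); n1 <- sum(at & g1_mask)
    dth <- sum(time == t0 & event); d1 <- sum(time == t0 & event & g1_mask)
    O1 <- O1 + d1
    E1 <- E1 + dth * n1 / n
    if (n > 1) V <- V + dth * (n1 / n) * (1 - n1 / n) * (n - dth) / (n - 1)
  }
  (O1 - E1)^2 / V
}
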