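# Independent oracles and fixture builders used across the suite.

# Rows: exactly standardized probes (mean 0, sample var 1) that are exactly
# uncorrelated with each other, built from an orthonormal basis orthogonal
# to the intercept.
make_orthogonal_probes <- function(k, n, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * k), n, k))))[, -1, drop = FALSE]
  Z <- t(Q) * sqrt(n - 1)
  meth_matrix(Z, sprintf("probe%04d", seq_len(k)),
              sprintf("S%04d", seq_len(n)), scale = "standardized-M")
}

# Dense brute-force REML for y = X b + g + e, g ~ N(0, sg2 K): restricted
# log-likelihood evaluated with explicit matrix inverses and determinants,
# maximized over the variance ratio by base-R golden-section/Brent search.
# Returns the estimate and SE of the LAST column of X.
brute_force_reml <- function(y, X, K, bounds = c(-10, 10)) {
  n <- length(y); p <- ncol(X)
  neg2_llr <- function(loglam) {
    V0 <- exp(loglam) * K + diag(n)
    Vi <- solve(V0)
    XtViX <- t(X) %*% Vi %*% X
    bh <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% bh
    se2 <- drop(t(r) %*% Vi %*% r) / (n - p)
    (n - p) * log(se2) +
      determinant(V0, logarithm = TRUE)$modulus[1] +
      determinant(XtViX, logarithm = TRUE)$modulus[1]
  }
  opt <- optimize(neg2_llr, bounds, tol = 1e-10)
  V0 <- exp(opt$minimum) * K + diag(n)
  Vi <- solve(V0)
  XtViX <- t(X) %*% Vi %*% X
  bh <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% bh
  se2 <- drop(t(r) %*% Vi %*% r) / (n - p)
  covb <- se2 * solve(XtViX)
  list(beta = drop(bh)[p], se = sqrt(covb[p, p]),
       lambda = exp(opt$minimum), sigma_e2 = se2)
}

# Exhaustive hypergeometric upper tail: enumerate every size-|b| draw from
# the background and count how often the overlap with `a` reaches ov.
enumerate_hyper_tail <- function(N, na, nb, ov) {
  draws <- combn(N, nb)
  mean(colSums(draws <= na) >= ov)  # wlog successes are ids 1..na
}

# Grid-search maximum-likelihood logistic regression with one binary
# predictor: coarse grid then a fine grid around the best point, profiling
# the intercept by an inner 1-D optimization of the exact Bernoulli
# log-likelihood.
grid_logistic_slope <- function(y, x) {
  prof_ll <- function(b) {
    ll_a <- function(a) sum(y * (a + b * x) - log1p(exp(a + b * x)))
    optimize(ll_a, c(-10, 10), maximum = TRUE)$objective
  }
  scan <- function(grid) grid[which.max(vapply(grid, prof_ll, 0))]
  b0 <- scan(seq(-5, 5, by = 0.05))
  scan(seq(b0 - 0.05, b0 + 0.05, by = 1e-4))
}

# Minimal mwas_result constructor for tests.
fake_results <- function(probe_id, beta, se, p = NULL, n = 100,
                         analysis = "test") {
  if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
  res <- data.frame(probe_id = probe_id, beta = beta, se = se, p = p,
                    n = n, analysis = analysis,
                    significant = p < MWAS_P_THRESHOLD,
                    stringsAsFactors = FALSE)
  class(res) <- c("mwas_result", "data.frame")
  res
}

# Annotation with all probes on one chromosome at the given positions.
fake_annotation <- function(probe_id, position, chromosome = "chr1") {
  data.frame(probe_id = probe_id, chromosome = chromosome,
             position = position, gene = "GENE01", on_450k = TRUE,
             on_epic = TRUE, is_smoking_proxy = FALSE,
             stringsAsFactors = FALSE)
}
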