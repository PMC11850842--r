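test_that("candidate enumeration follows gap, sign and p rules", {
  ann <- fake_annotation(paste0("p", 1:3), c(100, 400, 700))
  res <- fake_results(paste0("p", 1:3), beta = c(0.2, 0.3, 0.25),
                      se = rep(0.05, 3), p = rep(0.01, 3))
  # all p >= threshold: nothing
  res_ns <- fake_results(paste0("p", 1:3), beta = c(0.2, 0.3, 0.25),
                         se = rep(0.05, 3), p = rep(0.5, 3))
  expect_length(find_candidate_regions(res_ns, ann), 0)
  # one maximal run of 3 probes (gaps of 300 <= 500)
  runs <- find_candidate_regions(res, ann)
  expect_length(runs, 1)
  expect_equal(runs[[1]]$probe_ids, paste0("p", 1:3))
  expect_equal(c(runs[[1]]$start_bp, runs[[1]]$end_bp), c(100, 700))
  # sub-enumeration: exactly the 3 contiguous windows of length >= 2
  subs <- find_candidate_regions(res, ann, enumerate_subregions = TRUE)
  expect_length(subs, 3)
  spans <- sort(vapply(subs, function(x)
    paste(x$start_bp, x$end_bp), ""))
  expect_equal(spans, sort(c("100 400", "400 700", "100 700")))
  # opposite-sign neighbor splits the run
  res_flip <- res; res_flip$beta[2] <- -0.3
  split_runs <- find_candidate_regions(res_flip, ann)
  expect_length(split_runs, 0)  # singleton fragments fall below min_probes
  # a gap > 500 splits too
  ann_far <- fake_annotation(paste0("p", 1:3), c(100, 400, 1000))
  far <- find_candidate_regions(res, ann_far)
  expect_length(far, 1)
  expect_equal(far[[1]]$probe_ids, c("p1", "p2"))
  # missing annotation errors with the probe named
  expect_error(find_candidate_regions(res, ann[-2, ]), "p2")
})

test_that("dmr_test reduces to fixed-effect IVW under identity correlation", {
  k <- 4; n <- 50
  Z <- make_orthogonal_probes(k, n, seed = 20)  # exactly uncorrelated rows
  betas <- c(0.12, 0.08, 0.15, 0.10); se <- rep(0.04, k)
  res <- fake_results(rownames(Z), betas, se)
  cand <- list(chromosome = "chr1", start_bp = 1, end_bp = 4000,
               probe_ids = rownames(Z), direction = 1)
  out <- dmr_test(cand, res, Z, shrink = 0)
  # closed-form equal-se limit: B = mean(beta), Var = se^2 / k
  expect_equal(out$beta_region, mean(betas), tolerance = 1e-12)
  expect_equal(out$se_region, se[1] / sqrt(k), tolerance = 1e-12)
  z_ivw <- mean(betas) / (se[1] / sqrt(k))
  expect_equal(out$z, z_ivw, tolerance = 1e-12)
  # unequal se: matches general IVW formulas
  se2 <- c(0.03, 0.05, 0.04, 0.06)
  res2 <- fake_results(rownames(Z), betas, se2)
  out2 <- dmr_test(cand, res2, Z, shrink = 0)
  w <- 1 / se2^2
  expect_equal(out2$beta_region, sum(w * betas) / sum(w), tolerance = 1e-12)
  expect_equal(out2$se_region, sqrt(1 / sum(w)), tolerance = 1e-12)
})

test_that("perfect correlation yields no pseudo-precision", {
  n <- 40
  z <- rnorm(n); z <- (z - mean(z)) / sd(z)
  Z <- meth_matrix(rbind(p1 = z, p2 = z), scale = "standardized-M",
                   sample_ids = sprintf("S%02d", 1:n))
  res <- fake_results(c("p1", "p2"), beta = c(0.1, 0.1), se = c(0.05, 0.05))
  cand <- list(chromosome = "chr1", start_bp = 1, end_bp = 100,
               probe_ids = c("p1", "p2"), direction = 1)
  out <- dmr_test(cand, res, Z, shrink = 0)
  # Var(B) = se^2: the z equals the single-probe z exactly
  expect_equal(out$se_region, 0.05, tolerance = 1e-10)
  expect_equal(out$z, 0.1 / 0.05, tolerance = 1e-10)
})

test_that("correlation penalization: Var never below identity-rho variance", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 60; k <- 3
    base <- rnorm(n)
    V <- sapply(1:k, function(i) 0.7 * base + 0.71 * rnorm(n))  # all rho > 0
    Z <- standardize_probes(meth_matrix(t(V),
                                        probe_ids = paste0("p", 1:k),
                                        sample_ids = sprintf("S%02d", 1:n),
                                        scale = "M"))
    rho <- cor(t(unclass(Z)))
    if (any(rho < 0)) next
    se <- runif(k, 0.02, 0.08)
    res <- fake_results(paste0("p", 1:k), rnorm(k, 0.1, 0.02), se)
    cand <- list(chromosome = "chr1", start_bp = 1, end_bp = 3,
                 probe_ids = paste0("p", 1:k), direction = 1)
    out <- dmr_test(cand, res, Z, shrink = 0)
    w <- 1 / se^2
    var_identity <- sum(w^2 * se^2) / sum(w)^2
    expect_gte(out$se_region^2, var_identity - 1e-12)
  }
})

test_that("run_dmr applies the Bonferroni definition and sorts output", {
  # two disjoint candidate pairs on one chromosome
  ann <- fake_annotation(paste0("p", 1:4), c(100, 300, 5000, 5200))
  Z <- make_orthogonal_probes(4, 50, seed = 22)
  rownames(Z) <- paste0("p", 1:4)
  res <- fake_results(paste0("p", 1:4), beta = c(0.2, 0.22, 0.05, 0.06),
                      se = c(0.04, 0.04, 0.02, 0.02))
  out <- run_dmr(res, Z, ann)
  expect_equal(attr(out, "n_candidates"), 2L)
  expect_equal(out$p_adj, pmin(1, out$p * 2))
  expect_true(!is.unsorted(out$p_adj))
  # empty input path
  res0 <- fake_results("p1", 0.1, 0.05, p = 0.9)
  expect_equal(nrow(run_dmr(res0, Z, ann)), 0)
})

test_that("single-probe candidates are rejected", {
  Z <- make_orthogonal_probes(2, 30, seed = 23)
  res <- fake_results(rownames(Z), c(0.1, 0.1), c(0.05, 0.05))
  cand <- list(chromosome = "chr1", start_bp = 1, end_bp = 1,
               probe_ids = rownames(Z)[1], direction = 1)
  expect_error(dmr_test(cand, res, Z), "at least 2")
})
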