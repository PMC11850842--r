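test_that("make_families_grm produces the stated block structure", {
  expect_equal(unclass(make_families_grm(0, 0, 5)), diag(5),
               ignore_attr = TRUE)
  expect_equal(unclass(make_families_grm(1, 2, 0)),
               matrix(c(1, 0.5, 0.5, 1), 2), ignore_attr = TRUE)
  K <- make_families_grm(2, 3, 4)
  expect_equal(dim(K), c(10, 10))
  ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= 0)  # PSD by direct eigendecomposition
  expect_equal(K[1, 4], 0)   # across families
  expect_equal(K[7, 8], 0)   # unrelated block
  expect_error(make_families_grm(0, 0, 0), "positive")
})

test_that("independence limit: no local, family or exposure structure", {
  cfg <- sim_config(n_samples = 500, n_probes = 12, n_families = 0,
                    family_size = 0, local_corr = 0, h2_family = 0,
                    seed = 70)
  set.seed(cfg$seed)
  sim <- simulate_methylation(cfg, exposure = rep(0, 500))
  C <- cor(t(unclass(sim$methylation)))
  offdiag <- C[upper.tri(C)]
  expect_lt(max(abs(offdiag)), 0.15)
  expect_true(all(sim$true_beta == 0))
})

test_that("a planted effect is recovered by OLS on the generated data", {
  cfg <- sim_config(n_samples = 2000, n_probes = 10, n_families = 0,
                    family_size = 0, local_corr = 0, h2_family = 0,
                    causal_probes = "probe0003", causal_effect = 0.5,
                    seed = 71)
  set.seed(cfg$seed)
  expo <- rbinom(2000, 1, 0.4)
  sim <- simulate_methylation(cfg, expo)
  fit <- summary(lm(unclass(sim$methylation)["probe0003", ] ~ expo))
  b <- fit$coefficients[2, 1]; se <- fit$coefficients[2, 2]
  expect_lt(abs(b - 0.5), 3 * se)
})

test_that("adjacent-probe correlation matches the AR(1) coefficient", {
  cfg <- sim_config(n_samples = 600, n_probes = 60, n_families = 0,
                    family_size = 0, local_corr = 0.6, h2_family = 0,
                    n_chromosomes = 1, seed = 72)
  set.seed(cfg$seed)
  sim <- simulate_methylation(cfg, exposure = rep(0, 600))
  V <- unclass(sim$methylation)
  adj <- vapply(1:(nrow(V) - 1),
                function(j) cor(V[j, ], V[j + 1, ]), 0)
  mc_err <- sd(adj) / sqrt(length(adj))
  expect_lt(abs(mean(adj) - 0.6), 3 * mc_err + 0.02)
})

test_that("family kernel drives cross-sample covariance", {
  cfg <- sim_config(n_samples = 200, n_probes = 400, n_families = 50,
                    family_size = 2, local_corr = 0, h2_family = 0.5,
                    seed = 73)
  grm <- make_families_grm(50, 2, 100)
  set.seed(cfg$seed)
  sim <- simulate_methylation(cfg, exposure = rep(0, 200), grm = grm)
  V <- unclass(sim$methylation)
  Vc <- V - rowMeans(V)
  sib_cov <- mean(vapply(seq_len(50), function(f)
    cov(Vc[, 2 * f - 1], Vc[, 2 * f]), 0))
  # expected covariance h2 * 0.5 = 0.25 of a unit-variance probe
  expect_lt(abs(sib_cov - 0.25), 0.08)
})

test_that("prescription streams round-trip through the classifier", {
  # all unexposed, no excluded fraction: empty stream
  truth0 <- setNames(rep(FALSE, 4), paste0("u", 1:4))
  draws0 <- setNames(rep(500, 4), names(truth0))
  expect_equal(nrow(simulate_prescriptions(truth0, draws0, seed = 74)), 0)

  set.seed(75)
  truth <- setNames(rep(c(TRUE, FALSE), each = 25), sprintf("p%02d", 1:50))
  draws <- setNames(round(runif(50, 400, 1500)), names(truth))
  rx <- simulate_prescriptions(truth, draws)
  e <- derive_exposure(rx, draws)
  got <- setNames(e$status == "EXPOSED", e$person_id)
  expect_equal(got, truth)  # exact round-trip at excluded fraction 0
  expect_true(all(e$status[!truth] == "UNEXPOSED"))

  # excluded fraction 1: every unexposed person with records is EXCLUDED
  rx2 <- simulate_prescriptions(truth, draws, excluded_fraction = 1,
                                seed = 76)
  e2 <- derive_exposure(rx2, draws)
  with_recs <- names(truth) %in% rx2$person_id
  expect_true(all(e2$status[with_recs & !truth] == "EXCLUDED"))
  expect_true(all(e2$status[truth] == "EXPOSED"))
})

test_that("identical configs reproduce bit-identical cohorts", {
  cfg <- sim_config(n_samples = 60, n_probes = 30, n_families = 10,
                    family_size = 2, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(unclass(a$methylation), unclass(b$methylation))
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$prescriptions, b$prescriptions)
  expect_identical(a$truth, b$truth)
})

test_that("config validation catches impossible worlds", {
  expect_error(sim_config(exposure_prevalence = 0), "strictly inside")
  expect_error(sim_config(local_corr = 1), "local_corr")
  expect_error(sim_config(h2_family = 1), "h2_family")
  expect_error(sim_config(n_samples = 10, n_families = 10,
                          family_size = 2), "exceed")
  cfg <- sim_config(n_samples = 10, n_probes = 5, n_families = 0,
                    family_size = 0, causal_probes = "nope", seed = 1)
  expect_error(simulate_methylation(cfg, rep(0, 10)), "nope")
})

test_that("cohort containers share sample ids and truth is consistent", {
  cfg <- sim_config(n_samples = 80, n_probes = 40, n_families = 20,
                    family_size = 2,
                    causal_probes = c("probe0001", "probe0002"),
                    causal_effect = 0.3, seed = 78)
  ch <- simulate_cohort(cfg)
  ids <- ch$phenotypes$sample_id
  expect_identical(colnames(ch$methylation), ids)
  expect_identical(rownames(ch$grm), ids)
  expect_identical(names(ch$truth$exposure), ids)
  # truth effects are zero outside the causal set
  nz <- names(ch$truth$beta)[ch$truth$beta != 0]
  expect_setequal(nz, c("probe0001", "probe0002"))
})
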