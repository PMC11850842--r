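test_that("L1 coefficients match the soft-threshold closed form", {
  # two exactly orthogonal standardized predictors: at penalty lambda the
  # coefficient of each is sign(r) * (|r| - lambda)_+ with r = x'y/n
  n <- 200
  Z <- make_orthogonal_probes(2, n, seed = 40)
  # glmnet standardizes by the 1/n variance internally even with
  # standardize = FALSE off; use the 1/n-scaled inner products
  x1 <- unclass(Z)[1, ]; x2 <- unclass(Z)[2, ]
  set.seed(41)
  y <- 0.4 * x1 - 0.2 * x2 + rnorm(n, sd = 0.3)
  y <- y - mean(y)
  for (lam in c(0.05, 0.15, 0.3)) {
    model <- train_mps(y, Z, lambda = lam)
    soft <- function(r, l) sign(r) * pmax(abs(r) - l, 0)
    # glmnet's objective uses the 1/n empirical second moment of x
    s1 <- mean(x1^2); s2 <- mean(x2^2)
    exp1 <- soft(mean(x1 * y), lam) / s1
    exp2 <- soft(mean(x2 * y), lam) / s2
    got <- setNames(rep(0, 2), rownames(Z))
    got[names(model$weights)] <- model$weights
    expect_equal(unname(got[1]), exp1, tolerance = 1e-6)
    expect_equal(unname(got[2]), exp2, tolerance = 1e-6)
  }
  # full-shrinkage limit: no weights survive a huge penalty
  expect_length(train_mps(y, Z, lambda = 10)$weights, 0)
})

test_that("CV training recovers most causal probes", {
  set.seed(42)
  n <- 800; m <- 400; k <- 20
  V <- matrix(rnorm(m * n), m, n,
              dimnames = list(sprintf("p%04d", 1:m), sprintf("S%04d", 1:n)))
  Z <- standardize_probes(meth_matrix(V, scale = "M"))
  causal <- rownames(Z)[1:k]
  y <- colSums(unclass(Z)[causal, ]) * 0.3 + rnorm(n)
  model <- train_mps(y, Z, seed = 7)
  expect_gte(length(intersect(names(model$weights), causal)), 15)
  # deterministic given the seed
  model2 <- train_mps(y, Z, seed = 7)
  expect_identical(model$weights, model2$weights)
})

test_that("scoring handles missing probes and is idempotent", {
  model <- structure(list(weights = c(pA = 1, pB = 0.5, pC = -2),
                          lambda = 0.1, n_folds = 10, seed = 1L,
                          mask_size = 3,
                          train_stats = data.frame(
                            probe_id = c("pA", "pB", "pC"),
                            mean = 0, sd = 1)),
                     class = "mps_model")
  # only pA present; its per-cohort z-scores weight in directly
  V <- matrix(c(1, 2, 3, 4), 1, 4,
              dimnames = list("pA", paste0("s", 1:4)))
  s <- score_mps(model, meth_matrix(V, scale = "M"))
  z <- (V[1, ] - mean(V[1, ])) / sd(V[1, ])
  expect_equal(as.numeric(s), unname(z * 1))
  expect_equal(attr(s, "coverage")$n_missing, 2)
  expect_setequal(attr(s, "coverage")$missing, c("pB", "pC"))
  s2 <- score_mps(model, meth_matrix(V, scale = "M"))
  expect_identical(as.numeric(s), as.numeric(s2))
  # no overlap errors
  V2 <- matrix(0.1, 1, 4, dimnames = list("pZ", paste0("s", 1:4)))
  expect_error(score_mps(model, meth_matrix(V2, scale = "M")), "no weighted")
})

test_that("training-set scores correlate with the training outcome", {
  set.seed(43)
  n <- 300
  Z <- standardize_probes(meth_matrix(
    matrix(rnorm(100 * n), 100, n,
           dimnames = list(sprintf("p%03d", 1:100),
                           sprintf("S%03d", 1:n))), scale = "M"))
  y <- colSums(unclass(Z)[1:10, ]) * 0.4 + rnorm(n)
  model <- train_mps(y, Z, seed = 2)
  s <- score_mps(model, Z, standardize = "training")
  expect_gt(cor(s, y), 0)
})

test_that("cohort_association recovers the 2x2 log odds ratio", {
  # binary score: the logistic slope equals the table's log OR
  y <- c(rep(1, 30), rep(0, 70), rep(1, 15), rep(0, 85))
  x <- c(rep(1, 100), rep(0, 100))
  or_table <- log((30 * 85) / (70 * 15))
  fitb <- glm(y ~ x, family = binomial())
  expect_equal(unname(coef(fitb)["x"]), or_table, tolerance = 1e-6)
  # our wrapper standardizes the score, so rescale the slope to per-SD
  ca <- cohort_association(x, y, cohort = "hand")
  expect_equal(ca$beta, or_table * sd(x), tolerance = 1e-6)
  # and the slope agrees with brute-force likelihood maximization
  slope_grid <- grid_logistic_slope(y, x)
  expect_equal(or_table, slope_grid, tolerance = 1e-3)
})

test_that("null association: no signal, near-zero pseudo-R2", {
  set.seed(44)
  n <- 2000
  score <- rnorm(n)
  expo <- rbinom(n, 1, 0.3)
  ca <- cohort_association(score, expo)
  expect_lt(abs(ca$beta / ca$se), 3)
  expect_lt(ca$nagelkerke_r2, 0.01)
  expect_equal(ca$model_type, "glm")
  # Nagelkerke of the null model against itself is 0 by definition
  expect_equal(methrx:::.nagelkerke(-100, -100, 500), 0)
})

test_that("clustered cohorts switch to robust (estimating-equation) SEs", {
  set.seed(45)
  n_fam <- 150
  fam <- rep(seq_len(n_fam), each = 2)
  u <- rnorm(n_fam)[fam]          # shared family effect
  score <- rnorm(2 * n_fam) + u
  expo <- rbinom(2 * n_fam, 1, plogis(-0.5 + 0.5 * score + u))
  ca <- cohort_association(score, expo, clusters = fam)
  expect_equal(ca$model_type, "gee-exchangeable")
  ca_iid <- cohort_association(score, expo)
  # same point estimate, different (cluster-aware) SE
  expect_equal(ca$beta, ca_iid$beta)
  expect_false(isTRUE(all.equal(ca$se, ca_iid$se)))
})

test_that("dl_meta matches the hand-computed two-study case", {
  # beta = {0, 2}, se = {1, 1}: Q = 2, tau2 = 1, pooled = 1, se = 1, I2 = 50
  m <- dl_meta(data.frame(beta = c(0, 2), se = c(1, 1)))
  expect_equal(m$Q, 2)
  expect_equal(m$tau2, 1)
  expect_equal(m$beta_pooled, 1)
  expect_equal(m$se_pooled, 1)
  expect_equal(m$i2_percent, 50)
  expect_equal(m$ci95, c(1 - 1.96, 1 + 1.96))
})

test_that("dl_meta degenerate and invariance properties", {
  # single study passes through
  m1 <- dl_meta(data.frame(beta = 0.4, se = 0.1))
  expect_equal(m1$beta_pooled, 0.4)
  expect_equal(m1$tau2, 0)
  expect_equal(m1$i2_percent, 0)
  # homogeneous studies: Q = 0, pooled = common value
  mh <- dl_meta(data.frame(beta = rep(0.3, 4), se = c(0.1, 0.2, 0.1, 0.3)))
  expect_equal(mh$Q, 0)
  expect_equal(mh$beta_pooled, 0.3)
  # when Q <= k-1, DL equals fixed-effect IVW exactly
  set.seed(46)
  b <- c(0.30, 0.31, 0.29); se <- c(0.1, 0.1, 0.1)
  m <- dl_meta(data.frame(beta = b, se = se))
  expect_lte(m$Q, 2)
  w <- 1 / se^2
  expect_equal(m$beta_pooled, sum(w * b) / sum(w))
  expect_equal(m$se_pooled, sqrt(1 / sum(w)))
  # order invariance and scale equivariance
  b2 <- c(0.1, 0.5, 0.3); se2 <- c(0.05, 0.2, 0.1)
  ma <- dl_meta(data.frame(beta = b2, se = se2))
  mb <- dl_meta(data.frame(beta = rev(b2), se = rev(se2)))
  expect_equal(ma$beta_pooled, mb$beta_pooled)
  mc <- dl_meta(data.frame(beta = 2 * b2, se = 2 * se2))
  expect_equal(mc$beta_pooled, 2 * ma$beta_pooled)
  expect_equal(mc$se_pooled, 2 * ma$se_pooled)
  expect_error(dl_meta(data.frame(beta = 1, se = 0)), "positive")
})

test_that("external-cohort simulation supports recovery and identity", {
  model <- structure(list(weights = c(p1 = 0.5, p2 = -0.3, p3 = 0.2),
                          lambda = 0.1, n_folds = 10, seed = 1L,
                          mask_size = 3,
                          train_stats = data.frame(
                            probe_id = paste0("p", 1:3), mean = 0, sd = 1)),
                     class = "mps_model")
  expect_length(simulate_external_cohorts(model, 0, 100, 0.5), 0)
  # k = 1: the meta result equals the single cohort's association
  set.seed(47)
  ext <- simulate_external_cohorts(model, 1, 400, 0.5)
  s <- score_mps(model, ext[[1]]$methylation)
  ca <- cohort_association(s, ext[[1]]$exposure, cohort = "only")
  m <- dl_meta(list(ca))
  expect_equal(m$beta_pooled, ca$beta)
  expect_equal(m$se_pooled, ca$se)
  # computed standardized score equals the standardized latent score
  expect_equal(unname(as.numeric(scale(s))),
               unname(as.numeric(scale(ext[[1]]$latent_score))),
               tolerance = 1e-10)
})

test_that("DL pooling recovers a planted score effect", {
  set.seed(48)
  model <- structure(list(weights = c(p1 = 0.5, p2 = -0.3, p3 = 0.2),
                          lambda = 0.1, n_folds = 10, seed = 1L,
                          mask_size = 3,
                          train_stats = data.frame(
                            probe_id = paste0("p", 1:3), mean = 0, sd = 1)),
                     class = "mps_model")
  ext <- simulate_external_cohorts(model, 5, 2000, 0.5)
  assoc <- lapply(seq_along(ext), function(i)
    cohort_association(score_mps(model, ext[[i]]$methylation),
                       ext[[i]]$exposure, cohort = paste0("c", i)))
  m <- dl_meta(assoc)
  expect_lt(abs(m$beta_pooled - 0.5), 3 * m$se_pooled)
  # null effect: pooled z unremarkable
  ext0 <- simulate_external_cohorts(model, 5, 1000, 0)
  assoc0 <- lapply(seq_along(ext0), function(i)
    cohort_association(score_mps(model, ext0[[i]]$methylation),
                       ext0[[i]]$exposure, cohort = paste0("n", i)))
  m0 <- dl_meta(assoc0)
  expect_lt(abs(m0$beta_pooled / m0$se_pooled), 3)
})
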