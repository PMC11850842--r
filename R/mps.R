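# Methylation profile score: cross-validated L1 (LASSO) training of sparse
# probe weights on a residualized exposure phenotype, scoring of external
# cohorts, per-cohort logistic association with Nagelkerke pseudo-R2, and
# DerSimonian-Laird random-effects pooling.

#' Train a sparse methylation profile score by cross-validated LASSO
#'
#' L1-penalized least squares of the (relatedness-residualized, hence
#' continuous) exposure phenotype on the standardized probes inside an
#' array-intersection mask. Ten-fold cross-validation chooses the penalty at
#' the minimum mean CV error (mixing parameter fixed at 1 = pure LASSO);
#' fold assignment is seeded so training is deterministic.
#'
#' @param y_res numeric residualized phenotype.
#' @param Z standardized `meth_matrix` (probes x samples).
#' @param mask character vector of probe ids eligible as predictors
#'   (e.g. probes present on both array generations); default all probes.
#' @param n_folds cross-validation folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param lambda optional fixed penalty; when supplied, cross-validation is
#'   skipped and the model is fitted at exactly this penalty (the glmnet
#'   parameterization: `1/(2n) RSS + lambda * |w|_1`).
#' @return object of class `mps_model`: `weights` (named vector, nonzero
#'   only), `lambda`, `n_folds`, `seed`, `mask_size`, `train_stats`
#'   (per-weighted-probe mean/sd on the training scale).
#' @export
train_mps <- function(y_res, Z, mask = NULL, n_folds = 10, seed = 1L,
                      lambda = NULL) {
  if (!inherits(Z, "meth_matrix") || meth_scale(Z) != "standardized-M")
    stop("Z must be standardized")
  n <- ncol(Z)
  if (length(y_res) != n) stop("y_res length must match sample count")
  if (n < n_folds) stop("fewer samples than folds")
  probes <- if (is.null(mask)) rownames(Z)
  else intersect(rownames(Z), mask)
  if (length(probes) == 0) stop("mask leaves no probes")
  X <- t(unclass(Z[probes, , drop = FALSE]))
  if (is.null(lambda)) {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(n_folds), n))
    cv <- glmnet::cv.glmnet(X, as.numeric(y_res), alpha = 1,
                            foldid = foldid, standardize = FALSE,
                            family = "gaussian")
    lambda <- cv$lambda.min
    co <- stats::coef(cv, s = "lambda.min")
  } else {
    fit <- glmnet::glmnet(X, as.numeric(y_res), alpha = 1,
                          lambda = lambda, standardize = FALSE,
                          family = "gaussian", thresh = 1e-12)
    co <- stats::coef(fit)
  }
  w <- as.numeric(co)[-1]
  names(w) <- rownames(co)[-1]
  w <- w[w != 0]
  structure(list(weights = w, lambda = lambda, n_folds = n_folds,
                 seed = as.integer(seed), mask_size = length(probes),
                 train_stats = data.frame(probe_id = names(w),
                                          mean = rep(0, length(w)),
                                          sd = rep(1, length(w)))),
            class = "mps_model")
}

#' @export
print.mps_model <- function(x, ...) {
  cat(sprintf(
    "<mps_model> %d nonzero weights (of %d masked probes), lambda = %.4g\n",
    length(x$weights), x$mask_size, x$lambda))
  invisible(x)
}

#' Score an external cohort with a methylation profile score
#'
#' Weighted sum `sum_j w_j z_j` over the model's probes, where `z_j` by
#' default standardizes the external probe using the external cohort's own
#' mean and SD (each cohort is preprocessed separately); with
#' `standardize = "training"` the stored training statistics are used
#' instead. Probes absent from the cohort are skipped and reported.
#'
#' @param model an `mps_model`.
#' @param M_ext external `meth_matrix` (M scale or already standardized).
#' @param standardize `"cohort"` (default) or `"training"`.
#' @return numeric score per sample, with attribute `coverage` = list
#'   (`n_used`, `n_missing`, `missing`).
#' @export
score_mps <- function(model, M_ext, standardize = c("cohort", "training")) {
  standardize <- match.arg(standardize)
  w <- model$weights
  present <- intersect(names(w), rownames(M_ext))
  if (length(present) == 0) stop("no weighted probes present in the cohort")
  V <- unclass(M_ext[present, , drop = FALSE])
  if (standardize == "cohort") {
    mu <- rowMeans(V)
    sdv <- apply(V, 1, stats::sd)
    sdv[sdv == 0] <- 1  # constant probe contributes 0 after centering
    Zs <- (V - mu) / sdv
  } else {
    st <- model$train_stats
    i <- match(present, st$probe_id)
    Zs <- (V - st$mean[i]) / st$sd[i]
  }
  score <- drop(crossprod(Zs, w[present]))
  names(score) <- colnames(M_ext)
  attr(score, "coverage") <- list(n_used = length(present),
                                  n_missing = length(w) - length(present),
                                  missing = setdiff(names(w), present))
  score
}

# Nagelkerke pseudo-R2 from null and fitted log-likelihoods.
.nagelkerke <- function(ll1, ll0, n) {
  (1 - exp(-2 * (ll1 - ll0) / n)) / (1 - exp(2 * ll0 / n))
}

# Cluster-robust (sandwich) covariance for a glm fit: the estimating-
# equations variance with independence working correlation, summing score
# contributions within clusters.
.cluster_sandwich <- function(fit, clusters) {
  X <- stats::model.matrix(fit)
  r <- stats::residuals(fit, type = "response")
  W <- fit$weights  # glm IRLS weights = mu(1-mu) for logistic
  bread <- solve(crossprod(X * W, X))
  U <- X * r  # score contributions per observation
  Uc <- rowsum(U, group = as.character(clusters))
  meat <- crossprod(Uc)
  bread %*% meat %*% bread
}

#' Per-cohort association of exposure with a profile score
#'
#' Logistic regression of exposure on the standardized score plus
#' covariates. With `clusters` supplied (twin/family cohorts) the model is
#' fitted as estimating equations with cluster-robust standard errors.
#' Reports Nagelkerke's pseudo-R2 of the score model against the
#' covariates-only null.
#'
#' @param score numeric per-sample score.
#' @param exposure 0/1 vector.
#' @param covariates optional numeric matrix.
#' @param clusters optional cluster (family) ids; switches to robust SE.
#' @param cohort label stored in the result.
#' @return list of class `cohort_association`: `cohort`, `beta` (log-odds
#'   per SD of score), `se`, `p`, `nagelkerke_r2`, `n_exposed`,
#'   `n_unexposed`, `model_type`, `separation` flag.
#' @export
cohort_association <- function(score, exposure, covariates = NULL,
                               clusters = NULL, cohort = "cohort") {
  exposure <- as.numeric(exposure)
  if (min(table(exposure)) < 10)
    stop("need at least 10 samples in each exposure class")
  s <- as.numeric(scale(score))
  df <- data.frame(exposure = exposure, score = s)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- stats::glm(exposure ~ ., data = df, family = stats::binomial())
  null_fit <- stats::glm(exposure ~ . - score, data = df,
                         family = stats::binomial())
  separation <- !fit$converged ||
    any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  b <- stats::coef(fit)["score"]
  if (is.null(clusters)) {
    se <- sqrt(stats::vcov(fit)["score", "score"])
    model_type <- "glm"
  } else {
    vc <- .cluster_sandwich(fit, clusters)
    k <- which(names(stats::coef(fit)) == "score")
    se <- sqrt(vc[k, k])
    model_type <- "gee-exchangeable"
  }
  r2 <- .nagelkerke(as.numeric(stats::logLik(fit)),
                    as.numeric(stats::logLik(null_fit)), length(exposure))
  structure(list(cohort = cohort, beta = unname(b), se = unname(se),
                 p = 2 * stats::pnorm(-abs(b / se)),
                 nagelkerke_r2 = max(0, min(1, r2)),
                 n_exposed = sum(exposure == 1),
                 n_unexposed = sum(exposure == 0),
                 model_type = model_type, separation = separation),
            class = "cohort_association")
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Moment-based pooling of per-cohort estimates: fixed-effect weights
#' `w_i = 1/se_i^2` give Cochran's `Q = sum w_i (b_i - b_F)^2`; the
#' between-study variance is `tau2 = max(0, (Q - (k-1)) / C)` with
#' `C = sum w - sum w^2 / sum w`; random-effects weights `1/(se_i^2 + tau2)`
#' give the pooled estimate, its SE and a 95% CI, and
#' `I2 = max(0, (Q - (k-1))/Q) * 100` summarizes heterogeneity.
#'
#' @param associations list of `cohort_association` objects, or a data.frame
#'   with columns `beta` and `se`.
#' @return list of class `meta_result`: `beta_pooled`, `se_pooled`, `ci95`,
#'   `p`, `Q`, `df`, `tau2`, `i2_percent`, `k`, `per_study`.
#' @export
dl_meta <- function(associations) {
  if (is.data.frame(associations)) {
    b <- associations$beta; se <- associations$se
    labels <- if ("cohort" %in% names(associations)) associations$cohort
    else paste0("study", seq_along(b))
  } else {
    b <- vapply(associations, `[[`, 0, "beta")
    se <- vapply(associations, `[[`, 0, "se")
    labels <- vapply(associations, `[[`, "", "cohort")
  }
  k <- length(b)
  if (k == 0) stop("no studies to pool")
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  b_f <- sum(w * b) / sum(w)
  Q <- sum(w * (b - b_f)^2)
  if (k == 1) {
    tau2 <- 0; i2 <- 0
  } else {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (k - 1)) / C)
    i2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  }
  ws <- 1 / (se^2 + tau2)
  b_r <- sum(ws * b) / sum(ws)
  se_r <- sqrt(1 / sum(ws))
  structure(list(beta_pooled = b_r, se_pooled = se_r,
                 ci95 = c(b_r - 1.96 * se_r, b_r + 1.96 * se_r),
                 p = 2 * stats::pnorm(-abs(b_r / se_r)),
                 Q = Q, df = k - 1L, tau2 = tau2, i2_percent = i2, k = k,
                 per_study = data.frame(cohort = labels, beta = b, se = se,
                                        weight = ws / sum(ws))),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "<meta_result> k = %d: pooled beta %.3f [%.3f, %.3f], p = %.3g\n",
    x$k, x$beta_pooled, x$ci95[1], x$ci95[2], x$p))
  cat(sprintf("  Q = %.3f (df %d), tau2 = %.4f, I2 = %.1f%%\n",
              x$Q, x$df, x$tau2, x$i2_percent))
  invisible(x)
}
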