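#' Genome-wide significance threshold for array-based case-control MWAS
#' @export
MWAS_P_THRESHOLD <- 9.42e-8

#' Per-probe mixed-model association scan
#'
#' For each probe j fits `y_res = X c + z_j b_j + u + eps` with
#' `u ~ N(0, sigma_o^2 Omega)`, where `Omega` is an omics-relatedness matrix
#' and `z_j` the standardized probe, and reports the Wald test of `b_j`.
#' Because probes are standardized, `b_j` is the effect per 1 SD of M-value.
#'
#' Two estimation modes:
#' \describe{
#'   \item{`fast`}{estimates the variance ratio once under the probe-free
#'     null model and reuses it for every probe (generalized least squares
#'     per probe; the usual mixed-model association approximation).}
#'   \item{`exact`}{re-optimizes the REML variance ratio per probe with the
#'     probe in the fixed effects.}
#' }
#' With `omega = NULL` (or an identity kernel in `fast` mode) the model
#' collapses to per-probe ordinary least squares.
#'
#' @param y_res numeric phenotype vector, typically the output of
#'   [reml_blup_residualize()].
#' @param Z standardized `meth_matrix` (probes x samples).
#' @param covariates optional numeric matrix of fixed covariates (no
#'   intercept column; one is added).
#' @param omega optional `relatedness_matrix` random-effect kernel.
#' @param mode `"fast"` or `"exact"`.
#' @param analysis label attached to every row of the result.
#' @param sig_threshold genome-wide significance level for the `significant`
#'   flag; default [MWAS_P_THRESHOLD].
#' @return data.frame of class `mwas_result`: `probe_id`, `beta`, `se`, `p`,
#'   `n`, `analysis`, `significant`.
#' @export
run_mwas <- function(y_res, Z, covariates = NULL, omega = NULL,
                     mode = c("fast", "exact"), analysis = "mwas",
                     sig_threshold = MWAS_P_THRESHOLD) {
  mode <- match.arg(mode)
  if (!inherits(Z, "meth_matrix") || meth_scale(Z) != "standardized-M")
    stop("Z must be standardized (see standardize_probes)")
  n <- ncol(Z)
  y <- as.numeric(y_res)
  if (length(y) != n) stop("y_res length must match the sample count of Z")
  if (!is.null(omega) && nrow(omega) != n)
    stop("omega dimension must match the sample count")
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Zm <- unclass(Z)

  if (mode == "exact" && !is.null(omega)) {
    eig <- eigen(unclass(as.matrix(omega)), symmetric = TRUE)
    out <- vapply(seq_len(nrow(Zm)), function(j) {
      fit <- .reml_fit(y, cbind(X, probe = Zm[j, ]), eig)
      k <- ncol(X) + 1L
      se <- sqrt(fit$sigma_e2 * solve(fit$XtWX)[k, k])
      c(fit$beta[k], se)
    }, numeric(2))
    b <- out[1, ]; se <- out[2, ]
  } else {
    # fast path: one (optional) null REML fit, then vectorized GLS
    if (is.null(omega)) {
      w_sqrt <- rep(1, n)
      ys <- y; Xs <- X; Zs <- Zm
    } else {
      eig <- eigen(unclass(as.matrix(omega)), symmetric = TRUE)
      null_fit <- .reml_fit(y, X, eig)
      w_sqrt <- sqrt(null_fit$w)
      ys <- drop(crossprod(eig$vectors, y)) * w_sqrt
      Xs <- crossprod(eig$vectors, X) * w_sqrt
      Zs <- (Zm %*% eig$vectors) * rep(w_sqrt, each = nrow(Zm))
    }
    XtXi <- solve(crossprod(Xs))
    # residualize y and every probe on the (whitened) covariates
    yp <- ys - drop(Xs %*% (XtXi %*% crossprod(Xs, ys)))
    Zp <- Zs - (Zs %*% Xs) %*% tcrossprod(XtXi, Xs)
    szz <- rowSums(Zp^2)
    szy <- drop(Zp %*% yp)
    b <- szy / szz
    rss <- sum(yp^2) - szy^2 / szz
    df <- n - ncol(X) - 1L
    se <- sqrt(pmax(rss, 0) / df / szz)
  }
  p <- 2 * stats::pnorm(-abs(b / se))
  res <- data.frame(probe_id = rownames(Zm), beta = b, se = se, p = p,
                    n = n, analysis = analysis,
                    significant = p < sig_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("mwas_result", "data.frame")
  res
}

#' Compare two MWAS effect-estimate sets
#'
#' Computes (i) the Pearson correlation of effect estimates across the shared
#' probes with its two-sided p-value, (ii) a per-probe difference test
#' `z = (bA - bB) / sqrt(seA^2 + seB^2)` with two-sided normal p (a standard
#' stand-in when the source analyses do not share samples' covariance), and
#' (iii) the ratio of mean effects over an optional probe subset, the
#' "fold-change" style summary used when contrasting a subgroup scan with the
#' full scan at its significant probes.
#'
#' @param resA,resB `mwas_result` data.frames.
#' @param probes optional character vector of probe ids for the effect-ratio
#'   summary (defaults to all shared probes).
#' @return list with `n_shared`, `r`, `r_p`, `diff` (data.frame probe_id, z,
#'   p), and `effect_ratio` (= mean(betaA) / mean(betaB) over `probes`).
#' @export
compare_effect_sets <- function(resA, resB, probes = NULL) {
  m <- merge(resA[, c("probe_id", "beta", "se")],
             resB[, c("probe_id", "beta", "se")],
             by = "probe_id", suffixes = c("_a", "_b"))
  if (nrow(m) < 3) stop("need at least 3 shared probes")
  ct <- stats::cor.test(m$beta_a, m$beta_b)
  z <- (m$beta_a - m$beta_b) / sqrt(m$se_a^2 + m$se_b^2)
  diff <- data.frame(probe_id = m$probe_id, z = z,
                     p = 2 * stats::pnorm(-abs(z)),
                     stringsAsFactors = FALSE)
  sub <- if (is.null(probes)) m else m[m$probe_id %in% probes, ]
  if (nrow(sub) == 0) stop("none of the requested probes are shared")
  list(n_shared = nrow(m),
       r = unname(ct$estimate), r_p = ct$p.value,
       diff = diff,
       effect_ratio = mean(sub$beta_a) / mean(sub$beta_b))
}
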