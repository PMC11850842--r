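#' Construct a probe-by-sample methylation matrix
#'
#' Thin S3 wrapper around a numeric matrix with probes in rows and samples in
#' columns, carrying a scale flag so downstream code can refuse inputs on the
#' wrong scale. Beta-values are methylation fractions in (0, 1); M-values are
#' their log2 odds; `"standardized-M"` means every probe has mean 0 and unit
#' sample variance.
#'
#' @param values numeric matrix, probes x samples.
#' @param probe_ids,sample_ids character vectors; default to the dimnames of
#'   `values`.
#' @param scale one of `"beta"`, `"M"`, `"standardized-M"`.
#' @return a `meth_matrix` object.
#' @export
meth_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values),
                        scale = c("M", "beta", "standardized-M")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("meth_matrix needs probe and sample ids")
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(probe_ids)) stop("duplicated probe ids")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (scale == "beta" && any(values <= 0 | values >= 1, na.rm = TRUE))
    stop("beta scale requires all values strictly inside (0, 1)")
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(values, scale = scale, class = c("meth_matrix", "matrix", "array"))
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("<meth_matrix> %d probes x %d samples [%s scale]\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

meth_scale <- function(x) attr(x, "scale")

# Subsetting keeps the class and scale (a subset of a valid matrix is valid).
#' @export
`[.meth_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, scale = attr(x, "scale"),
                     class = c("meth_matrix", "matrix", "array"))
  out
}

#' Beta-value to M-value transform
#'
#' `M = log2(beta / (1 - beta))`: the log odds of the methylation fraction,
#' a strictly increasing map that makes the per-probe distributions closer to
#' Gaussian and variance more homoscedastic.
#'
#' @param beta numeric vector, matrix or `meth_matrix` of values in (0, 1).
#' @return object of the same shape on the M scale.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))  # -2 0 2
#' @export
beta_to_m <- function(beta) {
  if (inherits(beta, "meth_matrix")) {
    if (meth_scale(beta) != "beta") stop("matrix is not on the beta scale")
    return(meth_matrix(log2(unclass(beta) / (1 - unclass(beta))),
                       rownames(beta), colnames(beta), scale = "M"))
  }
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE))
    stop("beta values must lie strictly inside (0, 1)")
  log2(beta / (1 - beta))
}

#' Standardize each probe to mean 0, variance 1
#'
#' Per-probe z-scoring across samples using the sample (n-1) variance.
#' Zero-variance probes cannot be standardized; they are dropped and listed in
#' the `dropped` attribute, with a warning.
#'
#' @param M a `meth_matrix` on the M (or beta) scale with at least 2 samples.
#' @return a `meth_matrix` with scale `"standardized-M"`; attribute `dropped`
#'   holds the ids of any zero-variance probes removed.
#' @export
standardize_probes <- function(M) {
  if (!inherits(M, "meth_matrix")) stop("M must be a meth_matrix")
  if (ncol(M) < 2) stop("standardization needs at least 2 samples")
  v <- unclass(M)
  mu <- rowMeans(v)
  sdv <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1L))
  zero <- sdv == 0 | !is.finite(sdv)
  if (all(zero)) stop("all probes have zero variance; nothing to standardize")
  dropped <- rownames(v)[zero]
  if (length(dropped))
    warning(sprintf("dropped %d zero-variance probe(s): %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")))
  v <- (v[!zero, , drop = FALSE] - mu[!zero]) / sdv[!zero]
  out <- meth_matrix(v, rownames(v), colnames(v), scale = "standardized-M")
  attr(out, "dropped") <- dropped
  out
}

#' Construct a relatedness matrix (GRM or ORM)
#'
#' @param K symmetric n x n numeric matrix.
#' @param sample_ids character vector; defaults to rownames.
#' @param kind `"GRM"` (pedigree/genotype kinship) or `"ORM"`
#'   (methylation-derived).
#' @param tol eigenvalue tolerance for the positive-semi-definite check.
#' @return a `relatedness_matrix` object.
#' @export
relatedness_matrix <- function(K, sample_ids = rownames(K),
                               kind = c("GRM", "ORM"), tol = 1e-8) {
  kind <- match.arg(kind)
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("relatedness matrix must be square")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(K)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(K)) stop("sample id length mismatch")
  if (max(abs(K - t(K))) > 1e-10) stop("relatedness matrix must be symmetric")
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -tol)
    stop(sprintf("matrix is not PSD (min eigenvalue %.3g)", ev_min))
  dimnames(K) <- list(sample_ids, sample_ids)
  structure(K, kind = kind, class = c("relatedness_matrix", "matrix", "array"))
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  cat(sprintf("<relatedness_matrix> %s, %d samples, mean diag %.3f\n",
              attr(x, "kind"), nrow(x), mean(diag(x))))
  invisible(x)
}

#' Omics-relatedness matrix from standardized methylation
#'
#' The methylation analogue of a genetic relatedness matrix:
#' `Omega = Z' Z / m` over the m standardized probes, so the mean diagonal is
#' close to 1 and entry (i, j) is the average probe-wise product between
#' samples i and j. Used as the random-effect kernel in the association scan.
#'
#' @param Z a `meth_matrix` with scale `"standardized-M"`.
#' @return a `relatedness_matrix` of kind `"ORM"`.
#' @export
compute_orm <- function(Z) {
  if (!inherits(Z, "meth_matrix") || meth_scale(Z) != "standardized-M")
    stop("Z must be a standardized meth_matrix (see standardize_probes)")
  m <- nrow(Z)
  if (m == 0L) stop("no probes to build an ORM from")
  omega <- crossprod(unclass(Z)) / m
  relatedness_matrix(omega, colnames(Z), kind = "ORM")
}
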