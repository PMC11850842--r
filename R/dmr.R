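# Differentially methylated regions: candidate enumeration from per-probe
# association results, then a correlation-adjusted inverse-variance
# meta-analysis per candidate, Bonferroni-corrected over all candidates.

#' Enumerate candidate regions from MWAS results
#'
#' Probes are filtered to nominal significance (`p < p_thresh`), ordered by
#' genomic position, and grouped into maximal runs in which consecutive
#' probes are at most `max_gap` bp apart and all effects share one sign.
#' With `enumerate_subregions = TRUE` every contiguous sub-window of length
#' >= `min_probes` within each run is also emitted — this is what makes the
#' candidate count (and hence the Bonferroni denominator) large.
#'
#' @param results an `mwas_result` data.frame.
#' @param annotation probe annotation with `probe_id`, `chromosome`,
#'   `position`.
#' @param max_gap maximum inter-probe gap in bp (default 500).
#' @param p_thresh nominal significance filter (default 0.05).
#' @param min_probes minimum probes per candidate (default 2).
#' @param enumerate_subregions emit all contiguous sub-windows (default
#'   FALSE).
#' @return list of candidates; each is a list with `chromosome`, `start_bp`,
#'   `end_bp`, `probe_ids`, `direction` (+1/-1).
#' @export
find_candidate_regions <- function(results, annotation, max_gap = 500,
                                   p_thresh = 0.05, min_probes = 2,
                                   enumerate_subregions = FALSE) {
  missing_ann <- setdiff(results$probe_id, annotation$probe_id)
  if (length(missing_ann))
    stop("no annotation for probe(s): ",
         paste(utils::head(missing_ann, 5), collapse = ", "))
  d <- merge(results, annotation[, c("probe_id", "chromosome", "position")],
             by = "probe_id")
  d <- d[d$p < p_thresh, ]
  if (nrow(d) == 0) return(list())
  d <- d[order(d$chromosome, d$position), ]
  new_run <- c(TRUE, d$chromosome[-1] != d$chromosome[-nrow(d)] |
                 diff(d$position) > max_gap |
                 sign(d$beta[-1]) != sign(d$beta[-nrow(d)]))
  run_id <- cumsum(new_run)
  out <- list()
  for (r in split(seq_len(nrow(d)), run_id)) {
    if (length(r) < min_probes) next
    windows <- if (enumerate_subregions) {
      idx <- list()
      for (len in min_probes:length(r))
        for (s in 1:(length(r) - len + 1))
          idx[[length(idx) + 1L]] <- r[s:(s + len - 1)]
      idx
    } else list(r)
    for (w in windows)
      out[[length(out) + 1L]] <- list(
        chromosome = d$chromosome[w[1]],
        start_bp = d$position[w[1]],
        end_bp = d$position[w[length(w)]],
        probe_ids = d$probe_id[w],
        direction = sign(d$beta[w[1]]))
  }
  out
}

#' Correlation-adjusted inverse-variance test of one candidate region
#'
#' Fixed-effect inverse-variance pooling of the member probes' effects,
#' with the variance of the pooled effect inflated for the correlation of
#' the probes' methylation values:
#' `B = sum(w_i b_i) / sum(w_i)` with `w_i = 1/se_i^2`, and
#' `Var(B) = sum_ij w_i w_j rho_ij se_i se_j / (sum w_i)^2`
#' where `rho` is the sample correlation of the member probes across
#' samples. With `rho = I` this reduces exactly to the classical IVW
#' meta-analysis; with perfectly correlated probes no pseudo-precision is
#' gained.
#'
#' @param candidate one element from [find_candidate_regions()].
#' @param results `mwas_result` data.frame covering the member probes.
#' @param Z standardized `meth_matrix` covering the member probes.
#' @param shrink ridge added to the correlation diagonal for stability
#'   (default 1e-6).
#' @return list: the candidate fields plus `beta_region`, `se_region`, `z`,
#'   `p`, `n_probes`.
#' @export
dmr_test <- function(candidate, results, Z, shrink = 1e-6) {
  pids <- candidate$probe_ids
  if (length(pids) < 2) stop("a candidate region needs at least 2 probes")
  if (!all(pids %in% results$probe_id)) stop("probes missing from results")
  if (!all(pids %in% rownames(Z))) stop("probes missing from Z")
  r <- results[match(pids, results$probe_id), ]
  rho <- stats::cor(t(unclass(Z[pids, , drop = FALSE])))
  if (any(!is.finite(rho))) stop("NaN in probe correlation matrix")
  diag(rho) <- diag(rho) + shrink
  w <- 1 / r$se^2
  B <- sum(w * r$beta) / sum(w)
  varB <- drop(t(w * r$se) %*% rho %*% (w * r$se)) / sum(w)^2
  z <- B / sqrt(varB)
  c(candidate,
    list(beta_region = B, se_region = sqrt(varB), z = z,
         p = 2 * stats::pnorm(-abs(z)), n_probes = length(pids)))
}

#' Region analysis over a whole result set
#'
#' Enumerates candidates, tests each, and attaches a Bonferroni-adjusted
#' p-value with denominator equal to the number of candidates tested in this
#' run. Regions with `p_adj < 0.05` are flagged significant.
#'
#' @param results,Z,annotation as in [find_candidate_regions()] /
#'   [dmr_test()].
#' @param max_gap,p_thresh,min_probes,enumerate_subregions candidate options.
#' @return data.frame sorted by `p_adj`: `chromosome`, `start_bp`, `end_bp`,
#'   `n_probes`, `probe_ids` (comma-joined), `beta`, `se`, `z`, `p`,
#'   `p_adj`, `significant`; attribute `n_candidates`.
#' @export
run_dmr <- function(results, Z, annotation, max_gap = 500, p_thresh = 0.05,
                    min_probes = 2, enumerate_subregions = FALSE) {
  cands <- find_candidate_regions(results, annotation, max_gap, p_thresh,
                                  min_probes, enumerate_subregions)
  if (length(cands) == 0)
    return(structure(data.frame(chromosome = character(0),
                                start_bp = integer(0), end_bp = integer(0),
                                n_probes = integer(0),
                                probe_ids = character(0), beta = numeric(0),
                                se = numeric(0), z = numeric(0),
                                p = numeric(0), p_adj = numeric(0),
                                significant = logical(0)),
                     n_candidates = 0L))
  tested <- lapply(cands, dmr_test, results = results, Z = Z)
  ncand <- length(tested)
  out <- do.call(rbind, lapply(tested, function(t)
    data.frame(chromosome = t$chromosome, start_bp = t$start_bp,
               end_bp = t$end_bp, n_probes = t$n_probes,
               probe_ids = paste(t$probe_ids, collapse = ","),
               beta = t$beta_region, se = t$se_region, z = t$z, p = t$p,
               stringsAsFactors = FALSE)))
  out$p_adj <- pmin(1, out$p * ncand)
  out$significant <- out$p_adj < 0.05
  out <- out[order(out$p_adj, out$p), ]
  rownames(out) <- NULL
  attr(out, "n_candidates") <- ncand
  out
}
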