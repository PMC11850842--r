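# Cross-study concordance: exact hypergeometric overlap of top sets, and a
# circular-permutation enrichment test between two genome-ordered MWAS
# result sets with concordant-direction filtering and a max-over-thresholds
# empirical correction.

#' Exact hypergeometric overlap test
#'
#' Upper-tail probability `P(X >= overlap)` for `X` hypergeometric with
#' population `|background|`, `|a|` successes and `|b|` draws: the standard
#' test that two top-hit sets share more elements than chance, given the
#' background they were drawn from.
#'
#' @param a,b character vectors (id sets), both subsets of `background`.
#' @param background character vector of all eligible ids.
#' @return list: `set_a_size`, `set_b_size`, `overlap`, `background_size`,
#'   `p_upper_tail`.
#' @export
hypergeometric_overlap <- function(a, b, background) {
  a <- unique(a); b <- unique(b); background <- unique(background)
  if (!all(a %in% background) || !all(b %in% background))
    stop("both sets must be contained in the background")
  ov <- length(intersect(a, b))
  N <- length(background)
  # P(X >= ov); phyper's lower.tail=FALSE gives P(X > q)
  p <- stats::phyper(ov - 1, length(a), N - length(a), length(b),
                     lower.tail = FALSE)
  list(set_a_size = length(a), set_b_size = length(b), overlap = ov,
       background_size = N, p_upper_tail = p)
}

# Shared probes of two result sets, restricted to concordant effect
# direction and ordered along the genome. Returns the merged data.frame.
.concordant_ordered <- function(resA, resB, annotation) {
  m <- merge(resA[, c("probe_id", "beta", "p")],
             resB[, c("probe_id", "beta", "p")],
             by = "probe_id", suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stop("no shared probes between the result sets")
  m <- merge(m, annotation[, c("probe_id", "chromosome", "position")],
             by = "probe_id")
  m <- m[sign(m$beta_a) == sign(m$beta_b) & m$beta_a != 0, ]
  if (nrow(m) == 0) stop("no probes with concordant effect direction")
  m[order(m$chromosome, m$position), ]
}

# Mark the top ceiling(fraction * m) probes by ascending p; ties broken by
# larger |beta| then probe id.
.mark_top <- function(p, beta, probe_id, fraction) {
  k <- ceiling(fraction * length(p))
  o <- order(p, -abs(beta), probe_id)
  marks <- logical(length(p))
  marks[o[seq_len(k)]] <- TRUE
  marks
}

#' Genome-ordered top-hit indicator vector
#'
#' Restricts to probes whose effect sign agrees between `results` and
#' `reference`, orders them along the genome, and marks the top
#' `ceiling(fraction * m)` by ascending p-value (ties: larger |beta|, then
#' probe id).
#'
#' @param results,reference `mwas_result` data.frames sharing probes.
#' @param fraction top fraction in (0, 1).
#' @param annotation probe annotation (`probe_id`, `chromosome`,
#'   `position`).
#' @return named logical vector over the concordant probes in genome order.
#' @export
top_hits <- function(results, fraction, reference, annotation) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  m <- .concordant_ordered(results, reference, annotation)
  stats::setNames(.mark_top(m$p_a, m$beta_a, m$probe_id, fraction),
                  m$probe_id)
}

# log odds ratio of the 2x2 top/not-top table given the a-cell and fixed
# margins, with Haldane 0.5 correction applied when any cell is zero.
.log_or_from_a <- function(a, nA, nB, m) {
  b <- nA - a; c <- nB - a; d <- m - nA - nB + a
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5
                                 c <- c + 0.5; d <- d + 0.5 }
  log(a * d / (b * c))
}

# a-cell counts for every circular rotation of y against fixed x, via FFT
# cross-correlation: count[r+1] = sum_i x[i] * y[(i - r - 1) mod m + 1].
.rotation_acounts <- function(x, y) {
  m <- length(x)
  cc <- Re(stats::fft(stats::fft(as.numeric(x)) *
                      Conj(stats::fft(as.numeric(y))), inverse = TRUE)) / m
  round(cc)
}

#' Circular-permutation enrichment between two MWAS result sets
#'
#' For every pair of top-fraction thresholds `(fA, fB)` the observed 2x2
#' table of A-top by B-top membership over the concordant shared probes is
#' summarized by its log odds ratio (Haldane 0.5 correction on zero cells).
#' The null preserves the local correlation of methylation along the genome
#' by rotating B's genome-ordered indicator vector by a uniform random
#' offset per permutation (A fixed) and recomputing every pair's statistic.
#' Per-pair empirical p uses the plus-one estimator
#' `(1 + #{perm >= obs}) / (1 + n_perm)`; the corrected p compares the
#' observed best (maximum) statistic over all pairs against each
#' permutation's best, the standard max-statistic correction for having
#' scanned several thresholds.
#'
#' @param resA,resB `mwas_result` data.frames.
#' @param annotation probe annotation for genome ordering.
#' @param fractions numeric vector of top fractions (default
#'   `c(0.001, 0.005, 0.01)`).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the rotation offsets.
#' @return list of class `enrichment_result`: `pairs` (data.frame with
#'   `frac_a`, `frac_b`, a/b/c/d cells, `odds_ratio`, `log_or`,
#'   `p_empirical`), `p_corrected`, `best_pair`, `n_probes`, `n_perm`,
#'   `seed`, `statistic = "log-odds-ratio"`.
#' @export
circular_enrichment <- function(resA, resB, annotation,
                                fractions = c(0.001, 0.005, 0.01),
                                n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  mm <- .concordant_ordered(resA, resB, annotation)
  m <- nrow(mm)
  if (ceiling(max(fractions) * m) >= m)
    stop("too few shared probes for the largest top fraction")
  tops_a <- lapply(fractions, function(f)
    .mark_top(mm$p_a, mm$beta_a, mm$probe_id, f))
  tops_b <- lapply(fractions, function(f)
    .mark_top(mm$p_b, mm$beta_b, mm$probe_id, f))
  nA <- vapply(tops_a, sum, 0L); nB <- vapply(tops_b, sum, 0L)
  pairs <- expand.grid(ia = seq_along(fractions), ib = seq_along(fractions))
  # a-cell for every possible rotation offset of B, per pair (m x npairs)
  acounts <- mapply(function(ia, ib)
    .rotation_acounts(tops_a[[ia]], tops_b[[ib]]),
    pairs$ia, pairs$ib)
  obs_a <- acounts[1, ]  # offset 0 = observed table
  obs_stat <- mapply(function(j, a)
    .log_or_from_a(a, nA[pairs$ia[j]], nB[pairs$ib[j]], m),
    seq_len(nrow(pairs)), obs_a)
  set.seed(seed)
  offsets <- sample.int(m - 1L, n_perm, replace = TRUE)  # 1..m-1, never 0
  perm_stat <- sapply(seq_len(nrow(pairs)), function(j) {
    a_vals <- acounts[offsets + 1L, j]
    vapply(a_vals, .log_or_from_a, 0,
           nA = nA[pairs$ia[j]], nB = nB[pairs$ib[j]], m = m)
  })
  if (is.null(dim(perm_stat))) perm_stat <- matrix(perm_stat, nrow = n_perm)
  p_emp <- vapply(seq_len(nrow(pairs)), function(j)
    (1 + sum(perm_stat[, j] >= obs_stat[j])) / (1 + n_perm), 0)
  best_obs <- max(obs_stat)
  perm_best <- apply(perm_stat, 1, max)
  p_corr <- (1 + sum(perm_best >= best_obs)) / (1 + n_perm)
  pr <- data.frame(frac_a = fractions[pairs$ia], frac_b = fractions[pairs$ib],
                   a = obs_a, b = nA[pairs$ia] - obs_a,
                   c = nB[pairs$ib] - obs_a,
                   d = m - nA[pairs$ia] - nB[pairs$ib] + obs_a,
                   log_or = obs_stat, odds_ratio = exp(obs_stat),
                   p_empirical = p_emp)
  structure(list(pairs = pr, p_corrected = p_corr,
                 best_pair = pr[which.max(obs_stat),
                                c("frac_a", "frac_b"), drop = TRUE],
                 n_probes = m, n_perm = n_perm, seed = seed,
                 statistic = "log-odds-ratio"),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d concordant probes, %d permutations\n",
              x$n_probes, x$n_perm))
  print(x$pairs, row.names = FALSE)
  cat(sprintf("max-over-thresholds corrected p = %.4g\n", x$p_corrected))
  invisible(x)
}
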