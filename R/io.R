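# Readers and writers for the plain-text formats the pipeline touches.
# Conventions: methylation TSV has probe rows and a header of sample ids;
# annotation positions are 1-based inclusive; the BED writer converts to
# 0-based half-open at the boundary; GRMs are accepted dense or as
# lower-triangle (id1, id2, value) triplets.

#' Write / read a probe-by-sample methylation TSV
#'
#' First column `probe_id`, remaining columns one per sample.
#'
#' @param M a `meth_matrix`.
#' @param path file path.
#' @return `read_methylation` returns a `meth_matrix`.
#' @export
write_methylation <- function(M, path) {
  df <- data.frame(probe_id = rownames(M), unclass(M), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_methylation
#' @param scale scale flag of the stored values; `"beta"` inputs can be
#'   transformed on read with `as_m`.
#' @param as_m transform beta input to M-values on read (default FALSE).
#' @param max_missing probes with a larger missing fraction are dropped;
#'   remaining NAs are mean-imputed (both logged via message).
#' @export
read_methylation <- function(path, scale = c("M", "beta"), as_m = FALSE,
                             max_missing = 0.05) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe id(s): ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  ids <- colnames(df)[-1]
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  V <- as.matrix(df[, -1, drop = FALSE])
  rownames(V) <- df$probe_id
  miss <- rowMeans(is.na(V))
  if (any(miss > max_missing)) {
    message(sprintf("dropping %d probe(s) with > %.0f%% missing values",
                    sum(miss > max_missing), 100 * max_missing))
    V <- V[miss <= max_missing, , drop = FALSE]
  }
  if (anyNA(V)) {
    message(sprintf("mean-imputing %d missing value(s)", sum(is.na(V))))
    for (j in which(rowSums(is.na(V)) > 0)) {
      row <- V[j, ]
      row[is.na(row)] <- mean(row, na.rm = TRUE)
      V[j, ] <- row
    }
  }
  M <- meth_matrix(V, rownames(V), colnames(V), scale = scale)
  if (as_m) {
    if (scale != "beta") stop("as_m only applies to beta input")
    M <- beta_to_m(M)
  }
  M
}

#' Read / write a relatedness matrix
#'
#' Dense format: square TSV with sample-id header and row names. Triplet
#' format: three columns `id1`, `id2`, `value` holding the lower triangle
#' including the diagonal.
#'
#' @param K a `relatedness_matrix`; `path` a file path.
#' @param format `"dense"` or `"triplet"` (`read_grm` autodetects).
#' @param kind passed to [relatedness_matrix()] on read.
#' @export
write_grm <- function(K, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  if (format == "dense") {
    df <- data.frame(sample_id = rownames(K), unclass(K),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    idx <- which(lower.tri(K, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id1 = rownames(K)[idx[, 1]],
                     id2 = colnames(K)[idx[, 2]],
                     value = K[idx])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path, kind = c("GRM", "ORM")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (identical(colnames(df), c("id1", "id2", "value"))) {
    ids <- unique(c(df$id1, df$id2))
    K <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    K[cbind(match(df$id1, ids), match(df$id2, ids))] <- df$value
    K[cbind(match(df$id2, ids), match(df$id1, ids))] <- df$value
  } else {
    K <- as.matrix(df[, -1, drop = FALSE])
    rownames(K) <- df[[1]]
  }
  relatedness_matrix(K, rownames(K), kind = kind)
}

#' Write MWAS summary statistics joined to annotation
#'
#' Columns: `probe_id`, `chr`, `bp`, `gene`, `beta`, `se`, `p`, `n`,
#' `analysis` — the column order shared across the pipeline.
#'
#' @param results `mwas_result` data.frame.
#' @param annotation probe annotation.
#' @param path file path.
#' @export
write_sumstats <- function(results, annotation, path) {
  d <- merge(results,
             annotation[, c("probe_id", "chromosome", "position", "gene")],
             by = "probe_id")
  d <- d[order(d$chromosome, d$position),
         c("probe_id", "chromosome", "position", "gene", "beta", "se", "p",
           "n", "analysis")]
  colnames(d) <- c("probe_id", "chr", "bp", "gene", "beta", "se", "p", "n",
                   "analysis")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  res <- data.frame(probe_id = d$probe_id, beta = d$beta, se = d$se,
                    p = d$p, n = d$n, analysis = d$analysis,
                    significant = d$p < MWAS_P_THRESHOLD,
                    stringsAsFactors = FALSE)
  class(res) <- c("mwas_result", "data.frame")
  res
}

#' Write region results as a BED-compatible table
#'
#' Converts the 1-based inclusive region coordinates to BED's 0-based
#' half-open convention at this boundary only.
#'
#' @param dmr data.frame from [run_dmr()].
#' @param path file path.
#' @export
write_dmr_bed <- function(dmr, path) {
  d <- data.frame(chrom = dmr$chromosome, start = dmr$start_bp - 1L,
                  end = dmr$end_bp, n_probes = dmr$n_probes,
                  beta = dmr$beta, se = dmr$se, p = dmr$p,
                  p_adj = dmr$p_adj)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an MPS model (weights TSV + JSON metadata sidecar)
#'
#' @param model an `mps_model`; `path` the weights TSV path (the sidecar is
#'   `<path>.json`).
#' @export
write_mps_model <- function(model, path) {
  utils::write.table(
    data.frame(probe_id = names(model$weights), weight = model$weights),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- model[c("lambda", "n_folds", "seed", "mask_size")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mps_model
#' @export
read_mps_model <- function(path) {
  wdf <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(weights = stats::setNames(wdf$weight, wdf$probe_id),
                 lambda = meta$lambda, n_folds = meta$n_folds,
                 seed = meta$seed, mask_size = meta$mask_size,
                 train_stats = data.frame(probe_id = wdf$probe_id,
                                          mean = 0, sd = 1)),
            class = "mps_model")
}

#' Read a prescription CSV
#'
#' Columns `person_id`, `dispense_day` (integer day offset or ISO date —
#' dates are converted to days since 1970-01-01 at this boundary),
#' `drug_code`, `quantity`, `daily_dose`.
#'
#' @param path file path.
#' @export
read_prescriptions <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(drug_code = "character"))
  if (is.character(d$dispense_day)) {
    num <- suppressWarnings(as.numeric(d$dispense_day))
    if (anyNA(num))
      num[is.na(num)] <- as.numeric(as.Date(d$dispense_day[is.na(num)]))
    d$dispense_day <- num
  }
  d
}
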