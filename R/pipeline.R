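# End-to-end orchestration: simulate (or load) a cohort, derive the
# prescription exposure, run both association scans, compare them, region
# analysis, cross-phenotype enrichment, profile-score training and external
# meta-analysis, writing every stage's table plus a JSON manifest.

#' Build a pipeline configuration
#'
#' Either a `simulate` block (a [sim_config()]) or explicit input paths.
#' All thresholds and exposure parameters live here so every run records
#' them in its manifest.
#'
#' @param simulate a [sim_config()] (or NULL to read the input paths).
#' @param paths named list of input files (`methylation`, `grm`,
#'   `phenotypes`, `prescriptions`, `annotation`) when not simulating.
#' @param out_dir output directory.
#' @param sig_threshold genome-wide significance level.
#' @param dmr_max_gap,dmr_p candidate-region knobs.
#' @param enrich_fractions,n_perm enrichment knobs.
#' @param grace_days,lead_days,tail_days exposure knobs.
#' @param mps_external_k,mps_external_n,mps_score_effect simulated external
#'   cohorts for the score stage.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(), paths = NULL,
                            out_dir = "methrx_run",
                            sig_threshold = MWAS_P_THRESHOLD,
                            dmr_max_gap = 500, dmr_p = 0.05,
                            enrich_fractions = c(0.001, 0.005, 0.01),
                            n_perm = 1000, grace_days = 30, lead_days = 7,
                            tail_days = 7, mps_external_k = 5,
                            mps_external_n = 500, mps_score_effect = 0.3,
                            seed = 1L) {
  if (is.null(simulate)) {
    need <- c("methylation", "grm", "phenotypes", "prescriptions",
              "annotation")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop("config must provide path(s): ", paste(miss, collapse = ", "))
    for (p in unlist(paths[need]))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  stopifnot(sig_threshold > 0, dmr_max_gap > 0, dmr_p > 0,
            all(enrich_fractions > 0), n_perm > 0)
  structure(list(simulate = simulate, paths = paths, out_dir = out_dir,
                 sig_threshold = sig_threshold, dmr_max_gap = dmr_max_gap,
                 dmr_p = dmr_p, enrich_fractions = enrich_fractions,
                 n_perm = n_perm, grace_days = grace_days,
                 lead_days = lead_days, tail_days = tail_days,
                 mps_external_k = mps_external_k,
                 mps_external_n = mps_external_n,
                 mps_score_effect = mps_score_effect,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages: cohort (simulated or loaded), prescription-exposure derivation,
#' demographics, standardization + ORM, GRM-BLUP residualization, the
#' self-report and prescription-derived association scans, effect-set
#' comparison, region analysis, circular-permutation enrichment between the
#' two scans, profile-score training, scoring of simulated external cohorts
#' and random-effects pooling. Each stage writes a TSV under `out_dir`; a
#' `manifest.json` records parameters, seeds, a config hash, and per-stage
#' status. Deterministic for fixed seeds.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the output directory; side effect: files + manifest.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  cfg_hash <- substr(.config_hash(config), 1, 12)
  manifest <- list(package = "methrx",
                   version = as.character(utils::packageVersion("methrx")),
                   config_hash = cfg_hash, seed = config$seed,
                   params = config[setdiff(names(config),
                                           c("simulate", "paths"))],
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(list(value = force(expr), status = "ok"),
                    error = function(e)
                      list(value = NULL, status = paste("error:",
                                                        conditionMessage(e))))
    manifest$stages[[name]] <<- res$status
    if (res$status != "ok") {
      jsonlite::write_json(manifest, out("manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("stage '", name, "' failed: ", res$status)
    }
    res$value
  }

  cohort <- stage("cohort", {
    if (!is.null(config$simulate)) simulate_cohort(config$simulate)
    else {
      p <- config$paths
      list(methylation = read_methylation(p$methylation),
           annotation = utils::read.delim(p$annotation,
                                          stringsAsFactors = FALSE),
           grm = read_grm(p$grm),
           phenotypes = utils::read.delim(p$phenotypes,
                                          stringsAsFactors = FALSE),
           prescriptions = read_prescriptions(p$prescriptions))
    }
  })
  phen <- cohort$phenotypes

  expo <- stage("exposure", {
    e <- derive_exposure(cohort$prescriptions,
                         stats::setNames(phen$draw_day, phen$sample_id),
                         grace_days = config$grace_days,
                         lead_days = config$lead_days,
                         tail_days = config$tail_days)
    utils::write.table(e, out("exposure.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    e
  })

  stage("describe", {
    d <- describe_cohort(phen)
    utils::write.table(d, out("demographics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    d
  })

  prep <- stage("standardize", {
    Z <- standardize_probes(cohort$methylation)
    list(Z = Z, orm = compute_orm(Z))
  })
  Z <- prep$Z

  covars <- cbind(age = phen$age, sex_F = as.numeric(phen$sex == "F"),
                  smoking = phen$smoking_proxy_M,
                  mono = phen$monocyte_prop, lymph = phen$lymphocyte_prop)

  scan <- function(y, label) {
    res <- reml_blup_residualize(y, cohort$grm)
    run_mwas(res$residuals, Z, covariates = covars, omega = prep$orm,
             mode = "fast", analysis = label,
             sig_threshold = config$sig_threshold)
  }
  mwas_sr <- stage("mwas_self_report", {
    r <- scan(phen$exposure, "self-report")
    write_sumstats(r, cohort$annotation, out("mwas_self_report.tsv"))
    r
  })
  mwas_pd <- stage("mwas_prescription", {
    y <- as.numeric(expo$status == "EXPOSED")
    keep <- expo$status != "EXCLUDED"
    rr <- reml_blup_residualize(y[keep], cohort$grm[keep, keep])
    r <- run_mwas(rr$residuals, Z[, keep], covariates = covars[keep, ],
                  omega = relatedness_matrix(prep$orm[keep, keep],
                                             kind = "ORM"),
                  mode = "fast", analysis = "prescription-derived",
                  sig_threshold = config$sig_threshold)
    write_sumstats(r, cohort$annotation, out("mwas_prescription.tsv"))
    r
  })

  stage("compare", {
    cmp <- compare_effect_sets(mwas_sr, mwas_pd)
    jsonlite::write_json(cmp[c("n_shared", "r", "r_p", "effect_ratio")],
                         out("comparison.json"), auto_unbox = TRUE,
                         digits = NA)
    cmp
  })

  stage("dmr", {
    d <- run_dmr(mwas_sr, Z, cohort$annotation,
                 max_gap = config$dmr_max_gap, p_thresh = config$dmr_p)
    write_dmr_bed(d, out("dmr_self_report.bed"))
    d
  })

  stage("enrichment", {
    enr <- circular_enrichment(mwas_sr, mwas_pd, cohort$annotation,
                               fractions = config$enrich_fractions,
                               n_perm = config$n_perm,
                               seed = config$seed + 1L)
    jsonlite::write_json(list(pairs = enr$pairs,
                              p_corrected = enr$p_corrected,
                              n_perm = enr$n_perm, seed = enr$seed),
                         out("enrichment.json"), digits = NA)
    enr
  })

  meta <- stage("mps_meta", {
    rr <- reml_blup_residualize(phen$exposure, cohort$grm)
    mask <- cohort$annotation$probe_id[cohort$annotation$on_450k &
                                         cohort$annotation$on_epic]
    model <- train_mps(rr$residuals, Z, mask = mask,
                       seed = config$seed + 2L)
    write_mps_model(model, out("mps_weights.tsv"))
    if (length(model$weights) == 0) {
      # a fully shrunk model is a legitimate outcome at small n: record it
      # and skip external scoring
      utils::write.table(
        data.frame(cohort = character(0), beta = numeric(0),
                   se = numeric(0), weight = numeric(0),
                   nagelkerke_r2 = numeric(0)),
        out("mps_cohorts.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      jsonlite::write_json(list(k = 0, note = "no probes selected"),
                           out("mps_meta.json"), auto_unbox = TRUE,
                           digits = NA)
      NULL
    } else {
      set.seed(config$seed + 3L)
      ext <- simulate_external_cohorts(model, config$mps_external_k,
                                       config$mps_external_n,
                                       config$mps_score_effect)
      assoc <- lapply(seq_along(ext), function(i) {
        s <- score_mps(model, ext[[i]]$methylation)
        cohort_association(s, ext[[i]]$exposure, ext[[i]]$covariates,
                           cohort = sprintf("sim%02d", i))
      })
      mr <- dl_meta(assoc)
      per <- mr$per_study
      per$nagelkerke_r2 <- vapply(assoc, `[[`, 0, "nagelkerke_r2")
      utils::write.table(per, out("mps_cohorts.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(mr[c("beta_pooled", "se_pooled", "ci95", "p",
                                "Q", "df", "tau2", "i2_percent", "k")],
                           out("mps_meta.json"), digits = NA)
      mr
    }
  })

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(config$out_dir)
}

# Stable hash of the configuration (stored in the manifest so outputs can be
# tied to the exact parameter set).
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
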