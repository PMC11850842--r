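# Synthetic cohorts with the statistical structure the pipeline assumes:
# full-sib family blocks in the relatedness kernel, AR(1)-correlated probes
# along each chromosome, a binary exposure with small standardized effects at
# designated CpGs, age/sex/smoking confounding, and prescription streams
# consistent with a known true exposure state.

#' Build a simulation configuration
#'
#' Validates and freezes the knobs of the cohort generator. Defaults emulate
#' a family-based population cohort at desk scale: sib-pair families, probes
#' 1 kb apart with moderate local correlation, a ~10% exposed fraction, and
#' per-probe standardized effects of 0.02 SD at the causal CpGs (the
#' magnitude reported for array-scale drug-exposure signals).
#'
#' @param n_samples,n_probes cohort dimensions.
#' @param n_families,family_size full-sib family blocks; remaining samples
#'   are unrelated.
#' @param causal_probes character vector of probe ids carrying a true effect
#'   (probe ids are `probe0001`, ...).
#' @param causal_effect standardized effect (SD of M per exposure unit),
#'   recycled over `causal_probes`.
#' @param exposure_prevalence fraction exposed, strictly inside (0, 1).
#' @param local_corr AR(1) coefficient in [0, 1) for adjacent probes within a
#'   chromosome.
#' @param probe_spacing_bp fixed inter-probe spacing.
#' @param n_chromosomes chromosomes the probes are split across.
#' @param h2_family fraction of per-probe variance from the family kernel.
#' @param confounder_effects named numeric vector of covariate effects on
#'   methylation (names among `age_z`, `sex_F`, `smoking_proxy_M`); the same
#'   covariates also shift exposure odds, creating confounding.
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 500, n_probes = 200, n_families = 100,
                       family_size = 2,
                       causal_probes = character(0), causal_effect = 0.02,
                       exposure_prevalence = 0.1, local_corr = 0.4,
                       probe_spacing_bp = 1000, n_chromosomes = 4,
                       h2_family = 0.2,
                       confounder_effects = c(age_z = 0.05, sex_F = 0.05,
                                              smoking_proxy_M = 0.05),
                       seed = 1L) {
  if (exposure_prevalence <= 0 || exposure_prevalence >= 1)
    stop("exposure_prevalence must be strictly inside (0, 1)")
  if (local_corr < 0 || local_corr >= 1)
    stop("local_corr must be in [0, 1)")
  if (h2_family < 0 || h2_family >= 1)
    stop("h2_family must be in [0, 1)")
  if (n_families * family_size > n_samples)
    stop("families cannot exceed n_samples")
  structure(list(n_samples = n_samples, n_probes = n_probes,
                 n_families = n_families, family_size = family_size,
                 causal_probes = as.character(causal_probes),
                 causal_effect = causal_effect,
                 exposure_prevalence = exposure_prevalence,
                 local_corr = local_corr,
                 probe_spacing_bp = probe_spacing_bp,
                 n_chromosomes = n_chromosomes, h2_family = h2_family,
                 confounder_effects = confounder_effects,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Full-sib block relatedness matrix
#'
#' Block-diagonal kinship: 1 on the diagonal, 0.5 between members of the same
#' family (full siblings), 0 elsewhere. Such a matrix is always positive
#' semi-definite.
#'
#' @param n_families,family_size,n_unrelated structure counts (all >= 0,
#'   total >= 1).
#' @return a `relatedness_matrix` of kind `"GRM"` with sample ids `S0001`...
#' @export
make_families_grm <- function(n_families, family_size, n_unrelated = 0) {
  n <- n_families * family_size + n_unrelated
  if (n < 1) stop("total sample count must be positive")
  K <- diag(n)
  if (n_families > 0 && family_size > 1) {
    for (f in seq_len(n_families)) {
      idx <- ((f - 1) * family_size + 1):(f * family_size)
      K[idx, idx] <- 0.5
      diag(K)[idx] <- 1
    }
  }
  ids <- sprintf("S%04d", seq_len(n))
  relatedness_matrix(K, ids, kind = "GRM")
}

#' Synthetic probe annotation
#'
#' Probes laid out with fixed spacing on `n_chromosomes` chromosomes,
#' 1-based positions, gene labels cycling over a synthetic list, and array
#' membership flags (all probes on the wider array; a leading fraction also
#' on the legacy array so array-intersection masks are exercisable).
#'
#' @param n_probes,probe_spacing_bp,n_chromosomes layout parameters.
#' @param frac_450k fraction of probes flagged as present on the legacy
#'   array (default 0.7).
#' @return data.frame: `probe_id`, `chromosome`, `position`, `gene`,
#'   `on_450k`, `on_epic`, `is_smoking_proxy`.
#' @export
make_annotation <- function(n_probes, probe_spacing_bp = 1000,
                            n_chromosomes = 4, frac_450k = 0.7) {
  per_chr <- ceiling(n_probes / n_chromosomes)
  chr_idx <- rep(seq_len(n_chromosomes), each = per_chr)[seq_len(n_probes)]
  within <- stats::ave(seq_len(n_probes), chr_idx, FUN = seq_along)
  genes <- sprintf("GENE%02d", ((seq_len(n_probes) - 1) %/% 5) %% 40 + 1)
  data.frame(probe_id = sprintf("probe%04d", seq_len(n_probes)),
             chromosome = paste0("chr", chr_idx),
             position = as.integer((within - 1) * probe_spacing_bp + 1),
             gene = genes,
             on_450k = seq_len(n_probes) <= round(frac_450k * n_probes),
             on_epic = TRUE,
             is_smoking_proxy = FALSE,
             stringsAsFactors = FALSE)
}

#' Simulate a methylation matrix with local correlation and family structure
#'
#' Probe j of sample i is
#' `mu_j + beta_j * exposure_i + covariate effects + structured noise`,
#' where the noise follows an AR(1) process of coefficient `local_corr` along
#' probe order within each chromosome and, at every probe, has cross-sample
#' covariance `h2_family * K + (1 - h2_family) * I` — so adjacent-probe
#' correlation equals `local_corr` and the family kernel explains
#' `h2_family` of the per-probe variance.
#'
#' @param config a [sim_config()].
#' @param exposure 0/1 vector of length `n_samples`.
#' @param grm a `relatedness_matrix` (ignored when `h2_family = 0`).
#' @param covariates optional numeric matrix (samples x covariates) whose
#'   columns named in `config$confounder_effects` shift probe means.
#' @return list with `methylation` (a `meth_matrix`, M scale), `annotation`,
#'   and `true_beta` (named per-probe effect vector).
#' @export
simulate_methylation <- function(config, exposure, grm = NULL,
                                 covariates = NULL) {
  n <- config$n_samples; m <- config$n_probes
  if (length(exposure) != n) stop("exposure length must equal n_samples")
  ann <- make_annotation(m, config$probe_spacing_bp, config$n_chromosomes)
  bad <- setdiff(config$causal_probes, ann$probe_id)
  if (length(bad))
    stop("causal probe(s) not in annotation: ", paste(bad, collapse = ", "))
  beta <- stats::setNames(rep(0, m), ann$probe_id)
  beta[config$causal_probes] <- rep_len(config$causal_effect,
                                        length(config$causal_probes))
  h2 <- config$h2_family
  L <- if (h2 > 0) {
    if (is.null(grm)) stop("h2_family > 0 needs a grm")
    if (nrow(grm) != n) stop("grm dimension must equal n_samples")
    t(chol(h2 * unclass(as.matrix(grm)) + (1 - h2) * diag(n)))
  } else NULL  # no family variance: innovations are plain iid normals
  rho <- config$local_corr
  # AR(1) innovations restart at each chromosome boundary
  E <- matrix(0, m, n)
  prev_chr <- ""
  for (j in seq_len(m)) {
    innov <- if (is.null(L)) stats::rnorm(n)
    else drop(L %*% stats::rnorm(n))
    if (ann$chromosome[j] == prev_chr)
      E[j, ] <- rho * E[j - 1, ] + sqrt(1 - rho^2) * innov
    else E[j, ] <- innov
    prev_chr <- ann$chromosome[j]
  }
  mu <- stats::rnorm(m, mean = 0, sd = 2)  # probe-specific M-value baselines
  V <- mu + outer(beta, as.numeric(exposure)) + E
  ce <- config$confounder_effects
  if (!is.null(covariates) && length(ce)) {
    use <- intersect(names(ce), colnames(covariates))
    if (length(use))
      V <- sweep(V, 2, drop(covariates[, use, drop = FALSE] %*% ce[use]),
                 "+")
  }
  ids <- sprintf("S%04d", seq_len(n))
  list(methylation = meth_matrix(V, ann$probe_id, ids, scale = "M"),
       annotation = ann, true_beta = beta)
}

#' Simulate a prescription dispensing stream consistent with known truth
#'
#' True-exposed samples receive a run of 28-day dispensings at 28-day
#' intervals that, once merged, form a treatment period covering the blood
#' draw with a lead of at least 7 days. True-unexposed samples receive no
#' records, except that a configurable fraction instead receive a historical
#' run ending well before the draw — persons the classifier must mark
#' EXCLUDED rather than UNEXPOSED.
#'
#' @param truth named logical/0-1 vector of true exposure per person.
#' @param draw_days named numeric vector of blood-draw days (same ids).
#' @param excluded_fraction fraction of true-unexposed persons given stale
#'   records (default 0).
#' @param min_scripts,max_scripts range of dispensing counts per stream.
#' @param seed optional integer seed (otherwise the caller's RNG state is
#'   used).
#' @return prescription data.frame (see [clean_prescriptions()]).
#' @export
simulate_prescriptions <- function(truth, draw_days, excluded_fraction = 0,
                                   min_scripts = 2, max_scripts = 12,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- names(truth)
  if (is.null(ids) || !identical(ids, names(draw_days)))
    stop("truth and draw_days must share named person ids")
  recs <- list()
  stream <- function(id, first_day, n_scripts) {
    data.frame(person_id = id,
               dispense_day = first_day + 28 * (seq_len(n_scripts) - 1),
               drug_code = "040303/01", quantity = 28, daily_dose = 1,
               stringsAsFactors = FALSE)
  }
  for (id in ids) {
    if (as.logical(truth[id])) {
      n_scripts <- sample(min_scripts:max_scripts, 1)
      # last dispensing at or just before the draw so it is covered
      first <- draw_days[id] - 28 * (n_scripts - 1) -
        sample(7:27, 1)  # lead of the first script >= 7 days
      recs[[length(recs) + 1L]] <- stream(id, first, n_scripts)
    } else if (excluded_fraction > 0 &&
               stats::runif(1) < excluded_fraction) {
      n_scripts <- sample(min_scripts:max_scripts, 1)
      # stream ends > 90 days before the draw: outside any tail window
      last_end <- draw_days[id] - 90 - sample(0:60, 1)
      first <- last_end - 28 * n_scripts
      recs[[length(recs) + 1L]] <- stream(id, first, n_scripts)
    }
  }
  if (length(recs) == 0)
    return(data.frame(person_id = character(0), dispense_day = numeric(0),
                      drug_code = character(0), quantity = numeric(0),
                      daily_dose = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

#' Simulate a full synthetic cohort
#'
#' Ties the pieces together under one seed: family GRM, phenotype table
#' (age, sex, smoking proxy, cell proportions, batch, draw day), a true
#' exposure state confounded by age/sex/smoking, methylation with spiked
#' effects at the causal probes, and a matching prescription stream.
#'
#' @param config a [sim_config()].
#' @param excluded_fraction passed to [simulate_prescriptions()].
#' @param confounded when TRUE (default) exposure odds are shifted by
#'   standardized age (+0.3), female sex (+0.4) and smoking proxy (+0.2);
#'   when FALSE exposure is drawn independently at the configured prevalence.
#' @return list: `methylation`, `annotation`, `grm`, `phenotypes`,
#'   `prescriptions`, `truth` (list `exposure`, `beta`), `config`.
#' @export
simulate_cohort <- function(config, excluded_fraction = 0,
                            confounded = TRUE) {
  set.seed(config$seed)
  n <- config$n_samples
  n_unrel <- n - config$n_families * config$family_size
  grm <- make_families_grm(config$n_families, config$family_size, n_unrel)
  ids <- rownames(grm)
  age <- round(stats::runif(n, 25, 75))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  smoking <- stats::rnorm(n, -1, 1)  # AHRR-proxy M-values, lower = smoker
  age_z <- as.numeric(scale(age))
  lin <- stats::qlogis(config$exposure_prevalence)
  if (confounded)
    lin <- lin + 0.3 * age_z + 0.4 * (sex == "F") + 0.2 * smoking
  exposure <- stats::rbinom(n, 1, stats::plogis(lin))
  covars <- cbind(age_z = age_z, sex_F = as.numeric(sex == "F"),
                  smoking_proxy_M = smoking)
  sim <- simulate_methylation(config, exposure, grm, covariates = covars)
  mono <- stats::runif(n, 0.05, 0.15)
  lymph <- stats::runif(n, 0.2, 0.45)
  draw_day <- round(stats::runif(n, 400, 2000))
  phen <- data.frame(sample_id = ids, exposure = exposure, age = age,
                     sex = sex, smoking_proxy_M = smoking,
                     monocyte_prop = mono, lymphocyte_prop = lymph,
                     batch = sample(c("b1", "b2"), n, replace = TRUE),
                     draw_day = draw_day,
                     lifetime_MDD = stats::rbinom(n, 1,
                       stats::plogis(-2 + 1.5 * exposure)) == 1,
                     bipolar = stats::rbinom(n, 1, 0.01) == 1,
                     stringsAsFactors = FALSE)
  truth <- stats::setNames(exposure == 1, ids)
  rx <- simulate_prescriptions(truth, stats::setNames(draw_day, ids),
                               excluded_fraction = excluded_fraction)
  list(methylation = sim$methylation, annotation = sim$annotation,
       grm = grm, phenotypes = phen, prescriptions = rx,
       truth = list(exposure = truth, beta = sim$true_beta),
       config = config)
}

#' Simulate external cohorts carrying a methylation profile score signal
#'
#' Per cohort: a latent standard-normal score, exposure drawn from a logistic
#' model with the stated log-odds per SD of score, and methylation at the
#' model's weighted probes constructed so that the computed (per-cohort
#' standardized) score reproduces the latent score exactly when
#' `probe_noise_sd = 0`.
#'
#' @param model an `mps_model` (see [train_mps()]) with >= 1 nonzero weight.
#' @param k number of cohorts.
#' @param n_per_cohort samples per cohort.
#' @param score_effect log-odds of exposure per SD of score.
#' @param base_prevalence intercept-scale exposure prevalence (default 0.3).
#' @param probe_noise_sd SD of independent probe-level noise (default 0).
#' @param seed optional integer seed.
#' @return list of length `k`; each element has `methylation` (M scale),
#'   `exposure`, `covariates` (age, sex_F), `latent_score`.
#' @export
simulate_external_cohorts <- function(model, k, n_per_cohort, score_effect,
                                      base_prevalence = 0.3,
                                      probe_noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (k == 0) return(list())
  w <- model$weights
  if (length(w) == 0) stop("model has no nonzero weights")
  lapply(seq_len(k), function(ci) {
    n <- n_per_cohort
    s <- stats::rnorm(n)
    expo <- stats::rbinom(n, 1, stats::plogis(
      stats::qlogis(base_prevalence) + score_effect * s))
    # probe value = sign(weight) * latent score (+ optional noise); after
    # per-cohort standardization every weighted term contributes |w| * z(s)
    V <- outer(sign(w), s)
    if (probe_noise_sd > 0)
      V <- V + matrix(stats::rnorm(length(w) * n, sd = probe_noise_sd),
                      length(w), n)
    ids <- sprintf("C%02d_%04d", ci, seq_len(n))
    list(methylation = meth_matrix(V, names(w), ids, scale = "M"),
         exposure = stats::setNames(expo, ids),
         covariates = cbind(age_z = stats::rnorm(n),
                            sex_F = stats::rbinom(n, 1, 0.5)),
         latent_score = s)
  })
}
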