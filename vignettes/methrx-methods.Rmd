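---
title: "methrx: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methrx: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrx)
```

This vignette is the package's own account of its science: the models it
fits, the assumptions they rest on, what the synthetic-data generator does
and does not emulate, and the numerical choices that affect results. It
states no empirical claim that the test suite does not itself compute.

## 1. The exposure phenotype

Prescription-derived exposure is built in three steps.

**Cleaning.** Records are dropped when the drug code does not match the
class filter (default the antidepressant BNF paragraph prefix `"040303"`),
or when quantity or daily dose is missing or non-positive — without both,
the days of supply cannot be computed. Every dropped record carries a
machine-readable reason; kept and dropped partition the input.

**Treatment periods.** Each record covers `ceiling(quantity / daily_dose)`
days from its dispensing day. Scanning in date order, a record joins the
current period if its dispensing day is at most `grace_days` (default 30)
past the period's end, extending the end; otherwise a new period starts.
The grace gap absorbs imperfect adherence and late refills. Both the
coverage formula and the grace default are explicit stand-ins — the
cohort-specific episode mechanics they replace are not published in
detail — so both are configuration knobs and are recorded in the `params`
attribute of every exposure table.

**Classification at blood draw.** A person is EXPOSED when some period
satisfies `draw >= start + lead_days` and `draw < end + tail_days` (both
windows default to 7 days): long enough on drug for a biological signature
to plausibly exist, and not so long off drug that it has washed out.
Persons with no matching prescriptions on record are UNEXPOSED. Everyone
else — too early in a period, or in a gap — is EXCLUDED and removed from
analysis rather than contaminating either group. Time in treatment is
`draw - start` and is defined only when the draw falls inside the covering
period; a draw caught by the tail window alone is EXPOSED with missing
time-in-treatment, which is the convention the time-in-treatment
correlation analysis expects ("those within a treatment period").

The self-report phenotype is a plain column of the phenotype table; no
derivation logic. The MDD subgroup is lifetime-MDD cases with bipolar
cases removed (`mdd_subgroup()`).

## 2. The association model

Per probe $j$ the model is

$$ y = X c + z_j b_j + u + \varepsilon,\qquad
   u \sim N(0, \sigma^2_o \Omega),\ \varepsilon \sim N(0, \sigma^2_e I), $$

where $z_j$ is the standardized probe (so $b_j$ is per 1 SD of M-value),
$X$ holds the covariates (age, sex, smoking-proxy probe M-value, cell
proportions), and $\Omega = Z'Z/m$ is the omics-relatedness matrix over
the $m$ standardized probes. Before the scan the phenotype is residualized
on a kinship matrix by single-kernel REML with BLUP subtraction, removing
family structure; the binary exposure is treated as a linear probability
throughout, matching the residualization workflow it mirrors.

Numerical strategy: the kernel is eigendecomposed once; the REML criterion
is profiled over the log variance ratio and minimized by Brent search on
$[-10, 10]$ (ratio bounds $e^{-10}$ to $e^{10}$), followed by one
parabolic refinement on a fixed stencil. The refinement matters: Brent
alone resolves the ratio only to about $\sqrt{\epsilon}$, which shows up
as apparent violations of scale equivariance at the $10^{-7}$ level; with
it, rescaling the phenotype reproduces scaled effects and unchanged
p-values to $10^{-10}$. Boundary solutions (no kernel variance) are
reported with `converged = FALSE`, not errors. Note that BLUP residuals
are *not* uncorrelated with the fitted random effect — both are linear
images of $V^{-1}r$ — so the suite checks the projection identities that
actually hold: residuals orthogonal to the fixed design, and exact
decomposition $y = \hat\mu + \hat g + \hat e$.

Two estimation modes are provided because published mixed-model
association tools differ on the point and the original description does
not say which was used: `fast` estimates the variance ratio once under the
probe-free null and reuses it for every probe (vectorized generalized
least squares; the standard approximation), `exact` re-optimizes REML per
probe. On structured simulations their p-values agree in rank above 0.99;
`exact` is the reference against a dense brute-force REML oracle in the
tests. Wald p-values use the standard normal, the large-sample convention
of mixed-model association software; the genome-wide threshold defaults
to `9.42e-8`, the recommended array-scale level for case-control
methylome scans.

Sex-stratified scans are orchestration only: the same model on each sex
subset, minus the sex covariate. The per-probe sex-difference test
$z = (b_F - b_M)/\sqrt{SE_F^2 + SE_M^2}$ is a declared stand-in, since the
original statistic is unstated; it is exact when the two scans are
independent. The tested probe remains inside $\Omega$ (single-ORM design);
an exclude-self variant is deliberately out of scope.

## 3. Regions

Candidates are maximal runs of probes with nominal significance
(`p < 0.05`), shared effect sign, and inter-probe gaps ≤ 500 bp; with
sub-enumeration every contiguous sub-window of length ≥ 2 is also a
candidate, which is what makes published candidate counts run into the
hundreds of thousands. The minimum run length is 2: the source text's
"sets (> 2)" conflicts with its own reported two-CpG region, so ≥ 2 is
taken as intended and the cutoff is a configuration switch.

Each candidate is tested by correlation-adjusted inverse-variance
meta-analysis: with $w_i = 1/se_i^2$,

$$ B = \frac{\sum w_i b_i}{\sum w_i},\qquad
   \mathrm{Var}(B) = \frac{\sum_{ij} w_i w_j \rho_{ij} se_i se_j}
                          {(\sum w_i)^2}, $$

with $\rho$ the sample correlation of the member probes' standardized
M-values. With $\rho = I$ this is exactly classical IVW pooling; with
perfectly correlated probes the variance equals a single probe's — no
pseudo-precision. A ridge of $10^{-6}$ is added to the diagonal of $\rho$
for numerical stability (tests that verify exact limits pass
`shrink = 0`). Bonferroni uses the number of candidates tested in the run.

## 4. Cross-study concordance

The overlap of two top-hit sets is tested by the exact hypergeometric
upper tail against an explicit background (the caller must say whether the
background is the full array or the post-QC probe set; nothing is
defaulted silently). Enrichment between two full result sets uses circular
permutation: probes are filtered to concordant effect direction, ordered
along the genome, and the top 0.1/0.5/1% marked per set; for each
threshold pair the 2×2 table's log odds ratio (Haldane 0.5 on zero cells)
is the statistic; the null rotates one set's indicator vector by a uniform
random offset, which preserves the local correlation structure of the
marks. Per-pair p-values use the plus-one estimator
$(1 + \#\{perm \ge obs\})/(1 + n_{perm})$, never zero; the corrected p
compares the observed best statistic over all nine pairs with each
permutation's best — the max-statistic correction for having scanned
several thresholds. Internally the rotation counts for *all* offsets are
obtained at once by FFT cross-correlation, so permutation counts in the
thousands are cheap; the identity-offset column reproduces the observed
table exactly, which the suite checks.

## 5. The methylation profile score

Training is 10-fold cross-validated LASSO (`glmnet`, mixing parameter 1)
of the kinship-residualized exposure on the standardized probes inside an
array-intersection mask. The penalty is chosen at the minimum mean CV
error rather than the 1-SE rule — the source specifies only 10-fold CV
with mixing parameter 1, and the minimum is the less aggressive of the two
conventions; the choice is recorded in the model metadata. Fold assignment
is seeded, so training is deterministic. Training on the continuous
residual (linear L1, not logistic) mirrors the residualization workflow.

Scoring an external cohort is $\sum_j w_j z_j$ where $z_j$ standardizes
each probe with the *external cohort's own* mean and SD — each cohort is
assumed separately preprocessed, so training-set statistics would not
transfer; a `standardize = "training"` switch exists for the alternative.
Missing probes are skipped and counted in a coverage report.

Per-cohort association is logistic regression of exposure on the
standardized score plus covariates; family/twin cohorts pass cluster ids
and get estimating-equation (cluster-robust sandwich) standard errors.
Nagelkerke's pseudo-R² is computed from the fitted and covariates-only
log-likelihoods. Pooling is DerSimonian–Laird: moment estimator for τ²,
random-effects weights $1/(se_i^2 + \tau^2)$, $I^2 = \max(0, (Q - df)/Q)$.
When $Q \le k-1$ the estimator collapses exactly to fixed-effect IVW. I²
is reported as a point estimate only; the confidence-interval method for
I² used in the source is unstated, so none is fabricated.

## 6. What the generator emulates — and what it does not

`simulate_cohort()` produces, under one seed: a block full-sib kinship
matrix (coefficient 0.5; arbitrary pedigrees are out of scope — sib blocks
suffice to exercise BLUP), probe M-values with AR(1) correlation along
position within each chromosome (one parameter controls the structure
both the region analysis and circular permutation rely on; real cohorts'
correlation magnitude is not published, so the default 0.4 is nominal and
configurable), per-probe family variance `h2_family` through the kinship
kernel, confounding of both methylation and exposure odds by age, sex and
the smoking proxy, and a prescription stream whose round trip through the
exposure classifier reproduces the true exposure exactly when the
excluded fraction is zero. Causal probes shift by `causal_effect` M-value
SDs per exposure unit; note this *generator* unit differs from the
reported per-1-SD association scale by a factor of var(exposure), and the
acceptance tests plant effects on the reported scale. Dates are integer
day offsets from an epoch; calendar parsing is confined to the readers.

Not emulated: array chemistry, batch/chip effects, realistic LD or
genotypes, cell-composition estimation, normalization. A green suite
therefore establishes the statistical machinery on data with the *assumed*
structure, not robustness to assay artefacts.

External cohorts for the score stage are generated so that the computed
standardized score equals the latent score exactly (probe values are
sign(weight) × latent score; optional probe noise relaxes this), with
exposure drawn from a logistic model at the stated log-odds per SD.

## 7. Acceptance targets and known limitations

The three worked-example targets are the chi-squared statistics of
published exposed/unexposed count tables, recomputed by
`chisq_independence()` under the convention that exactly reproduces them:
Yates continuity correction for 2×2 tables, never for wider ones. The
published self-report sex statistic is *not* reproducible from its printed
counts under either convention (reconstruction gives ~216 vs printed 214,
presumably a sample-filtering difference upstream of the printed table);
it is therefore not a target.

Known limitations: linear-probability treatment of a binary outcome;
single variance component (no multi-kernel models); no inflation-factor
correction (none is described for the workflow mirrored here); Spearman
p-values by t approximation (no exact permutation p); no dose-equivalence
conversion between drugs.
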