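---
title: "Hazard-ratio-weighted signature scoring and optimal-cutoff survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hazard-ratio-weighted signature scoring and optimal-cutoff survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senosurv)
```

# The analysis in one paragraph

senosurv evaluates whether a gene signature — a curated list of gene
symbols, such as senescence programs in lung cancer — carries prognostic
information in an integrated, multi-dataset expression cohort. The chain
is: harmonize the expression matrices onto one scale and one probe
universe, with duplicate and quality-control filtering; summarize the
signature per patient as a hazard-ratio-weighted average of gene
expression; dichotomize the score at the most statistically significant
cutoff within the interquartile range; and quantify the split by
Kaplan–Meier curves, the log-rank test, Cox proportional-hazards models,
Benjamini–Hochberg FDR control across signatures/strata/endpoints, and
two-variable covariate-adjusted Cox models.

# Harmonization

Input matrices hold nonnegative linear-scale intensities (MAS5-like), one
column per sample. Five stages run in a fixed order; each is available as a
standalone function and `harmonize()` logs per-stage sample/feature counts:

1. **Mean-target scaling.** Every sample is multiplied by
   `target / mean(sample)`; the default target of 1000 is the conventional
   second-pass scaling value for this array generation. The operation is
   idempotent and only meaningful on the linear scale, which is why
   harmonization stays linear and any log transform happens inside scoring.
2. **Shared-probe restriction** to the probe universe common to all
   platforms in the database.
3. **Duplicate removal.** Samples whose expression vector equals an earlier
   sample's after rounding to 4 decimals are dropped, keeping the first
   occurrence. Rounding makes the rule immune to float round-off while
   still catching true technical replicates; the chance that two distinct
   biological samples collide at 4 decimals across thousands of probes is
   nil.
4. **QC interval filtering.** A sample is kept iff every QC metric
   (background, noise, present-call rate, 3′/5′ housekeeping ratios …) lies
   within the central 95% interval of that metric across the pooled cohort.
   We implement the interval as the 2.5th–97.5th percentile band rather
   than mean ± 1.96 SD because the metrics this rule polices are exactly
   the heavy-tailed ones that wreck a parametric interval
   (`method = "parametric"` is available). Intervals are computed once on
   the full input and applied once — no iteration — and on the pooled
   cohort, not per batch, because the database is analyzed as one cohort.
   Note the consequence: with five independent metrics the conjunction
   trims roughly `1 - 0.95^5 ≈ 23%` of even a clean cohort. That is the
   documented behavior of the rule, not an accident; skip the `qc`
   argument to skip the stage.
5. **Probe-to-gene collapse.** One row per gene: the mapped probe with the
   largest interquartile range across samples, ties broken by the
   lexicographically smallest probe id. This is a deterministic stand-in
   for annotation-database-driven probe selectors (e.g. JetSet-style
   specificity scoring, which needs sequence annotation outside our scope);
   users with a curated probe choice encode it in the mapping table, which
   is an ordinary input.

# Signature scoring

Weights come from the data: for each matched gene a univariate Cox model on
the per-gene z-score of `log2(intensity + 1)` yields a hazard ratio per
1 SD, and the weight is `w_g = −ln HR_g`. The sign convention follows the
risk interpretation — HR > 1 (risk) gives negative weight, HR < 1
(protective) positive weight — so *high scores always mean good prognosis*.
Only the sign rule is canonical; the `−ln HR` magnitude uses exactly the
quantity the weights are derived from, and `mode = "sign_only"` is kept as
a sensitivity analysis. Zero-variance genes cannot be z-scored: they get
HR = 1, weight 0 and a flag, so the weight vector always aligns with the
matched gene list.

The score is `S_i = Σ w_g e_ig / Σ |w_g|`. By default `e_ig` is the
per-gene z-score of log2 intensity, which makes the score dimensionless,
comparable across genes, and invariant to positive rescaling of the matrix
(exactly invariant up to the `+1` guard, negligible at MAS5-scale
intensities); `expression_mode = "raw"` reproduces a literal weighted mean
of intensities for users who want the platform-style raw average. Whether
the original platform weights raw or standardized expression is not
something we assert; both are first-class modes.

**In-sample optimism.** Deriving weights and scores on the same cohort
(the default, matching the single-cohort procedure) makes even a null gene
set's score outcome-correlated, inflating downstream significance on top of
the cutoff-selection effect. `crossfit_scores()` provides the k-fold
alternative — weights and z-parameters from k−1 folds, scores on the
held-out fold — and `analysis_config(cv_folds = k)` switches the pipeline
to it. It is documented and optional, never silently applied.

# Survival machinery

The Kaplan–Meier estimator and Cox partial-likelihood maximization are
delegated to the survival package (`survfit`, `coxph` with Efron ties by
default and Breslow via `ties =`); confidence intervals are Wald intervals
at the fixed 95% level. Degenerate inputs are surfaced: constant covariates
error by name, non-convergence errors, and a monotone likelihood (perfect
separation) flags the fit instead of silently reporting a huge HR. Exact
subject replication leaves the Breslow estimate unchanged and scales the SE
by `1/√2`; under Efron the manufactured ties perturb the estimate slightly,
which is why that classical identity is exact only for Breslow.

The **log-rank statistic is computed in-package** from aggregated risk-set
counts (observed-minus-expected with hypergeometric variance, χ²₁ upper
tail). The reason is the cutoff scan: it needs the statistic at hundreds of
candidate dichotomizations and, for permutation calibration, at thousands
of permuted group assignments; our implementation evaluates whole blocks of
assignments with one matrix product, which `survdiff()` cannot do. The test
suite pins the single-assignment path to `survdiff` and to the Cox score
test on untied data.

## The minimum-p cutoff scan

Candidates are all distinct score values whose quantile rank lies in
[0.25, 0.75] (the IQR window) and which leave both groups with at least
`min_group = 5` subjects — the floor prevents degenerate splits inside the
window on small strata. Samples with score strictly greater than the cutoff
are "high"; this half-open convention is stated once and used everywhere.
The selected cutoff minimizes the log-rank p, with ties resolved to the
smallest cutoff for determinism. The result keeps the full p-versus-cutoff
profile, the Cox HR/CI of the selected indicator and both KM curves.

The selected p is an unadjusted minimum over many correlated tests and is
therefore anti-conservative — under a null score the scan rejects at 5%
roughly a quarter of the time (the acceptance script measures this). We
report that minimum because it is what optimal-cutoff platforms display,
and we attach: (i) a multiplicity note with the candidate count, (ii) an
optional permutation-adjusted p (`n_perm` score permutations of the full
scan; `(1 + #{min-p ≤ observed})/(n_perm + 1)`), which restores the nominal
level, and (iii) BH FDR control across signatures, strata and endpoints at
the 10% threshold, applied exactly as stated to the selected p-values.
Whether a platform's displayed p is selection-corrected is left open; both
values are surfaced.

## Two-variable adjusted models

Each clinical covariate is assessed in its own
`signature + covariate` Cox model on the samples with a non-missing value
for that covariate. Complete cases per model — rather than one
all-covariate complete-case set — maximizes the n available to each
comparison, at the price that models are not fitted on identical cohorts;
that trade-off is inherited deliberately from the analysis design this
package implements. The signature term can be the selected high/low
indicator (default) or the continuous score; the published table's choice
is not stated, so both are supported.

# The synthetic cohort generator

`generate_cohort()` emulates what the analysis assumes, with known truth
for recovery tests:

- **Expression**: gene g in sample i is `2^(μ_g + z_ig)` with
  `μ_g ~ U(6, 10)` on the log2 scale and `z ~ N(0, 1)` — a log-normal
  intensity spread resembling MAS5-scale arrays without modeling chip
  chemistry.
- **Survival**: hazard `h_i = λ0 · exp(Σ β_g z_ig + Σ γ_c)`, exponential
  event times, censoring as the minimum of an independent exponential and
  an administrative horizon — the simplest mechanism satisfying the
  non-informative censoring KM and Cox assume. Hazards are driven by the
  *latent* z-scores, not the raw intensities, so batch shifts are pure
  nuisance and harmonization's job is cleanly separable in tests.
- **Nuisance**: per-batch multiplicative intensity shifts (log-normal,
  SD `batch_log_shift_sd` on the natural-log scale), exact-copy duplicate
  samples, and appended samples whose QC metrics are pushed far outside
  the central 95% interval of the rest.
- **Reproducibility**: five named RNG substreams (expression, survival,
  batch, injection, qc) derived from one seed, so changing, say, the batch
  model leaves the survival outcomes bit-identical.

Defaults are fixed once and describe a lung-cancer-like cohort, time in
months: `λ0 = 0.012`/month (median survival ≈ 58 months),
`censor_rate = 0.01`/month with a 120-month horizon (≈ half the cohort
censored, typical of public lung series), covariate frequencies
(histology/sex/smoking) taken from a large integrated cohort's OS arm with
zero covariate log-hazards unless requested. For the recovery studies that
specify 30% censoring, censor rates are solved analytically from
`P(censor < event)` under a 240-month horizon (0.0048418/month for a
homogeneous null arm; 0.0016883/month for the two-arm ln HR = −1 design) —
at 120 months the administrative cutoff alone would already exceed 30% in
the protective arm.

What the generator does *not* emulate: probe-level cross-hybridization, RNA
degradation, 3′/5′ chemistry (QC metrics are abstract numeric columns),
platform-specific probe architecture, or correlated gene–gene structure
beyond the shared survival signal. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to every artifact of real microarray data.

# Numerical and design choices

- Percentages in cohort summaries round half-up to one decimal so published
  count tables recompute exactly; both the full-cohort and annotated-only
  denominators are supported because the two conventions legitimately
  coexist in summary tables and figures.
- Strata below 30 samples are analyzed but flagged `underpowered`, echoing
  the ≥ 30-sample inclusion floor such databases use.
- Weight antisymmetry: inverting every HR (swapping the risk/protective
  reading) negates every weight and hence every score. Note this is an
  algebraic identity of the weighting scheme; recoding the event indicator
  of a Cox fit is *not* an exact sign flip, because it changes the risk
  sets, not just the coefficient sign.
- A "perfectly separated" score does not force the scan to cut between the
  clusters: with everything separated, a more extreme split can carry a
  larger log-rank statistic than the clean one. The scan is faithful to
  min-p; the tests construct the cluster gap at the window edge, where the
  clean split provably wins.
- Determinism: every stochastic step (generator, fold assignment,
  permutations) is seeded through the configuration, and two runs with one
  seed produce byte-identical report bundles.
- Problem sizes in the tests and acceptance script (e.g. 100 seeds at
  n = 600 for group-effect recovery, 50 seeds at n = 800 for weight signs,
  1000 null replicates for the inflation measurement, 200–500 permutations
  per scan) were chosen once as the smallest sizes at which Monte-Carlo
  error is clearly inside the stated tolerances.

# Known limitations

- No proportional-hazards diagnostics, time-varying covariates, competing
  risks or restricted-mean summaries; the modeling scope is the classical
  KM / log-rank / Cox toolkit the analysis design calls for.
- The probe selector is variance-based, not annotation-based; it matches
  the intent (one reliable probe per gene) but not the exact choices of
  sequence-aware selectors unless a curated map is supplied.
- In-sample weighting remains the default because it mirrors the
  single-cohort procedure; its optimism is documented and measurable with
  `cv_folds`, not corrected silently.
- Raw CEL-file processing, public-repository download, and the derivation
  of the signature gene lists themselves are out of scope; signatures are
  consumed as inputs.
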