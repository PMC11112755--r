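---
title: "Methods: multiomic analysis of crossover exposure studies"
author: "crossomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiomic analysis of crossover exposure studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossomix)
```

# The study design the package models

`crossomix` analyses repeated-measures crossover exposure studies: each
participant is exposed under two conditions (for example, a walk at a
high-traffic site and at a low-traffic background site) and sampled at
three occasions per condition — before, 2 h after and 24 h after the
exposure. With 50 participants this yields 300 omics profiles; every
participant acts as their own control, so between-person confounding is
absorbed by the within-person covariance rather than by covariates.

The package covers the full chain: synthetic data generation,
preprocessing, per-feature association testing against continuous
exposures, consensus clustering of redundant features, sparse
conditional-independence network estimation, and annotation/enrichment.
`runPipeline()` orchestrates all stages under one master seed.

# The synthetic-data generator

`simulateStudy()` emulates the statistical structure the analysis
assumes, so every downstream stage is testable without any download:

* **Design** (`generateDesign()`): 50 participants by default, two sites,
  three occasions, first-visit site randomized per participant; a
  three-level health group (proportions 0.36/0.36/0.28), age (mean 65.5,
  SD 6), sex (64% male) and BMI drawn per participant; two crossed
  technical factors (4 plates, 7 boxes) assigned round-robin.
* **Exposures** (`generateExposures()`): five pollutants (PM10, PM2.5,
  NO2, BC, PCNT) with the high-exposure site mean strictly above the
  low-exposure mean for each; one value per (participant, visit),
  constant across the visit's three occasions, with visit-level Gaussian
  noise floored at zero. The default means/SDs (e.g. NO2 90 vs 35 with
  SD 18, BC 12 vs 2 with SD 2) give clearly separated sites with partial
  interquartile overlap for the particulate measures — the qualitative
  pattern seen in kerbside-versus-park monitoring.
* **Feature correlation**: profiles are drawn from a multivariate normal
  whose precision matrix has a known sparse support
  (`generatePrecisionMatrix()`; diagonal dominance guarantees positive
  definiteness and the support is exactly the drawn edge set — the
  ground truth for network-recovery tests).
* **Within-person correlation**: a per-(participant, feature) random
  intercept (SD 0.5 by default) across all six occasions.
* **Exposure effects** (`effectSpec()`): sparse — by default 10% of
  features respond to NO2 with 0.01 log2 units per concentration unit.
  The effect enters on the two post-walk occasions only
  (`mode = "post"`), which creates the within-person contrast the
  repeated-measures model exploits; a visit-level main-effect mode
  (`mode = "all"`) is available because the entry convention is a
  genuinely open modelling choice.
* **Batch effects**: additive offsets on the log2 scale (hence
  multiplicative on raw intensity), one per feature and factor level,
  SD 0.3 by default, for both crossed technical factors — consistent
  with downstream log2 modelling.
* **Left-censoring**: the lowest `censorFraction` quantile of each
  feature (10% by default, hard per-feature threshold) is set missing —
  the simplest missing-not-at-random mechanism that quantile-based
  imputation assumes.

What the generator does **not** emulate: chromatographic drift,
isotopologue structure, probe-level microarray noise, heavy-tailed
intensity distributions, or exposure measurement error. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to instrument artifacts.

# Preprocessing

The pipeline order is filter → log2 → impute → outlier-flag → denoise,
recorded in the run manifest. The order is enforced by the scale flag of
the `OmicsSet` container (imputation refuses raw-scale data); it is a
deliberate choice since the relative ordering of imputation and outlier
screening is not canonical.

**Missingness filter.** A feature is removed when missing in at least
40% of participants (threshold inclusive). The fraction is computed over
participants — a feature observed in any sample of a participant counts
as observed for that participant — with a per-sample variant available
(`by = "sample"`).

**QRILC imputation.** Left-censored missing values are imputed per
sample (column): with missing fraction $f$, the observed order
statistics are regressed on standard-normal quantiles at plotting
positions spanning $(f, 1)$, giving estimates $(\hat\mu, \hat\sigma)$ of
the latent complete distribution; missing values are drawn from
$\mathcal N(\hat\mu, (\texttt{tuneSigma}\cdot\hat\sigma)^2)$ truncated
above at the censoring quantile $\hat\mu + \hat\sigma\Phi^{-1}(f)$.
`tuneSigma` defaults to 1; columns with fewer than 4 observed values
fall back to half-minimum imputation with a warning. On a 20%-censored
$\mathcal N(10,1)$ column of length 500 the estimates land within 0.15
of the truth (verified in the acceptance suite).

**PCA outlier flagging.** Samples are flagged when their score on any of
the first 3 principal components (standardized features) deviates from
the median by more than 5 robust SDs (MAD × 1.4826). This is a concrete,
reproducible stand-in for visual PCA screening; the number of flagged
samples is data-dependent, never hard-coded, and the caller decides on
removal.

**Technical denoising.** For each feature an intercept-only linear mixed
model with crossed random intercepts for the technical factors is fitted
by REML (`lme4::lmer`), and the per-sample best linear unbiased
predictors are subtracted, retaining the fixed-effect mean. Single-level
factors are dropped with a warning; if the joint fit fails the fall-back
is sequential one-factor fits. With batch SD 2 against residual SD 0.5,
the post-denoising between-batch variance share is below 5%.

# The repeated-measures association model

For each feature and exposure, the participant's vector of (up to) six
occasion values is modelled as

$$Y_i \sim \mathcal{MVN}(X_i\beta, \Sigma), \qquad
  \Sigma = D\,R\,D,$$

with $R$ an unstructured 6×6 correlation matrix (15 free parameters) and
$D$ diagonal occasion-specific SDs (6 parameters), occasions ordered
site × time. The mean includes the exposure (visit-level value repeated
over the visit's occasions), age, sex, health group and BMI. BMI is
included by default; it is exposed as a switch because adjustment sets
legitimately differ between analyses.

Estimation is REML: $\beta$ is profiled out by generalized least
squares and $\Sigma$ maximized by an EM iteration whose update is the
expected residual cross-product matrix plus the $\beta$-uncertainty
correction, monitored on the restricted log-likelihood (tolerance 1e-8,
max 500 iterations, restart from an inflated diagonal on failure, and a
compound-symmetry refit — flagged as downgraded — as last resort).
Participants with missing occasions contribute their observed
sub-vector with the corresponding sub-covariance. The implementation is
validated against `nlme::gls` with `corSymm` + `varIdent` (agreement to
~1e-6 on the exposure coefficient and its SE) and reduces to OLS when
the true covariance is the identity. The tested coefficient is the
exposure main effect by default; an exposure × post-walk interaction
mode is available (`effectMode = "postInteraction"`) since the model
statement leaves the interaction question open — the crossover contrast
is carried by the covariance structure either way.

Wald p-values use the standard-normal reference (a t reference is
available; the difference is negligible at 300 observations), with
strict inequality at every significance threshold.

**Multiple testing.** The effective number of tests (ENT) is the
smallest number of principal components of the standardized feature
matrix explaining strictly more than 99% of variance — a spectral
alternative to permutation-based ENT. Two Bonferroni flags are reported:
`fwer/ENT` and `fwer/nFeatures`, the latter always at least as
stringent.

## A known limitation of plug-in Wald inference

The Wald SE treats the REML covariance estimate as known. With 21 free
covariance parameters estimated from 100 participants, the null Wald
statistic is measurably overdispersed (SD ≈ 1.065 in our global-null
simulations, versus 0.99 for the 3-parameter compound-symmetry
submodel), which inflates far-tail rejection rates: at Bonferroni-scale
thresholds the realized family-wise error is roughly two to three times
nominal (≈ 0.1–0.17 instead of 0.05 in the acceptance suite's
global-null simulation, for any strength of feature correlation). This
is a property of plug-in GLS inference itself — reference
implementations of the same model produce identical estimates and SEs —
and it shrinks as the number of participants grows. A
Kenward–Roger-type SE correction or parametric-bootstrap calibration
would temper it; neither is part of the method implemented here, and
the acceptance suite reports the inflation as measured rather than
masking it.

# Consensus clustering

Exposure-associated features are often redundant ions of the same
compound. `consensusCluster()` runs hierarchical clustering (Ward
linkage on 1 − |Pearson r|; chosen for determinism per subsample, with
the distance and linkage being pluggable in principle) on 500 random 80%
subsamples of the samples for each candidate number of clusters G,
accumulates pairwise comembership proportions, and calibrates (G, π)
jointly by the same binomial-null stability score used for networks,
applied to comembership counts. The final partition cuts the
comembership graph at the calibrated threshold and takes connected
components; if fewer than G components result, components are split at
their weakest comemberships by average-linkage agglomeration until G
clusters exist. Each cluster is represented by its **medoid** — the
member with the highest summed |correlation| to its co-members, ties
broken to the lowest feature index. A retention-time coherence report
(`clusterRtCoherence()`) is provided for inspection, not assertion.

# Stability-calibrated graphical LASSO networks

Conditional-independence structure is estimated by the graphical LASSO:

$$\hat\Theta = \arg\max_\Theta \; \log\det\Theta - \mathrm{tr}(S\Theta)
  - \sum_{j \ne k} \lambda_{jk} |\Theta_{jk}|,$$

solved by block coordinate descent over columns with cyclic
coordinate-descent lasso subproblems (compiled code). The input is the
correlation matrix; the diagonal is unpenalized. Solutions satisfy the
subgradient conditions to 1e-5 and match proximal-gradient and direct-
inversion oracles.

**Stability calibration** (`stabilityNetwork()`): the glasso is run on
K = 500 subsamples (80%, drawn without replacement; the resampling unit
is the participant, since profiles of one person are dependent) for 25
log-spaced penalties from $\lambda_{max}$ (the smallest penalty giving
an empty graph) down to 0.01 $\lambda_{max}$. Each edge's selection
proportion is compared against an exchangeable binomial null
$B \sim \mathrm{Bin}(K, q)$, $q$ the average selection probability at
that penalty: stably selected edges contribute
$\log P(B \ge \lceil K\pi\rceil)$, stably excluded ones
$\log P(B \le \lfloor K(1-\pi)\rfloor)$, the rest the middle-range
log-probability, and the score is minus the sum. The penalty and the
threshold $\pi \in (0.51, 0.99)$ are calibrated jointly by maximizing
the score. The middle-range probability is computed from whichever
binomial tail avoids catastrophic cancellation — the naive difference of
CDFs underflows to zero for extreme $q$ and silently corrupts the
calibration. The scoring interface is pluggable so alternative
calibration criteria can be swapped in.

**Multiomic networks** (`multiblockNetwork()`): with two blocks
(metabolite-cluster medoids and gene-mapped transcripts) three penalty
groups — within-block 1, within-block 2, cross-block — enter the same
objective elementwise; all combinations of the per-group grids are
calibrated jointly with π by the summed score. A coupled-grid mode
(`expand = FALSE`) ties the groups to one penalty axis and reduces
exactly to the single-block estimator when the grids coincide. Networks
are estimated separately at the three occasions on denoised, imputed,
per-feature standardized data (both sites pooled within occasion), and
`compareNetworks()` classifies each edge across
before / +2 h / +24 h as stable, baseline-only, acute, persistent,
lagged, attenuated (present before and at +2 h only) or recurrent
(present before and at +24 h — patterns reverting to their
pre-exposure state). The last two names cover presence patterns the
primary five-class scheme leaves out.

## A known limitation of score-based calibration

On data whose true conditional-independence graph is empty, any finite
dataset still contains a few chance correlations that the glasso selects
in nearly every subsample at moderate penalties. Because each stably
selected edge adds its own positive term to the score, configurations
with many such edges can outscore the near-empty solutions at strong
penalties, and the calibrated network then retains spurious edges (we
observe 15–35 at p = 20 for n between 50 and 300). Subsampling measures
the *stability* of selection, not its *validity*: an edge driven by a
persistent chance correlation in the one observed dataset is stable. A
per-family error-rate constraint on the admissible (λ, π) region would
temper this, but is deliberately not part of the calibration implemented
here; the acceptance suite reports the empty-graph behaviour as
measured.

# Annotation and over-representation

`matchMz()` annotates feature m/z values against a user-supplied
reference mass list using the positive-mode adducts [M+H]+ (+1.007276
Da), [M−H2O+H]+ (−17.003289 Da) and [M+Na]+ (+22.989218 Da) at an
inclusive ±8 ppm tolerance, returning all candidates ordered by |ppm
error|. `oraFisher()` computes one-sided Fisher exact
over-representation p-values per pathway over the assayed universe —
identical to the hypergeometric survival function at overlap − 1.
Per-pollutant p-value thresholds for building the selected set (0.05
for PM10/PM2.5, 0.01 for BC/PCNT, 0.005 for NO2) are exposed via
`oraThresholds()`. Curated pathway databases and permutation-based
enrichment are out of scope: the reference masses and pathway maps are
user-supplied, and `generateReferenceSet()` builds clearly-labelled
synthetic ones for testing.

# Numerical choices and problem sizes

* Glasso convergence: mean absolute change of the working covariance
  below `tol` (1e-6) × mean |off-diagonal of S|; inner lasso at a tenth
  of that.
* REML: EM on the restricted log-likelihood, tolerance 1e-8; the
  compound-symmetry submodel is fitted by Nelder–Mead on
  (log σ², logit ρ).
* Strict inequalities at all significance and tolerance thresholds;
  ties in medoid selection break to the lowest feature index.
* The test and acceptance suites run at sizes chosen to make the
  statistical properties visible while staying desk-scale: 200
  replicates for error-rate and coverage checks, K = 100 subsamples and
  p = 20 nodes for network recovery, 500 subsamples for consensus
  clustering, n = 500 for imputation recovery. K = 500 is the
  method-faithful default for real analyses.

# Worked example

```{r example, eval = FALSE}
sim <- simulateStudy(nParticipants = 20, nFeatures = 60, seed = 1)
os  <- filterMissingness(sim$omics)
os  <- imputeQRILC(log2Transform(os), seed = 1)
os  <- denoiseTechnical(os[, !flagPCAOutliers(os)])
res <- associateExposures(os, sim$exposures, pollutants = "NO2")
associationSummary(res)
```

The `runPipeline()` vignette-level entry point performs the same chain,
adds clustering, per-occasion networks and enrichment, and writes every
table with a manifest of all resolved parameters so a run can be
reproduced bit-identically from its seed.
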