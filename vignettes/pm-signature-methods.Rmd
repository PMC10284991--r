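---
title: "Methods: discovering a peritoneal-metastasis risk signature from paired proteomes"
author: "pmsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering a peritoneal-metastasis risk signature from paired proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmsig)
```

## The problem

Peritoneal metastasis (PM) is the dominant failure mode of advanced gastric
cancer. A recurring study design asks whether the primary tumour's proteome
already carries a PM-propensity signal: a small cohort of patients with and
without PM contributes paired tumour and adjacent-normal tissue, quantified by
multiplexed (TMT-style) mass spectrometry, and a weighted protein panel is
derived that predicts PM status and stratifies survival. `pmsig` implements
that discovery procedure as a single fitting function,
`fit_pm_signature()`, with the stages exposed as ordinary functions.

This vignette records the model, its assumptions, the tunable parameters, and
the design decisions taken where the procedure is underdetermined — together
with what the synthetic world does and does not establish.

## Preprocessing

Raw intensities are normalized per sample to **fraction of total**
(`fot_normalize()`): $\mathrm{FOT}_{ps} = x_{ps} / \sum_p x_{ps}$, removing
per-sample loading differences. Proteins are retained when identified by at
least 2 unique peptides **and** quantified above FOT $10^{-5}$ in at least one
sample (`filter_proteins()`); the "any sample" reading keeps proteins that are
reliably measured anywhere, which matches the filter's purpose of removing
never-well-quantified identifications. `log2_zscore()` then takes
$\log_2(\max(\mathrm{FOT}, \text{floor}))$ with floor $10^{-8}$ (FOT zeros are
otherwise unloggable; the floor is configurable) and standardizes **each
sample column** to mean 0, SD 1. Scaling by each subject-sample's own SD is
the default orientation; a per-protein alternative is available
(`by = "protein"`) since the phrase "scaled by subjects' SD" admits both
readings. The normalization state is carried on the matrix and the order
raw → FOT → filter → z-score is enforced.

## Differential proteins: two tests, intersected

**Test (a)** (`sam_test()`) is a SAM-style moderated test. For protein $p$,
$d_p = r_p / (s_p + s_0)$, with $r_p$ the paired mean difference (or the
unpaired group difference) and $s_p$ its standard error. The fudge constant
$s_0$ is chosen Tusher-style: among percentiles $\{0, 5, \dots, 95\}$ of the
$s_p$ distribution, the value minimizing the coefficient of variation of the
MAD of $d$ across five $s$-quantile bins. The null is built from label
permutations — sign flips of the paired differences, or group-label
permutations — enumerated exhaustively whenever the number of distinct
permutations is within `n_perm` (default 100), otherwise sampled with a fixed
seed. At a symmetric cutoff $\Delta$ the estimated FDR is
$\pi_0 \cdot \mathrm{median}_b |\{p : |d^{(b)}_p| \ge \Delta\}| / |\{p :
|d_p| \ge \Delta\}|$ with $\pi_0 = 1$ (conservative; configurable). The
smallest $\Delta$ with estimated FDR at or below the target (0.05) is used;
if none qualifies, nothing is called. A protein's q-value is the minimum
estimated FDR over all cutoffs at which it would be called. Calls must also
pass the linear fold-change threshold (1.5). Fold changes are computed on the
log2 FOT scale (`fc_matrix`), where a ratio is meaningful — a fold change of
z-scores is not.

**Test (b)** (`pairfc_test()`) follows the per-pair fold-change idea: for
each tumour/normal pair the distribution of per-protein log2 fold changes is
fit by a location–scale t (location = median, scale = 1.4826·MAD), and each
protein receives $p = 2(1 - F_t(|lfc - \hat\mu| / \hat\sigma))$. The degrees
of freedom default to a profile-likelihood fit over a grid
(1–100, `df = "ml"`); a fixed heavy-tailed choice such as $\nu = 4$ is
supported but measurably less sensitive when the fold-change distribution is
close to Gaussian — on the synthetic world the fixed-$\nu$ critical value
($|z| > 2.78$) sits above most planted effects and halves downstream
recovery, which is why the fitted default was adopted. A protein is called
when its significant pairs (p < 0.05) all agree in sign and make up at least
`min_frac` (default 0.5) of the pairs; requiring *all* significant pairs to
agree implements the direction-consistency aggregation strictly.

The **final differential set** is the intersection of (a) and (b)
(`overlap_deps()`). A second-level unpaired run of test (a) between PM and
PM-free tumours, restricted to that set (`group_dep()`), yields the
PM-associated differential proteins.

## Module selection by signal-to-noise

Each PM-associated protein is represented by a three-number profile: its mean
z-expression in PM tumours, PM-free tumours, and normals. Profiles are
clustered by seeded k-means (`cluster_deps()`). The module count defaults to
`k = "auto"`: the Tibshirani gap statistic against a uniform reference in the
PCA-aligned bounding box (25 references, one-standard-error rule), with
$k = 1$ a first-class outcome. This matters: when the second-level
differential set is already one coherent co-expression program, a fixed
$k = 8$ would shred it into arbitrary fragments and the subsequent
highest-SNR selection would keep only a fragment. A fixed numeric `k` remains
available.

Module SNR is the mean over member proteins of
$|\mu_{PM} - \mu_{PMfree}| / (\sigma_{PM} + \sigma_{PMfree} + \varepsilon)$,
$\varepsilon = 10^{-8}$ (`module_snr()`; median aggregation available). The
module with the highest SNR is the PM-associated module, ties going to the
smaller index. `external_filter()` then keeps members whose two-sample Welch
test in an external transcriptome cohort is significant (p < 0.05) with a
mean-difference sign matching the proteomic direction — an invented but
conventional concordance criterion, since "used for filtering" is all that is
stated in this literature.

## Panel selection by cross-validated AUC

Combinations of pool proteins with sizes 3–10 are scored by mean AUC under
stratified five-fold cross-validation (`cv_auc()`), all combinations sharing
one seeded fold split. Below the budget (default 200,000 at the function
level) enumeration is exhaustive; above it, the budget's worth of distinct
combinations is sampled uniformly, and the mode is recorded. The pipeline
default budget is 2,000: a ~20-protein pool over sizes 3–10 spans roughly
4×10⁵ combinations and exhaustively cross-validating them is hours of
compute for no inferential gain in this setting — the budget is a runtime
knob, not a statistical threshold.

Two classifier backends are provided. `"gbtree"` is a gradient-boosted
decision-stump ensemble (logistic loss, shrinkage 0.3, L2 leaf penalty, 50
rounds, no subsampling — deterministic). `"logistic"` is ridge-penalized
logistic regression fit by IRLS, the convergence target of an additive linear
booster with L2 shrinkage; it is the fully deterministic backend used in
continuous testing and in the acceptance runs. At $n = 20$ with a strong
planted module both backends saturate near AUC 1; the choice matters on real,
noisier cohorts.

`best_panel_size()` implements the nested-prefix pool sizing (rank by
importance from a full fit, score prefixes of increasing size, keep the best,
ties to the smaller size). On a near-separable cohort the prefix curve
saturates at 1.0 immediately and the tie rule collapses the prefix to one
protein, so the pipeline enumerates over the **full filtered pool** (the
documented default pool definition) and reports the prefix search as a
diagnostic.

`frequency_select()` sorts scored combinations by mean CV AUC (ties: smaller
combination, then lexicographic), keeps the top 500, counts each protein's
frequency among them, and returns the 10 most frequent proteins (ties: larger
marginal univariate AUC distance, then lexicographic). All tie-breaking rules
are package conventions, stated here because the procedure itself fixes none.

## PM risk score and stratification

`fit_weights()` fits ridge-penalized logistic regression of PM status on the
panel's z-scores ($\lambda = 1$ on slopes, intercept unpenalized) and takes
the slopes as weights; the intercept is dropped because the score is used
only for ranking. The PM risk score is the weighted sum
$\mathrm{score}_s = \sum_j w_j z_{js}$ (`pm_risk_score()`). `stratify()` cuts
each evaluation cohort at its own 25th/75th percentiles
(linear-interpolation quantiles): top quartile high risk, bottom quartile
low, middle half moderate. Boundary ties go to the extreme groups; a
degenerate score distribution (coincident quartiles) is an error rather than
a silent collapse. Cutpoints are recomputed per cohort by default — matching
how external cohorts are stratified in this literature — with a
fixed-cutpoint mode for applying a trained stratification.

## Survival validation

`validate_signature()` scores and stratifies a cohort, then compares the
extreme strata: Kaplan–Meier curves (Greenwood variance), the log-rank test,
and Cox regression with high-vs-low risk as exposure, optionally adjusted for
covariates (age and ordinal stage by default). The moderate stratum is
excluded from the extreme-quartile comparison by design. Standard estimators
are delegated to the `survival` package with Breslow tie handling (Efron
available); the test suite checks them against hand-computed product-limit
and brute-force partial-likelihood oracles, and calibrates log-rank p-values
against the uniform on null simulations.

## The synthetic world

`simulate_cohort()` generates the stated cohort: 14 PM and 6 PM-free
subjects, one tumour and one paired normal sample each, 2000 proteins.
Per-protein baseline log2 abundance is Normal(25, 3) and every measurement
adds Normal(0, 0.5) technical noise — a log-normal intensity model, standard
for MS intensities, since no abundance model is ever published for such
cohorts. 300 planted differential proteins are shifted in tumours by
0.8–2.0 log2 units with random sign. A 20-protein module (subset of the
differential set) is additionally shifted in PM tumours by
$\delta = \mathrm{SNR} \cdot (\sigma_{PM} + \sigma_{PMfree})$ with target SNR
1.2. Two coherence choices are deliberate: the module's PM shifts share one
direction, and its members' tumour-vs-normal effects share the positive sign
— a "module" in the co-expression sense is a coherently regulated program,
and that coherence is precisely what profile clustering can detect.
Incoherent random-sign sets are not recoverable by any centroid method and
would test nothing but the noise.

Survival is exponential with log-hazard 0.7 per unit of the standardized
planted module score; the planted weights are |w| ~ Uniform(0.5, 1.5) with
signs aligned to the PM direction, so the prognostic signal is the same
signal a PM classifier can learn — with anti-aligned weights the survival
score would be orthogonal to anything the pipeline estimates, by
construction. Censoring is independent Uniform(0, c) with c solved
numerically for a 30% censoring fraction. Unique-peptide counts are
2 + Poisson(4), with 5% of proteins forced to a single peptide to exercise
the filter. The external transcriptome (`simulate_external_transcriptome()`)
carries the module effects shrunk by 0.6 on a unit-noise z-like scale with
balanced labels, 300 samples. The synchronous/metachronous annotation
follows the 13:19 enrolment proportion and is used by no model.

What a green test establishes: the pipeline recovers a planted, coherent,
moderately strong module from a small paired cohort, controls its false
discovery rate on global nulls, and its survival machinery is calibrated.
What it does not establish: behaviour under batch structure, missing values
beyond the abundance floor, correlated background proteins, heavy-tailed
intensity noise, or module structures weaker or less coherent than the
stated world — none of which the generator emulates.

## Numerical conventions

* Permutation nulls switch to exhaustive enumeration whenever the number of
  distinct permutations is within `n_perm`; sampled otherwise, always seeded.
* Zero-variance rows in the moderated statistic yield $d = 0$ when the mean
  difference is 0 (exact-null duplicates), $\pm\infty$ otherwise.
* All stage seeds derive deterministically from one master seed, and every
  randomized routine restores the caller's RNG state.
* `stratify()` uses type-7 (linear interpolation) quantiles; the example
  scores 1..8 give high = {7, 8} and low = {1, 2}.
* Cox fits refuse to return silently unstable estimates (non-convergence or
  near-infinite coefficients raise errors).

## Known limitations

* The internal cohort (n = 20, 5-vs-5 extreme quartiles) is underpowered for
  survival comparisons; the log-rank and Cox validation is designed for
  external cohorts of hundreds of subjects.
* The module-clustering step reimplements the stated contract
  (phenotype-conditioned profiles, SNR ranking) rather than any specific
  published clustering tool's internals.
* "All combinations" of a large pool is combinatorially infeasible; the
  budgeted search is the documented reconstruction, with the enumeration
  mode recorded in every report.
* No batch correction, imputation, enrichment analysis, or immune
  deconvolution; those are outside the signature-discovery contract.
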