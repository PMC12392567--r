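---
title: "Statistical methods behind npxpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind npxpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npxpanel)
```

`npxpanel` implements a complete discovery-and-validation workflow for
cerebrospinal-fluid (CSF) protein biomarker panels measured with targeted
proximity extension assays (PEA). Abundances arrive as NPX — a log2-scale
relative unit in which a difference of 1 corresponds roughly to a 2-fold
concentration change — together with a per-assay limit of detection
(LOD). This vignette describes each stage's model, its assumptions, the
tunable parameters, and the choices made where the design was genuinely
open.

## Preprocessing

**LOD filtering.** Assays whose values fall below their LOD in more than
15% of the analysis samples (`max_below_frac = 0.15`) are excluded. The
rule is strictly "more than": a protein at exactly 15% is retained. QC
aliquots and bridging re-measurements are excluded from the denominator,
so adding them cannot flip a retention decision. Values below LOD in
retained assays are kept exactly as reported — assays are filtered,
values are never masked or imputed, which matches how PEA vendors report
data and avoids fabricating signal near the detection limit.

**Bridging normalization.** When a cohort is measured in several rounds,
a set of bridging aliquots (by default 16, spanning the clinical groups)
is re-measured in every round. For each non-reference round and protein
we subtract the median of (round minus reference) differences over the
shared bridging aliquots. The batch model is deliberately the simplest
one that bridging can provably remove — a per-protein additive constant
per round — and the median (not the mean) keeps the estimate robust at
n = 16. An additive per-protein shift leaves within-round sample ranks
untouched.

**Assay precision.** Intra- and inter-assay coefficients of variation
are computed on the linear scale (`2^NPX`): a CV of log-scale values is
not a coefficient of variation. Intra-CV is the mean of within-plate
CVs; inter-CV is the CV of plate means. The 3-SD-above-background LOD
convention is carried as metadata, not recomputed, because raw
negative-control fluorescence is not modeled.

## Differential abundance

Each protein is tested with a nested linear model: the full model
`NPX ~ group + age + sex` against the reduced model `NPX ~ age + sex`,
compared by the F statistic with one numerator degree of freedom. With
no covariates this is algebraically the squared pooled two-sample t
(verified to 1e-10 in the tests). The reported `beta` is the group
coefficient — a log2 fold-change, oriented disease-minus-reference
(FTD−CON, FTD−AD, AD−CON) to match volcano-plot conventions. Samples
with missing NPX or covariates are dropped per protein (`n_used` records
the fit size); nothing is imputed.

Multiplicity is controlled per contrast with Benjamini–Hochberg q-values
over all tested proteins of that contrast, not pooled across contrasts.
Proteins are then assigned to one of six overlap categories from the
three q-value patterns: FTD-unique, shared-dementia, AD-dominant-shared,
opposite-direction (significant everywhere but with opposite signs in
the two disease-versus-control contrasts), AD-only, or none. The
categories partition the protein set.

Term enrichment of hit lists uses the exact hypergeometric upper tail
against a fixed background (the set of analyzed proteins), with the
conventional retention thresholds p < 0.01, count ≥ 3, and enrichment
factor > 1.5. Clustering of terms by membership similarity is out of
scope; annotation tables are user-supplied.

## Panel selection

Classification signatures are built with elastic-net penalized logistic
regression (via `glmnet`) over a two-dimensional grid: the mixing
parameter alpha in {0.1, …, 1.0}, spanning strong decorrelation to pure
lasso, and a cap on the number of selected markers in {5, 10, 15, 21},
never exceeding 21 (the practical limit for translating a signature into
a small custom assay panel). The grids themselves are configurable; the
defaults above were fixed once, before any evaluation, as a reasonable
coverage of both axes. Age and sex enter every model unpenalized, so
panel AUCs include their contribution.

Within each grid cell the penalty weight lambda is chosen by balanced
(stratified) 10-fold cross-validation of the held-out model likelihood,
restricted to path points whose full-data fit respects the cap. Each
cell is scored by the AUC of its pooled out-of-fold predictions; the
winning cell has the highest AUC, with ties broken by fewer markers and
then by larger alpha (sparser, more decorrelating solutions preferred —
the tie-break order is fixed and documented because only "highest AUC,
fewest markers" is externally constrained). Marker standardization is
redone inside every training fold, so no scaling information leaks into
held-out predictions.

**Stability selection.** The fraction of fold refits (at the winning
cell's lambda) in which each marker receives a nonzero coefficient is
its fold-based selection proportion. Markers at or above the stability
threshold (default 0.9, i.e. near-unanimity across folds) form the final
signature; the full proportion table is always reported. The final
marker set is then re-estimated by ridge-penalized logistic regression
with penalty 0.1 to temper the selection pressure of the manual
filtering step.

**Ridge refit conventions.** The refit minimizes the *average* negative
log-likelihood plus `0.1/2 * ||b||^2` on standardized markers, with the
intercept and covariates unpenalized; the convention (and the training
means/SDs) is stored in the panel object so predictions are exactly
reproducible after serialization. The optimizer is Newton/IRLS with step
halving; it stops when the largest coefficient change falls below 1e-8
or, on separable data where an unpenalized direction has no finite
optimum, when the penalized objective stops changing (relative change
below 1e-13) — the fitted probabilities are then saturated and further
coefficient growth cannot alter any ranking-based metric.

## Internal validation and confidence intervals

Performance is estimated by repeated stratified 5-fold cross-validation,
1000 repeats by default. Each repeat draws a fresh split, refits the
ridge model inside every training fold, and yields one AUC from the
pooled out-of-fold scores; the reported point estimate is the mean of
these per-repeat AUCs. A label-permutation canary (null designs must
score 0.5 ± 0.05) guards the honesty of the scheme.

The 95% interval is the 2.5/97.5 percentile of the *fold-level* AUCs
(folds × repeats values) rather than of the per-repeat pooled AUCs. The
two choices were compared on simulated null cohorts: pooled per-repeat
AUCs vary only through the random split, giving intervals so narrow that
they covered the true null value 0.5 in barely 53–85% of simulations
across a range of sample sizes and marker counts, while fold-level
percentiles cover it essentially always and collapse to (1, 1) on
separable data. Fold-level resampling also produces interval widths
consistent with what this kind of study reports at a few hundred
samples. The full fold-level and repeat-level AUC vectors are both kept
in the `cv_performance` object.

## External validation

A frozen panel scores a new cohort with its stored coefficients and
training standardization; markers missing from the cohort are dropped
together with their coefficients (never imputed — imputation would
fabricate signal), and the AUC receives a stratified-bootstrap
percentile CI (2000 resamples). Because a signature re-measured on a
different assay generation is on a different scale, the default mode
instead *refits* the ridge model within the validation cohort on the
available markers and evaluates it by repeated CV; both modes are
available and the report records which was used. Cross-cohort
reproducibility of effect estimates is summarized by the Spearman
correlation of per-protein log2 fold-changes over common proteins.

## Cross-platform harmonization

Conversion formulas between assay platforms measuring the same analyte
(e.g. two immunoassay generations) are fit with classical Passing–Bablok
regression: the shifted median of all pairwise slopes, with slopes equal
to −1 discarded and the median offset by the count of slopes below −1,
which makes the fit symmetric in the two axes and robust to measurement
error in both. The 95% slope CI uses the rank-based normal approximation
(quantile 1.96); intercept bounds are recomputed at the CI-boundary
slopes. The variant assuming a positive relationship is implemented,
appropriate for two assays of one analyte; Deming regression and the
CUSUM linearity diagnostic are out of scope.

## Clinical-score associations

Associations between panel proteins and clinical scores (MMSE for
global cognition, FTLD-CDR for FTD disease severity) are partial
Spearman correlations: both variables and every covariate column are
rank-transformed (average ranks for ties), the ranked variables are
residualized on the ranked covariates (age, sex, and the dummy-coded
FTLD-CDR rater, one-hot with the first level dropped) by least squares,
and the residuals are correlated; p-values use the t approximation with
n − 2 − k degrees of freedom. The alternative estimator — Pearson on
ranks of raw-scale residuals — was rejected because it is not invariant
to monotone transforms of the covariates. With no covariates the
estimator reduces exactly to plain Spearman. Deletion is listwise per
pair and `n_used` is reported per cell; matrices are computed for the
full cohort and within one diagnostic group.

## The synthetic cohort generator

No raw cohort data are distributable, so the package ships a generator
that emulates the statistical structure the analysis assumes: three
diagnostic groups (CON/FTD/AD, defaults 196/189/232) with FTLD-Tau/TDP
subgroup labels (87/67) inside FTD; 642 proteins of which planted
subsets carry log2 effects in the four overlap categories (36/19/21/7 by
default) plus Tau-/TDP-specific effects (3/2); age confounding (patients
older by 7 years on average, matching the consistent pattern that
controls are younger) and unequal sex ratios; two measurement rounds
with per-protein additive offsets (SD 0.2 NPX — a free parameter, since
the real between-round magnitude is not published) bridged by 16
aliquots; and LOD left-censoring at a configurable marginal quantile,
with below-LOD values retained and the LOD stored separately. The
AD-dominant category plants half the effect in FTD and the full effect
in AD so that all three pairwise contrasts carry signal with a common
sign. Planted effect directions alternate across proteins. Bridging
aliquots are true duplicates: their underlying value is drawn once and
only the round offset differs between their measurements, the setting in
which a per-protein median difference removes the batch effect exactly.

Clinical scores are group-shifted latents; a protein–score link of
chosen rank strength is planted through a Gaussian copula
(`r = 2 sin(pi * rho / 6)` converts the target Spearman coefficient to
the latent Pearson correlation). When a link is requested the score
becomes a pure monotone map of the copula latent, because group-level
score shifts would otherwise dilute the planted rank correlation.

All randomness flows from a single mandatory seed through one named
generator (Mersenne-Twister with inversion normals); identical
configuration and seed give byte-identical cohorts. What the generator
does *not* emulate: vendor-internal plate normalization, genetic
pedigree structure, longitudinal sampling, heavy-tailed or
heteroscedastic residuals, and correlated protein co-expression blocks.
Passing tests on these cohorts therefore demonstrate the correctness and
calibration of the machinery under its stated assumptions, not the
clinical performance of any real panel.

## Problem sizes and numerical choices

The bundled demo configuration (the `run_config()` defaults) uses 60
samples per group, 200 proteins, a 4 × 4 selection grid and 100 CV
repeats, chosen so the complete pipeline runs in seconds while
exercising every stage; the test suite and the acceptance script use
600-protein, 100-per-group cohorts for calibration and recovery checks
and the spec-scale cap grid for selection. Degenerate inputs are
rejected loudly: constant covariates, folds exceeding the minority
class, all-identical x in method comparison, empty marker sets after
stability filtering. Ties are handled by average ranks everywhere a rank
is taken (AUC, Spearman, bridging medians are order statistics). CSV
round-trips write 15 significant digits so written results re-read to
machine precision.

## Known limitations

Variance moderation (empirical-Bayes shrinkage) is deliberately absent —
the differential model is the plain nested F. The enrichment stage stops
at term-level filtering. Multinomial (three-class) signatures, survival
endpoints, prevalence recalibration of intercepts, and meta-analysis
across cohorts are out of scope. The duplicate-assay question (one
protein measured on two PEA panels) is left to the caller: the container
keeps assay-level IDs and exposes a gene-symbol alias map rather than
silently collapsing duplicates.
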