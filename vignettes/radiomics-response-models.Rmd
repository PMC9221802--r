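---
title: "Radiomics models for embolization response: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics models for embolization response: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtae)
```

This vignette is the package's own account of the methods it implements:
the two response-prediction models, the statistics around them, the
synthetic cohort that replaces unavailable patient data, and the design
decisions taken where the methodology left choices open.

## The clinical problem and the data shape

Patients with unifocal HCC treated with transarterial embolization are
assessed at one month with mRECIST; roughly a quarter achieve complete
response and just over half an objective response. The modelling question
is whether pre-treatment MRI radiomics (854 features per phase: first
order, GLCM and other texture families, shape, and wavelet-filtered
variants), 12 clinical variables and 19 LI-RADS qualitative features can
predict these binary endpoints in a cohort of ~51 patients. Two properties
of that setting shape everything here: *p ≫ n* (hundreds of features, tens
of patients), and *strong feature redundancy* (wavelet families are highly
correlated by construction).

## mRECIST classification

`mrecist_classify()` encodes the four categories with precedence
CR > PD > PR > SD: complete response requires the disappearance of
arterial enhancement; progressive disease a ≥ 20% size increase; partial
response a ≥ 30% enhancement decrease; stable disease is residual. The
precedence is a design decision: the criteria define SD residually and do
not state how to classify a lesion whose enhancement falls while its size
grows, so progression dominates — the clinically conservative reading, and
the only deterministic one. Both thresholds are boundary-inclusive.

## Model 1: elastic net + ridge

The penalized stage uses the standard coordinate-descent solver (glmnet)
behind the package's interface. Decisions:

* **α grid `{0.5, 0.6, …, 1.0}`** — only the interval [0.5, 1] is
  specified by the method; a 0.1 step is the coarsest grid that still
  distinguishes LASSO-like from balanced mixing.
* **Stratified 80/20 split** (`split_80_20()`): with prevalence 14/51 an
  unstratified 20% test set is frequently class-degenerate, so test
  allocation is proportional per class with largest-remainder rounding
  (n = 51 → 41 train / 10 test, 3 positive).
* **z-scoring on training statistics only**, applied unchanged to the test
  set: penalties are scale-sensitive and any use of test statistics would
  leak.
* **CV criterion = binomial deviance**, not AUC: the smoother, standard
  criterion for penalized logistic paths; folds are stratified and shared
  across the α grid so the comparison is paired.
* **Empty-selection fallback**: the elastic net is preferred to the LASSO
  precisely to reduce the chance of selecting zero features; if the
  CV-optimal λ still selects none, the next smaller λ on the path with a
  non-empty active set is used, with a warning.

## Model 2: hybrid descriptive-inferential selection + LDA

The selection cycle (`hybrid_select()`) ranks features by |r_pb| and adds
them one at a time to a logistic regression, stopping as soon as "the
p-value" fails to decrease. The method description does not pin down which
p-value; the package interprets it as the **1-df likelihood-ratio test of
the current model against the previous iteration's model** (for the first
feature, against the intercept-only model). This is well defined at every
iteration, matches "compared with the previous iteration", and makes the
retained prefix's p-trajectory strictly decreasing by construction. The
Wald p-value of the newly added coefficient is implemented behind
`p_method = "wald"` as the plausible alternative reading.

Further decisions:

* **Ties in |r_pb|** break by ascending original column order, so the
  ranking is a deterministic permutation and column-order permutations of
  the input yield the same retained set.
* **Constant features** get r_pb = 0 and sink to the bottom rather than
  erroring: real feature tables routinely contain degenerate columns.
* **Separation** (perfect fits during the cycle) is detected by a
  coefficient cap at ±30 on z-scored inputs or a vanishing deviance; the
  fit is flagged, coefficients are capped, and the cycle terminates —
  keeping the loop total on small folds where separation is common.
* **z-scoring before the fits** is for numeric conditioning only; r_pb is
  scale-invariant so the ranking is unaffected.

On pure-noise tables the stopping rule retains a median of ≤ 3 features
over repeated runs (tested) — the overfitting guard this selection is
designed to provide.

The classifier (`lda_fit()`) is a two-class LDA with pooled within-class
covariance (scatter / (n − 2)) and **empirical priors**: the method's
stated rationale for LDA is robustness to the 14-vs-37 imbalance, and
empirical priors carry that imbalance into the decision rule rather than
erasing it. Singular covariances (duplicated or constant columns) receive
a diagonal ridge of `1e-6 · trace/d`, flagged. Cross-validation
(`stratified_kfold()`) builds disjoint folds whose sizes differ by at most
one and whose per-fold positive counts follow proportional allocation ±1
(51 patients, 14 positives, k = 5 → sizes 11,10,10,10,10; positives
3,3,3,3,2). Selection runs inside each training fold only; the permuted-
label null centering at AUC 0.5 is the no-leakage test. Fold-averaged
metrics are the arithmetic mean over folds (the literal reading of
"performance averaged"); the pooled out-of-fold AUC is also reported,
since a single cross-validated ROC is the other common convention.
The per-fold operating threshold is chosen by Youden's index **on the
fold's training scores** — the threshold rule is otherwise unstated.

## Evaluation

AUC is computed as the pairwise concordance probability with ties counted
½ (rank formula). Confidence intervals default to **DeLong** placements —
the standard for single-cohort AUC CIs — with a stratified percentile
bootstrap as the alternative; the p-value against AUC = 0.5 uses the
DeLong standard error. Degenerate cases (perfect separation: zero DeLong
variance) collapse the CI to the point estimate and are flagged rather
than producing NaN. The operating point maximizes Youden's J over all
observed thresholds with ties broken toward the lower threshold (higher
sensitivity), matching the convention of reporting the most sensitive of
equally good operating points.

## Cohort statistics

Fisher's exact test uses the two-sided point-probability rule (sum of all
fixed-margin tables whose probability does not exceed the observed one, up
to a 1e-7 relative tolerance) — the convention that reproduces the
printed baseline-table p-values; a zero-margin table returns p = 1.
Pearson's χ² applies no continuity correction and refuses tables with a
zero expected cell. `compare_groups()` routes categorical variables to
Fisher whenever any expected cell is below 5, else χ²; re-testing the
printed contingency counts shipped in `inst/extdata/tables_1_2_counts.csv`
with that router reproduces 40 of the 42 printed p-values to three
decimals (one printed value appears to be a rounding slip of the exact
Fisher value, and one row prints the Fisher value where the router picks
χ² — the per-row test choice was never published). The Mann–Whitney U test
is exact for small untied samples and uses the tie-corrected normal
approximation (no continuity correction) otherwise.

## The synthetic cohort

`generate_feature_table()` emulates the *statistical* structure the
pipelines assume, not the images themselves:

* **Equicorrelated Gaussian blocks** (default block size 8, ρ = 0.6):
  features are unit-variance Gaussians correlated within consecutive
  blocks and independent across blocks. This stands in for wavelet-family
  redundancy — the property the elastic net's grouping and the
  decorrelation step exist to handle. ρ = 0.6 is a typical within-family
  radiomics correlation; it is configurable but deliberately not tuned.
* **Planted effects**: a planted feature's class-conditional means differ
  by δ pooled standard deviations, so its population AUC has the closed
  form Φ(δ/√2) — the calibration the tests check (δ = 2 → 0.921).
* **Exact prevalence**: positives are placed by exact count
  (`round(prevalence · n)`), not Bernoulli draws, so the reference rates
  14/51 and 29/51 are exact; mRECIST categories are allocated consistently
  with the binary endpoint using the reference category mix (14:15:19:3).
* **Clinical/LI-RADS tables**: continuous labs are log-normal
  (strictly positive and right-skewed, as platelet count and AFP are),
  parameterized by target median and IQR; binary features are Bernoulli at
  configurable rates matched to the reference cohort's frequencies.
  The generator emits both continuous and categorical columns and leaves
  encoding to the modelling layer (`build_design_matrix()` dummy-codes
  categoricals), since no coding scheme was published.
* **Lesion volumes**: ellipsoidal masks with mean + smoothed Gaussian
  noise interiors, enough to exercise the extractor end to end (mask
  calibration against the analytic ball volume is tested).

What it does **not** emulate: scanner- or vendor-specific intensity
distributions, inter-phase correlation of the same patient's features,
non-Gaussian radiomics marginals, segmentation variability, or any real
association between clinical covariates and outcome. Passing tests
therefore demonstrate the *pipelines'* correctness and calibration on
data with known structure — not clinical performance on real cohorts, and
the published per-phase AUCs of the original 51-patient cohort are
explicitly not reproducible without that data.

## Radiomics extraction scope

The extractor implements a bounded, documented subset: 18 first-order
features (population moments; histogram entropy/uniformity in base-2 bits
on the discretized levels), 14 GLCM features from symmetrized,
per-direction-normalized co-occurrence matrices averaged over the 13
unique 3D directions at distance 1 (the common default behavior of
standard radiomics tooling), 4 shape features (voxel volume, exposed-face
surface area, sphericity, center-to-center maximum 3D diameter), and
re-extraction on the 8 sub-bands of a single-level orthonormal 3D Haar
transform (odd dimensions edge-replicated to even; Parseval equality and
exact inversion are tested). Discretization defaults to a fixed bin width
of 25 intensity units — a common radiomics default, configurable because
no setting was published. GLDM/GLRLM/GLZLM/NGTDM families, multi-level
wavelets, resampling of anisotropic volumes, and numerical parity with any
specific extraction software are out of scope; the exposed-face surface
area overestimates smooth surfaces (digitized-ball sphericity plateaus
near 2/3), which is acceptable and documented for a subset extractor.
Undefined values (skewness/kurtosis of constant regions, GLCM correlation
with zero variance, fewer than two voxel pairs) are returned as flagged
`NA`, never as propagating NaN.

## Numerical choices and problem sizes

Logistic fits use IRLS via `glm` with the ±30 coefficient cap above;
likelihood-ratio p-values come from the χ² upper tail of the deviance
drop. Elastic-net oracle agreement is verified against a generic numeric
optimizer at fixed (α, λ) to 1e-6 on the objective; GLCM against
brute-force pair enumeration to 1e-10; LDA posteriors against a
from-densities Gaussian Bayes oracle to 1e-8; Fisher against exhaustive
fixed-margin enumeration to 1e-10. The test and acceptance workloads use
n = 5000 for the single-feature AUC calibration (Monte-Carlo error well
below the 0.02 tolerance), n = 300 cohorts with 100 radiomics features for
pipeline recovery, and n = 200 with 20 permuted-label replicates for the
no-leakage null — sizes chosen so every check is decisive yet the whole
suite runs in well under a minute per module on one core.

## Known limitations

* The sequential stopping rule tests one nested comparison per step; it is
  a greedy heuristic, not a multiplicity-controlled procedure (the
  original method applies no multiple-testing correction either).
* DeLong intervals are asymptotic; at 10-patient test sets (the 20% split
  of 51) they are wide and can clamp at the [0, 1] bounds, which is
  faithful to how such tables look at this cohort size.
* LDA assumes shared-covariance Gaussian classes; with one or two selected
  features this is mild, but the package deliberately does not offer
  quadratic DA (out of scope).
* The generator's independence across blocks and phases means multi-phase
  analyses on synthetic data overstate the information gain from adding
  phases.
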