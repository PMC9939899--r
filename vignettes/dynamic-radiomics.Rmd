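---
title: "Dynamic radiomics of multi-phase CT: models, defaults and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic radiomics of multi-phase CT: models, defaults and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynradiomics)
```

## The problem and the model

Contrast-enhanced abdominal CT acquires the same liver lesion at four
vascular phases: precontrast (PP), arterial (AP, ~30–35 s post injection),
portal venous (PVP, ~60–75 s) and delayed (DP, ~100–120 s). A lesion's
enhancement trajectory across these phases is a surrogate of its
vascularity, which is what antiangiogenic therapy targets. Conventional
radiomics summarises a single phase; this package instead converts each
static feature's *phase series* f₁,…,f_k into dynamic features:

* **SD** — mean absolute deviation (1/k)·Σ|fᵢ − f̄|: how much the feature
  moves at all;
* **DC** — SD divided by |f̄|: the same, made scale-free;
* **RCR** — |fⱼ − fᵢ|/|fᵢ| for every ordered pair j < i: pairwise relative
  change rates (6 values for k = 4);
* **RACR** — |fⱼ − fᵢ|/|f̄|: pairwise changes relative to the series mean;
* **P** — coefficients of an ordinary least-squares polynomial fit of fᵢ on
  the phase times.

Three conventions deserve a note, because the defining formulas are
ambiguous at the edges:

1. **Pair range.** The pairwise definitions formally include j = i, which is
   identically zero; only j < i is emitted (zero columns would be removed by
   `drop_constant_features()` anyway).
2. **Denominators.** Radiomics features can be negative (skewness, cluster
   shade), so all denominators are taken in absolute value; RCR divides by
   the *later* phase of the pair as the change-rate definition is written,
   with `rcr_denominator = "earlier"` available since either reading is
   defensible. Denominators under 1e-12 in magnitude yield 0 and a flag in
   the column metadata rather than Inf/NaN, keeping matrices finite for
   selection.
3. **Series mean.** f̄ is the arithmetic mean of the feature values across
   phases (not the feature of a mean image — the alternative reading would
   require voxel-wise registration across phases, which the data model does
   not assume).
4. **Polynomial degree and times.** The P transform defaults to degree
   k − 1 = 3 (4 coefficients for 4 phases; a saturated fit, so the value is
   in the coefficients, not the residual). Phase times default to ordinal
   1..k; a nominal-seconds mode (0, 32.5, 67.5, 110 — midpoints of the
   acquisition windows) is available via `pipeline_config(times = "seconds")`.
   SD/DC/RCR/RACR are time-agnostic.

## Static extraction

`extract_static_features()` implements a compact extractor: 17 first-order
intensity statistics, 7 shape descriptors and 11 grey-level co-occurrence
(GLCM) texture features. Preprocessing mirrors common radiomics practice:
whole-volume z-normalisation scaled by 100 and shifted by 1000, resampling
to 1 mm isotropic spacing (trilinear for the image, nearest-neighbour with
re-binarisation for the mask), and fixed-bin-width discretisation
(`level = floor((v − min)/25) + 1`, anchored at the ROI minimum). GLCMs use
the 13 unique 3-D directions at distance 1, symmetric accumulation, features
averaged over directions. Single-voxel ROIs produce NaN shape/GLCM features
carrying an explanatory flag instead of silent zeros.

Richer families (run-length, size-zone, wavelet-filtered features and so on)
are deliberately not re-implemented: the package's contribution is the
dynamic construction, which is agnostic to where static features come from.
Tables from any external extractor enter through `read_feature_csv()`
(long CSV: `patient_id`, `phase`, one numeric column per feature), and the
dynamic, selection, response and survival stages operate on them unchanged.
Images and masks are read from NRRD (ascii or raw little-endian encodings);
there is no DICOM reader in this package.

## The synthetic cohort generator

Because no public cohort accompanies this design, `simulate_feature_cohort()`
generates one with the statistical structure the analysis assumes. Each
feature value is

f(patient i, feature f, phase p) = s_f · B_if · e_g(i)(p) · exp(ε),

with `s_f` a per-feature scale spanning ~5 orders of magnitude (log-uniform,
as real radiomics features do), `B_if` a per-(patient, feature) log-normal
level factor **constant across phases**, `e_g` the group enhancement curve
and ε ~ N(0, noise_sd²) per phase. Responders get a brisk-arterial/washout
curve, non-responders a flat accumulating one; at `effect_size = 0` the
curves coincide and the cohort is null.

Two design points matter:

* **Why level signal is damped rather than removed.** One might wish the two
  group curves matched per phase, so that single-phase levels carry *no*
  signal. In a multiplicative model that is impossible: matching
  E[f | group, p] for every p forces the curves to be proportional, which
  also equalises every phase ratio — removing the dynamic signal too (we
  verified this empirically; an exactly mean-corrected variant has no signal
  of any kind). The curves are therefore matched on their *across-phase
  mean*, and the level factor `B_if` (default sd 1.5 on the log scale) damps
  the residual per-phase signal: ratios cancel `B_if` exactly, single-phase
  levels drown in it.
* **Why the level factor is feature-wise independent.** A factor shared by
  all features of a patient would make every null column's t statistic hinge
  on one latent draw, so the ~5% null rejection rate would not hold within a
  cohort. Independence across features restores column-wise calibration
  while leaving each column's marginal distribution unchanged.

PFS is Weibull (default shape 1.3, scale 300 days) under proportional
hazards with log-hazard `pfs_coef` (default 1) per SD of the realised
kinetic signal — the standardised mean log(delayed/arterial) contrast of the
informative features, i.e. delayed accumulation is progression-prone.
Censoring is independent uniform; the upper bound is set at the empirical
quantile that hits the target `censor_rate` (default 0.2) exactly, which
keeps cohorts deterministic given the seed. Clinical covariates (age, sex,
site, CEA, AFP, tumor size) are simulated independent of outcome, consistent
with a baseline table in which no covariate separates the groups.

Defaults follow the motivating study design where one exists (n = 76,
OR fraction 33/76, four phases); noise scales (`noise_sd = 0.2`,
`patient_sd = 1.5`) are the implementer's choices of realistic values and
are documented here rather than claimed to be data-derived. What passing
tests on this generator show is that the *pipeline* behaves correctly —
recovery under a known signal, calibration under none; they cannot show
that real lesions carry such signal.

`simulate_phantom_images()` complements this at the voxel level: an
ellipsoidal lesion on a uniform liver background whose ROI mean follows a
configured enhancement curve, for exercising the image path end to end.

## Selection, evaluation and the leakage switch

Screening follows two stages in order: a two-sided Welch t-test per column
(keep p ≤ 0.05; zero-variance columns get p = 0 when means differ and p = 1
otherwise, logged) and then a binomial LASSO on standardised columns, λ
chosen at the deviance minimum of a seed-fixed stratified 5-fold inner CV.
No multiplicity correction is applied at the t stage — it is a screen, not an
inference. If the t stage leaves fewer than two columns the two smallest
p-values are passed on; if the LASSO shrinks everything to zero the single
strongest t-test feature is used, with a warning.

`loocv_evaluate()` pools one held-out score per patient into a single ROC.
The critical design choice is *where selection runs*:

* `onepass = FALSE` (default): selection is refit inside every training
  fold — the leakage-free estimate;
* `onepass = TRUE`: selection runs once on the full data before
  cross-validation, a common but optimistic shortcut.

On null cohorts the nested mode concentrates near AUC 0.5 while the one-pass
mode is strongly inflated (the acceptance suite asserts the direction of the
gap, about +0.4 AUC at n = 60 with 300 candidate columns). Both modes are
provided because published workflows are often ambiguous about which was
used; no claim is made about any particular study.

Classifier conventions (hyperparameters deliberately unremarkable): LDA with
a shrinkage fallback when the pooled covariance is singular; linear SVM,
cost 1, decision values as scores; random forest, 500 trees, √p features per
split, probability scores; accuracy thresholds 0.5 on probabilities, 0 on
margins. `compare_feature_sets()` arranges AUC/accuracy grids with rows
RACR, RCR, SD, DC, P, AP, DP, PP, PVP, Multi_static (the concatenation of
all four phases' static features).

## The survival workflow

`pfs_pipeline()` composes: univariate Cox screen (Efron ties, Wald p < 0.05;
constant or non-convergent features flagged and excluded) → random survival
forest risk score → median split → Kaplan–Meier, log-rank, time-dependent
ROC at 90/180/270/360 days.

The forest (via `ranger`, log-rank splitting, 500 trees, √p candidates per
split, minimum node size 3) scores each patient by the ensemble cumulative
hazard *summed over the event-time grid* — the usual mortality measure. The
terminal CHF value alone is not a usable score: without censoring a leaf's
final Nelson–Aalen value reflects leaf size, not when hazard accrues (we
measured concordance ≈ 0.4 on a strong signal using it, ≈ 0.89 with the
summed measure). With `loocv = TRUE` (default) each patient is scored by a
forest grown without them, and fold CHFs are evaluated on the common
full-data event-time grid so scores are comparable across folds. Median-split
ties go to the low-risk group, deterministically.

`td_roc()` implements the cumulative-case / dynamic-control AUC(t) with
Kaplan–Meier weighting: cases have events by t, controls are event-free
beyond t, sensitivity/specificity derive from the marginal KM curve and the
conditional KM curves above each score cutpoint, and the area is taken by
trapezoid along the cut-ordered ROC path. (Re-sorting the path by FP/TP
values is numerically fragile — float-level ties in the KM values can
re-sequence the staircase and bias the area; traversal in threshold order is
exact.) With no censoring the estimator reduces exactly to the static AUC of
the event-by-t indicator, which the tests assert to 1e-10.

## Baseline tables and exact tests

`fisher_exact_2x2()` enumerates the hypergeometric distribution over tables
with the observed margins; `fisher_exact_rxc()` is the Freeman–Halton
generalisation by complete enumeration (fine for baseline-table sizes). The
two-sided p sums the probabilities of tables no more probable than observed,
with 1e-7 relative slack on the comparison to absorb float noise; zero
margins give p = 1. Both agree with `stats::fisher.test` to enumeration
accuracy, and the enumerated probabilities sum to 1.

`table2_report()` reports, per categorical variable, counts by response
group with *both* the exact Fisher p and the continuity-corrected chi-square
p (plain Pearson above 2×2). The duplication is deliberate: in the
76-patient worked example used by the acceptance suite, the published
baseline table is footnoted as Fisher's exact test, but its printed
p-values (0.323, 0.597, 0.671, 1, 0.629) are reproduced — to all three
printed decimals — by the default chi-square of mainstream software, not by
Fisher's test (which gives 0.253, 0.650, 0.490, 1, 0.610). Reporting both
makes the table reproducible while flagging the mislabel. Tumor size is
continuous and gets Student and Welch t-tests rather than an arbitrary
binning; which test produced any published tumor-size p-value is not
knowable, so none is claimed.

## Problem sizes used by the tests

The test and acceptance suites run at sizes a reviewer can reproduce on a
laptop core: transform oracles on 100 random series; GLCM oracles on 50
random ROIs up to 6³; null calibration at n = 60 with 300 dynamic columns
over 20 seeds; signal recovery at n = 80 with 200 base features over 10
seeds (median RCR AUC must beat every single-phase static set by ≥ 0.10
under LDA); Cox recovery at n = 300 uncensored (median of 5 replicates
within ±0.15 of log-HR 1 — a single draw has SE ≈ 0.12, so a one-draw check
would fail by luck one time in five); strong-signal PFS grouping at n = 100
over 10 seeds with 200-tree forests (log-rank p < 1e-4 required in ≥ 9).

## Known limitations

* The generator emulates multiplicative, log-normal feature noise with
  group-dependent kinetics; it does not model scanner batch effects,
  segmentation variability, inter-feature correlation structure beyond the
  shared level factor, or heavy-tailed outliers. Raw-scale t-tests on
  log-normal features are mildly anti-conservative at these sample sizes —
  the null calibration that matters (LOOCV AUC) is asserted directly.
* The static extractor covers first-order/shape/GLCM only; other families
  must be ingested from external tables.
* No nomograms, calibration curves, multivariable Cox models or competing
  risks; the survival output is the risk score, its grouping and its
  discrimination summaries.
* NRRD support covers the common subset (no gzip encoding, no detached
  headers); DICOM series are out of scope.
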