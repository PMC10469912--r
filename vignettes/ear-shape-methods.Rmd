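---
title: "Methods: ear-shape morphometrics and syndrome classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ear-shape morphometrics and syndrome classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(earmorph)
```

This vignette is the package's account of its statistical machinery: the
models and their assumptions, the parameters that matter, what the synthetic
cohort generator does and does not emulate, the numerical choices, and the
design decisions taken where the methodology left genuine freedom. Every
number quoted here is computed by the test suite or by
`scripts/acceptance.R`; nothing is asserted that the code does not produce.

## The analysis problem

External-ear (pinna) malformations carry diagnostic signal for several
craniofacial syndromes. MFDM ears show a rotated, vertically shifted concha
and an enlarged, squared lobe; CHARGE ears a triangular concha and a reduced
lobe; Nager (NAFD) and Treacher Collins (TC) ears overlap MFDM far more.
Severely microtic ears (Marx grade II and worse) lack the anatomical
structures needed for landmarking, so the pipeline combines *shape* of
landmarkable ears with *ordinal severity and asymmetry scores* that remain
defined when shape is not.

The package starts at 41 named 2D landmarks per ear; the upstream
photograph-processing steps (ear detection, automatic annotation) are out of
scope. The 41-point catalogue (`default_template()`) organises the points
into seven curves — outer helix (12), inner helix (8), lobe (5), tragus (3),
antitragus (3), crus helicis (3), concha (7) — with no antihelix segment:
antihelix points are not reproducible between annotators. The catalogue
itself is an artifact definition: the named regions are anatomically
standard, but the exact per-curve point counts are this package's choice,
since no numeric template is published. Each curve's first and last points
are fixed anatomical anchors; the 27 interior points are sliding
semilandmarks.

## Superimposition

Coordinates are image pixels (x rightward, y downward, 0 at top-left); the
convention is irrelevant downstream because all geometry is
Procrustes-aligned. Left ears are mirrored about the vertical axis into the
right-ear frame *before* any alignment (`reflect_to_reference_side()`), and
the Procrustes machinery itself is strictly rotation-only (determinant +1).
This split matters: an optimizer allowed to reflect would silently erase the
left/right fluctuating-asymmetry signal the clinical asymmetry scale
depends on.

`gpa()` iterates: center and scale every configuration to unit centroid
size, rotate each to the consensus, recompute the consensus (rescaled to
unit size), until the consensus changes by less than 1e-8 (RMS) or 100
iterations. Because photographs are uncalibrated, centroid sizes carry no
information and only shape is analysed.

`slide_semilandmarks()` alternates GPA with tangential sliding. For each
configuration the semilandmarks move along the unit chord between their
curve neighbors; in the default `bending_energy` mode the sliding amounts
solve the reduced linear system `t = -(U'BU)^{-1} U'B (x - xbar)` with `B`
the thin-plate-spline bending-energy matrix of the current consensus, in
`procrustes_distance` mode each point simply takes the tangential component
of its deviation. Three numerical safeguards apply:

* **Chord clamp.** A semilandmark never travels more than 45% of the way to
  either neighbor in one step. Larger moves would leave the curve segment
  the point parameterizes.
* **Monotone safeguard.** The recorded objective is the *state* objective at
  each outer-iteration boundary (the mode's criterion for the current
  configurations against their current consensus). A sliding step whose
  re-superimposed state raises this objective is retried with halved
  amounts (up to five halvings), and the loop stops when no damping
  improves. The objective trace is therefore non-increasing by
  construction — the plain alternation is not guaranteed monotone in
  bending mode, because the consensus and its bending matrix are recomputed
  every iteration.
* **Ridge fallback.** A numerically singular reduced system gets a 1e-10
  ridge with a warning.

Defaults: 5 outer iterations, relative tolerance 1e-6.

## Shape space and covariate adjustment

`shape_pca()` performs PCA of the flattened aligned coordinates and retains
the smallest leading set of components reaching the variance target
(default 0.90). On simulated cohorts at the default effect scale this
retains on the order of 10–30 components depending on cohort size; the
retained count is data-dependent and deliberately not asserted anywhere.
One interaction worth knowing: if the group deformations are made very
large relative to noise (effect scale ≳ 4), the between-group contrast
dominates total variance and the 90% rule keeps only 2–3 components,
truncating exactly the fine contrasts a classifier needs. The separability
harness therefore uses effect scale 2.

For each retained component, `fit_pc_mixed_model()` fits by REML

```
score ~ alpha + beta1 * age + beta2 * gender + b_i * age + eps,
b_i ~ N(0, sigma_b^2),   eps ~ N(0, sigma_eps^2)
```

with patient as the single grouping factor and female as the gender
reference. The equation has a random *slope* only; the option
`random_intercept = TRUE` exists because the prose description of such
models is often ambiguous, but the default implements the slope-only form.
No age-by-gender interaction is included. A boundary fit
(`sigma_b -> 0`) returns a `singular` flag rather than an error.

`residualize()` offers two modes. *Conditional* residuals subtract the
individual's predicted random slope as well as the fixed effects;
*marginal* residuals subtract fixed effects only. Validation patients are
unseen, so their random effects are inestimable and they are always
residualized marginally with training-frozen fixed effects.

**The classifier consumes marginal residuals on both sides.** This is a
deliberate design decision with a concrete reason, found the hard way: on
simulated cohorts, per-individual random slopes absorb a large share of the
*group-level* shape offset during training (for a patient photographed in a
narrow age window, a constant offset is nearly collinear with `b_i * age`).
Conditional training features therefore lose most of the class signal that
marginal validation features retain — the classifier trains and tests on
different feature distributions, and held-out accuracy collapses even for
well-separated groups. With marginal residuals on both sides the age and
gender trends are still removed, and the group signal survives
identically in both cohorts. Conditional residuals remain available (and
default in `adjust_covariates()`) for diagnostics such as the
residual-vs-age checks in the test suite.

## Clinical scores

`severity_score()` is the sum of the two ears' Marx grades (0–8; grades are
coded 0 = normal, 1–4 = Marx I–IV, with 0 and I pooled wherever the
clinical convention pools them). `asymmetry_score()` is the mixed 0–3
scale: `|left - right|` when either ear is grade ≥ II, otherwise the
normalized fluctuating-asymmetry index. The FA index
(`fluctuating_asymmetry_index()`) is the full Procrustes distance between
the mirrored left and the right configuration; `normalize_fa()` divides by
the cohort maximum. The normalization constant is *frozen from the training
cohort* and new values are clipped into [0, 1] — nothing anchors the scale
otherwise. Patients with one unobserved side get missing scores and drop
out of score-using designs.

Between-group score comparisons (`compare_scores_between_groups()`) use a
linear model on group indicators with MFDM as reference, adding a
per-patient random intercept (Satterthwaite t tests) when the caller
passes repeated photo-level rows; patient-level scores (the default, one
row per patient) use plain least squares.

## Classification and evaluation

`train_classifier()` is gradient boosting with multinomial log-loss,
learning rate 0.3, gamma 0, maximum depth 6, up to 500 rounds; stratified
5-fold cross-validation (fold construction seeded in-package) selects the
round with minimal mean CV log-loss, and the final model is refit on all
rows at that round. No class weighting or resampling is applied by default,
mirroring the original design despite strong class imbalance. Severity and
asymmetry scores, when a design includes them, are patient-level features
broadcast to the patient's ear rows.

`evaluation_report()` derives everything from the prediction × reference
confusion matrix: accuracy with the exact Clopper–Pearson interval
(`exact_binomial_ci()`, Beta-quantile form), the one-sided binomial
no-information-rate test (`nir_test()`), and per-class one-vs-all
sensitivity, specificity, balanced accuracy, precision and F1. Two
conventions deserve emphasis:

* **Binary positive class.** The headline Se/Sp pair of a binary design is
  reported for the *alphabetically first* label — for MFDM vs control that
  is "Control", the reverse of clinical intuition, but the orientation
  under which the published binary table (Se 1.000, Sp 0.909) reads
  correctly against its own confusion matrix.
* **Multiclass "balanced accuracy".** The overall multiclass headline
  number is the plain accuracy trace/total (verified cell-by-cell against
  the published tables); per-class balanced accuracy is (Se + Sp)/2.

Displayed values round half-up to 3 decimals (`round_half_up()`); note one
published value (binary balanced accuracy 0.954) truncates 21/22 = 0.9545
rather than rounding it.

One-vs-all AUC uses the rank (Mann–Whitney) formulation with ties counted
one half; a class absent from the references yields `NA` with a warning.
`icc_two_raters()` implements ICC(2,1) — two-way random effects, absolute
agreement, single rater — from the ANOVA mean squares; the variant choice
is the package's own, as none is named in the source methodology.

`umap_embed()` is an in-package implementation of the UMAP algorithm
(exact cosine kNN graph, smooth-kNN bandwidth calibration to log2(k),
probabilistic t-conorm symmetrization, spectral initialization, vectorized
SGD with negative sampling), with the study's visualization settings as
defaults: k = 15, cosine metric, minimum embedded distance 1e-6. It is
written for the moderate cohort sizes of this package (dense distance
matrix, so memory grows quadratically in ears).

## The synthetic cohort generator

`simulate_cohort()` exists so that every downstream stage is testable
without clinical photographs. It emulates, per patient: gender (per-group
female probabilities 53/52/56/40/42%), a baseline age from a truncated
log-normal matched to mean 7.2 and SD 5.9 years, a per-individual random
age slope, per-side Marx grades from per-group distributions whose pooled
grade 0–I mass is 100/92/100/80/100% (control/MFDM/NAFD/TC/CHARGE), MFDM
genotype classes at the observed 11/9/7/4 split, and one to five
photographs at monotonically increasing ages. Per ear, the landmark
configuration is

```
base shape
+ effect_scale * group deformation field
+ (beta_age + b_i) * age * age field
+ male * beta_gender * gender field
+ left * da_offset * directional-asymmetry field
+ per-side fluctuating displacement        (FA, stable across photos)
+ per-photo measurement noise
```

mirrored for left ears, with no landmarks when the ear's grade is ≥ II.
Group sizes default to the training-cohort sizes 471/31/9/15/24 (scalable
with `n_scale`). The group deformation fields encode the described
morphology — MFDM: clockwise concha rotation + downward concha shift +
lobe enlargement + helix thickening; CHARGE: triangular concha + reduced
lobe + thinner helix; NAFD/TC: attenuated MFDM-like fields (0.6× and 0.7×)
with small distinct tragus/crus components so they overlap MFDM more than
CHARGE does. No quantitative effect sizes are published for these
deformations, so the field magnitudes are calibration knobs, not
estimates; `effect_scale` makes separability tunable for power-style
tests. The covariate fields have unit Frobenius norm, which makes the
configured `beta_age`/`beta_gender` *exactly* recoverable by projecting
raw right-frame landmarks onto them — the test suite exploits this for a
calibration-free parameter-recovery check of generator + mixed model
together.

What the generator does **not** emulate: annotation error structure of an
automatic landmarking model (measurement noise is iid Gaussian), ethnicity
or other unmodelled covariates, photograph quality and pose variation,
correlation between grade and residual shape within a group, and any
genotype–phenotype correlation (genotype labels are shape-uninformative by
construction, which is exactly what the design-3 null check needs).
Passing tests on simulated cohorts therefore demonstrate *internal
consistency* of the pipeline under its own assumptions, not performance on
clinical photographs — the published real-data AUCs require the images and
are not reproduced here.

## Problem sizes and harness conditions

The test-suite simulations are sized to exercise every code path at
desk scale: morphometric fuzz suites use cohorts of ~25–30 ears (200
similarity-transform cases, 100 closed-form pairs, 50 sliding cohorts);
mixed-model recovery uses 200 patients × 3 photographs × 100 seeds, with
the random-slope SD checked at ensemble (Monte Carlo) precision because a
single REML fit does not come with an honest standard error for a variance
component; the end-to-end harness uses balanced groups of 40–60 patients
(validation 12–15 per group) at effect scale 2. Balance is intentional:
with the real cohort's 9 NAFD patients (2 in validation), held-out errors
measure class size rather than shape separability — the original study's
own multiclass accuracies (~0.81) reflect that — and the harness is meant
to verify that the pipeline recovers separable classes when they are
genuinely separable. The zero-effect-scale null run checks the complement:
accuracy indistinguishable from the majority rate, and genotype (design 3)
one-vs-all AUC near 1/2 on held-out data. Resubstitution AUC is not used
for the null check because a depth-6 boosted tree partially memorizes noise
even at the CV-selected round.

## Known limitations

* 2D landmarks only; no 3D morphometrics, no centroid-size analysis
  (sizes are unavailable from uncalibrated photographs by design).
* The 41-point catalogue is an artifact convention; results depend on it
  only through the curve structure, but coordinates in it are not
  interchangeable with other templates.
* The UMAP implementation is exact-kNN and dense; it is not intended for
  cohorts beyond a few thousand ears.
* Validation-set residuals are necessarily marginal; any true individual
  effect in new patients stays in their features.
* The FA normalization ties the asymmetry scale to the training cohort's
  maximum; a training cohort with an extreme outlier compresses everyone
  else's index.
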