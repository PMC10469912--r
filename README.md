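# earmorph

Landmark-based analysis of external-ear (pinna) shape for the differential
diagnosis of **Mandibulo-Facial Dysostosis with Microcephaly (MFDM)** against
non-syndromic controls and against its main differential diagnoses — Nager
acro-facial dysostosis (NAFD), Treacher Collins syndrome (TC) and CHARGE
syndrome. The package is written for clinical researchers in dysmorphology
and for methodologists who want a fully testable, simulation-driven
re-implementation of the landmark-onward analysis: photograph handling and
automatic annotation are out of scope, and a synthetic cohort generator
stands in for clinical images.

## What it computes

Starting from 41 named 2D landmarks per ear (seven curves: outer helix,
inner helix, lobe, tragus, antitragus, crus helicis, concha — no antihelix,
whose points are not reproducible between annotators):

1. **Superimposition.** Left ears are mirrored into the right-ear frame,
   then all configurations go through Generalized Procrustes Analysis
   (translation, unit-centroid-size scaling, rotation-only alignment) with
   thin-plate-spline **sliding semilandmarks**: interior curve points slide
   along their neighbor chords to minimize the bending energy of their
   deviation from the consensus.
2. **Shape space.** PCA of the Procrustes coordinates; the smallest set of
   components reaching 90% of shape variance is retained.
3. **Covariate adjustment.** For each retained component *j* and ear
   photograph *i* of a patient, a linear mixed model

   PC<sub>i,j</sub> ~ α + age·β₁ + gender·β₂ + age·β₁,ᵢ + ε<sub>i,j</sub>

   with a per-individual random age slope β₁,ᵢ is fitted by REML; the
   residuals ε are the classifier inputs.
4. **Clinical scores.** Marx microtia grades (0 = normal, I–IV) give a
   patient severity score (sum of both ears' grades, 0–8) and a mixed 0–3
   asymmetry scale: |left − right| grade when either ear is grade ≥ II,
   otherwise a normalized **fluctuating-asymmetry index** (Procrustes
   distance between the mirrored left and the right ear, scaled to [0, 1]
   by the training-cohort maximum).
5. **Classification.** XGBoost (learning rate 0.3, γ = 0, depth 6) on the
   residuals (± scores) in four designs — MFDM vs control; five-class with
   controls; four-class syndromes only; MFDM genotype classes — with the
   boosting round chosen by stratified 5-fold CV log-loss.
6. **Evaluation.** Confusion matrices (prediction rows × reference columns),
   accuracy with exact Clopper–Pearson intervals and a one-sided
   no-information-rate test, one-vs-all sensitivity/specificity/balanced
   accuracy/F1, rank-based ROC/AUC, two-rater ICC(2,1), and UMAP embeddings
   (k = 15, cosine metric, minimum distance 10⁻⁶).

## Worked example

```r
library(earmorph)

cfg <- pipeline_config(
  simulation = simulation_config(
    group_sizes = c(control = 60, MFDM = 40, NAFD = 40, TC = 40, CHARGE = 40),
    effect_scale = 2, seed = 501),
  validation = simulation_config(
    group_sizes = c(control = 15, MFDM = 12, NAFD = 12, TC = 12, CHARGE = 12),
    effect_scale = 2, role = "validation", seed = 502),
  design = "2.2", seed = 5, max_rounds = 200)

res <- run_pipeline(cfg)
#> simulate: 691 training ears (220 patients), 126 validation ears (63 patients)
#> landmarks-process: 650/691 ears aligned, 12 components retained
#> adjust: 12 mixed models fitted (0 singular)
#> score: 148 training / 63 validation patients scored (FA max 0.04228 frozen)
#> 94 row(s) dropped for missing required features.
#> train: design 2.2 on 368 ears, chosen iteration 56
#> evaluate: 48 validation ears, accuracy 0.979 [0.889-0.999]

res$report$confusion        # 4x4 prediction x reference matrix
generics::tidy(res$report)  # per-class Se/Sp/balanced accuracy/F1 (+ AUC)
ggplot2::autoplot(res$report)  # one-vs-all ROC curves
```

The log above is what the pipeline prints: 220 simulated patients yield
691 ear photographs, of which the grade 0–I ears (650) can be landmarked;
12 shape components cover 90% of variance; training rows of patients whose
contralateral ear was never photographed lack severity/asymmetry scores and
are dropped from this score-using design; and the held-out four-class
accuracy is 0.979 with its exact 95% interval. The published
validation metrics are reproduced from the built-in confusion-matrix
fixtures:

```r
r <- evaluation_report(paper_confusion_fixtures()$design1)
round_half_up(r$accuracy)   # 0.969
round_half_up(r$ci)         # 0.838 0.999
r$nir_p                     # 2.5e-05  (< 0.001)
```

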