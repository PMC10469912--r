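Package: earmorph
Title: Geometric Morphometrics and Syndrome Classification for External Ear Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based analysis of external ear (pinna) shape for the
    differential diagnosis of mandibulofacial dysostosis with microcephaly
    (MFDM) and related craniofacial syndromes. Provides a 41-point ear
    template, generalized Procrustes superimposition with thin-plate-spline
    semilandmark sliding, shape principal components, per-component linear
    mixed models adjusting for age and gender with a per-individual random
    age slope, Marx-grade severity and fluctuating-asymmetry scores,
    gradient-boosted multiclass classification, and a full evaluation suite
    (confusion matrices, exact binomial intervals, no-information-rate tests,
    one-vs-all ROC/AUC, two-rater ICC, UMAP embeddings). A synthetic
    landmark-cohort generator reproduces the statistical structure the
    analysis assumes so the whole pipeline is testable without clinical
    photographs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    nlme,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
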