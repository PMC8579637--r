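Package: qmriresp
Title: Quantitative MRI Parameter Mapping and Treatment-Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise fitting of four quantitative MRI signal models
    (mono-exponential diffusion, diffusion kurtosis, segmented intravoxel
    incoherent motion, and the Tofts two-compartment pharmacokinetic model)
    to produce parameter maps, together with ROI change metrics, RECIST 1.1
    responder labelling, and the diagnostic-statistics layer used to compare
    imaging biomarkers of induction-chemotherapy response in nasopharyngeal
    carcinoma: normality-gated group tests, logistic combination into a
    predictive score, ROC analysis with Youden-optimal cutoffs, likelihood
    ratios and predictive values at cohort prevalence, and pairwise DeLong
    comparison of correlated ROC curves. A seeded synthetic-cohort generator
    renders paired pre/post-treatment signal volumes from known tissue
    parameters so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    rlang,
    car
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
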