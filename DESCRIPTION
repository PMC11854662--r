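Package: flradiomics
Title: Baseline FDG PET/CT Radiomics for Time-to-Treatment Prediction in
    Follicular Lymphoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end radiomics pipeline for baseline 18F-FDG PET/CT of
    low tumour burden follicular lymphoma under watchful waiting. Provides
    PERCIST liver-threshold lesion segmentation with per-lesion metabolic
    volumes, IBSI-style first-order and morphological feature extraction
    under a three-region scheme (pooled tumour burden, hottest lesion,
    healthy-liver reference), ComBat scanner harmonization with a
    Wilcoxon/FDR audit, forward-selected linear-regression and radial-kernel
    SVM models of time-to-treatment validated by leave-one-out
    cross-validation, and a median-split Kaplan-Meier feature screen.
    A seedable synthetic PET phantom cohort generator makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti,
    e1071,
    survival,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    sva,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
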