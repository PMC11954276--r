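Package: hipporad
Title: Hippocampal Functional Radiomics for Cognitive Impairment in Parkinson's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for separating cognitively impaired from
    cognitively preserved Parkinson's disease patients using radiomics of
    resting-state fMRI derivative maps of the bilateral hippocampus.
    Computes ALFF, ReHo, VMHC and degree-centrality maps from 4D BOLD
    volumes; extracts 819 radiomics features per map (first-order, five
    texture-matrix families, and undecimated 3D wavelet sub-bands);
    reduces them by Spearman redundancy pruning and cross-validated LASSO;
    builds rad-score and logistic-regression classifiers with ROC/Youden,
    DeLong comparisons, SMOTE balancing, decision-curve analysis and
    linear SHAP attribution; and relates selected features to clinical
    scales through age-adjusted partial correlations. Includes a synthetic
    cohort generator with planted group effects so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
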