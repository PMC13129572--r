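Package: shapQTL
Title: QTL and Epistasis Mapping with Gradient Tree Boosting and SHAP
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps quantitative trait loci (QTLs) and QTL-by-QTL interactions
    (epistasis) in biparental populations by fitting gradient-boosted
    regression trees to marker genotypes and attributing predictions to
    markers and marker pairs with Shapley additive explanations (SHAP).
    Bootstrap-resampled model fits yield per-line SHAP values and SHAP
    interaction values, which are averaged into global marker and
    marker-pair importance scores. Includes an F2/RIL biparental cross
    simulator with hidden QTL loci (Haldane crossover model), an epistatic
    phenotype generator targeting a set broad-sense heritability, an exact
    subset-enumeration Shapley oracle for tree ensembles, and an ROC/AUC
    evaluation harness for detection power.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    xgboost,
    pROC,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
biocViews: Software, Genetics, FeatureExtraction, Regression
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
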