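Package: mrmcascade
Title: Targeted MRM Proteomics Quantitation and Logistic Biomarker Model Cascade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Absolute quantitation of multiplexed MRM (multiple reaction
    monitoring) plasma protein panels from NAT/SIS peak-area ratios via
    1/x^2-weighted calibration curves with below-LLOQ substitution, a
    normality-gated univariate statistics layer (Shapiro-Wilk gating,
    Welch t / Mann-Whitney, ANOVA with Tukey or Games-Howell post-hocs,
    Kruskal-Wallis with Dunn-Holm post-hocs, Benjamini-Hochberg correction,
    Cohen's d, clinical correlations), OPLS-DA variable importance in
    projection, and a multi-step logistic biomarker model-building cascade
    (engineered-feature expansion, VIP filter, backward AIC elimination,
    Wald p-value pruning, leave-one-out cross-validation, Youden threshold
    selection). A synthetic-cohort generator with known ground truth makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
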