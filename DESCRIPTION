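Package: radstrat
Title: Multi-Lesion CT-Radiomics Patient Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Patient-level stratification of metastatic lung adenocarcinoma
    from lesion-level CT radiomic features. Provides reproducibility
    filtering of radiomic features (intraclass correlation and near-zero
    variance), center-scaling with Yeo-Johnson normalization, three
    patient-level integrations of multi-lesion data (per-patient centroid,
    largest lesion, biopsied lesion), lesion-to-centroid dispersion
    statistics, hierarchical consensus clustering with adjusted-Rand-index
    comparison of clusterings, association statistics (odds ratios with
    Wald intervals, univariable screening and backward stepwise logistic
    regression, Kaplan-Meier/log-rank and Cox models), Monte Carlo
    cross-validated AUROC comparison of nested feature sets, and a
    synthetic cohort generator emulating the cohort structure the analysis
    assumes so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
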