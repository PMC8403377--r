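Package: lpsprs
Title: Low-Pass Sequencing Imputation and Polygenic Risk Score Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for comparing low-pass
    whole-genome sequencing followed by genotype-likelihood-aware imputation
    against genotype arrays for polygenic risk scoring. Provides a phased
    haplotype-panel and mosaic cohort simulator, a site-level read and
    genotype-likelihood model, a diploid Li-Stephens haplotype-copying HMM
    with genotype-likelihood and hard-call emission modes (exact scaled
    forward-backward), coverage breadth and Lorenz/Gini uniformity metrics,
    a genotype concordance suite (Pearson R2, non-reference discordance,
    FPR/FNR, allele-frequency-stratified aggregate R2), clumping and
    thresholding (P+T) polygenic scores under a liability-threshold
    case/control model, and ROC/AUC discrimination statistics, orchestrated
    by a seeded end-to-end experiment driver with VCF and TSV interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
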