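Package: smotescan
Title: SMOTE-Balanced GWAS Manhattan-Plot Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for handling extreme case-control imbalance in biobank-scale
    genome-wide association studies by minority oversampling and image
    recognition. Simulates imbalanced case-control cohorts with designed
    comorbidity structure; identifies comorbid disease groups by
    phi-correlation distance and PAM k-medoids with silhouette-selected k and
    prunes comorbid controls; applies call-rate, minor-allele-frequency and
    exact Hardy-Weinberg quality-control filters; performs allelic chi-square
    and logistic-dosage association scans; oversamples minority cases with
    covariate-stratified SMOTE; rasterizes association results into grayscale
    Manhattan-plot images; preprocesses them with Gaussian/median smoothing and
    morphological dilation/erosion/gradient operators; and compares balancing
    strategies by the softmax similarity of a compact convolutional neural
    network trained on the resulting image corpora.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
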