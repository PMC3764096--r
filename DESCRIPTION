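Package: markerbias
Title: Ascertainment Bias Diagnostics and Genomic Prediction for SNP Marker Platforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ascertainment bias of a candidate marker platform
    (for example an array designed on a small discovery panel) against a
    reference platform (for example genotyping-by-sequencing) genotyped on
    the same inbred lines. Implements an equal-size marker-subsampling
    null distribution over population-genetic statistics (Weir-Cockerham
    Fst, Kullback-Leibler divergence between realized relationship
    matrices, minor-allele-frequency spectra, PCA eigenstructure,
    tag-SNP redundancy, marker distance variance), random-forest
    imputation of missing marker scores, GBLUP genomic prediction with
    REML variance components under fixed-partition cross-validation, and
    a pedigree-based simulator of inbred breeding populations genotyped
    on an unbiased and a panel-ascertained platform.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    ranger
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
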