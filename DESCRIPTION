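Package: gwadl
Title: Genome-Wide Association Enriched Deep Learning for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction of quantitative traits from SNP dosages by
    GWAS P-value marker enrichment feeding a two-hidden-layer feed-forward
    regression network (GWADL), benchmarked against kinship-based GBLUP and
    genomically-spaced marker controls. Includes VCF/dosage-matrix ingestion
    with missingness/MAF filtering and mean imputation, Box-Cox trait
    normalization selected by the Shapiro-Wilk statistic, broad-sense
    heritability by the repeatability (one-way ANOVA) method, a FarmCPU-style
    multilocus association scan with pseudo-QTN covariates, VanRaden kinship
    with spectral REML variance components, Gedeon weight-magnitude variable
    importance, heritability-normalized accuracy comparison with Tukey HSD
    letters, and a Balding-Nichols structured-population simulator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
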