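Package: mfssgblup
Title: Metafounder-Based Multibreed Single-Step Genomic Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for multibreed genetic evaluation with metafounders:
    estimation of ancestral (metafounder) relationships from SNP gene
    contents by generalized least squares, pedigree and genomic
    relationship matrices with and without metafounder augmentation,
    breed-of-origin partial relationship matrices, single-step GBLUP
    H-inverse construction, bivariate repeatability animal models with
    AI-REML variance component estimation, variance rescaling to the
    unrelated-base scale, and forward validation of breeding values.
    Includes a synthetic multibreed population generator with known truth
    (ancestral relationships, variance components, breeding values) for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    methods,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
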