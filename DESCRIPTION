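Package: wssgblup
Title: Single-Step and SNP-Weighted Genomic BLUP with LR-Method Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pedigree and single-step genomic evaluation for repeatability
    animal models: numerator relationship matrices and their sparse inverses,
    VanRaden genomic relationship matrices with optional per-SNP weights,
    single-step H-inverse construction, Henderson mixed-model equations with
    direct and preconditioned conjugate-gradient solvers, the iterative
    nonlinear-A SNP-weighting scheme (weighted ssGBLUP), and validation of
    predictions by the linear-regression (LR) method on partial/whole data
    splits. Includes a deterministic simulator of multi-generation pedigrees,
    gene-dropped genotypes, oligogenic traits and repeated records for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
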