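Package: sparsemix
Title: Sparsely Regularized Admixture Models for Genomic Breed Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised admixture models for estimating the genomic breed
    composition (GBC) of individual animals from SNP genotypes and
    breed-specific allele frequencies. Implements the non-regularized
    maximum-likelihood admixture model and three sparsely regularized
    variants (L1, minimax concave penalty, smoothly clipped absolute
    deviation) fitted by projected minimum-norm subgradient ascent on the
    probability simplex, with KKT convergence certificates. Includes
    likelihood-based curation of reference panels, selection of the
    regularization parameter by k-fold cross-validation on the
    percent-of-pure-animals criterion, conditional and restricted-reference
    estimators for composite (crossbred) animals, a Balding-Nichols
    simulator of differentiated breed panels with known admixture truth,
    and readers/writers for PLINK text PED/MAP and tabular allele-frequency
    formats, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
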