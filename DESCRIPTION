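Package: mfqls
Title: Multivariate Family-Based Quasi-Likelihood Score Tests
Version: 0.1.0
Authors@R: person("MFQLS", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Retrospective quasi-likelihood score tests for the joint
    association of multiple genetic variants with multiple quantitative
    and/or dichotomous phenotypes in family samples (MFQLS), together with
    the MMQLS (prevalence offset) and MMASTOR (mixed-model working
    covariance) variants.  Includes pedigree kinship and genomic
    relationship matrices, restricted-maximum-likelihood null models with
    BLUP phenotype offsets, conditional-expectation handling of missing
    genotypes, PLINK file input/output, and a pedigree simulator
    (two-locus haplotypes, polygenic effects, liability thresholding,
    Balding-Nichols population substructure) for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
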