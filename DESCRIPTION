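Package: hybridGP
Title: Genomic Prediction of F1 Hybrid Performance from Parental Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection in hybrid breeding programs that
    cross inbred seed parents (testers) to panels of pollinator lines.
    Builds additive and dominance design matrices for F1 hybrids from
    parental SNP genotypes, fits ridge-regression BLUP (RR-BLUP) models
    with additive-only (partial) or additive-plus-dominance (full) marker
    effects by restricted maximum likelihood, estimates multi-environment
    variance components and broad-sense heritability, computes VanRaden
    genomic relationships, identity-by-state distances and principal
    components for population structure, and evaluates prediction accuracy
    through five-fold cross-validation, training-population sizing, and
    parent-relatedness validation schemes. Includes a synthetic-data
    generator emulating structured parental panels, tester-by-pollinator
    mating designs and replicated multi-environment trials, plus VCF/TSV
    genotype input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
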