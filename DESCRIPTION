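Package: rmgwas
Title: Genome-Wide Association Scans for Related Individuals with Repeated Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage genome-wide association testing for populations of
    related individuals with repeated phenotype records, as found in long-term
    studies of wild populations. A linear mixed model with a polygenic random
    effect (covariance proportional to a VanRaden genomic relationship matrix)
    and a permanent-environment random effect is fitted once by REML to
    estimate the phenotypic covariance; every SNP is then tested by
    generalized least squares after whitening with that covariance, using an
    efficient low-rank factorization so the observation-level
    eigendecomposition is never formed densely. Includes genotype QC and GRM
    construction, a phenotype simulator (Gaussian and liability-threshold
    binary traits, balanced and unbalanced repeat designs, year effects),
    analytic liability-to-observed-scale transformations for binary traits,
    and an individual-averages baseline scan for power comparisons.
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
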