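Package: cohortsel
Title: Selection Scans on Trait-Associated Alleles Across Birth Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects natural selection on trait-associated alleles from
    allele-frequency trends across birth cohorts in biobank-style data,
    attributes selection signals to reproductive pleiotropy versus
    lifespan effects, and converts the inferred genetic change into a
    predicted change in disease prevalence under a liability-threshold
    model. Includes a synthetic-cohort generator with planted ground
    truth (selection coefficients, liability effects, reproductive and
    lifespan effects) used to validate every stage of the pipeline, a
    covariate-adjusted single-SNP association engine with QC, LD pruning
    and FDR control, matched-SNP resampling negative controls, and an
    end-to-end seeded pipeline runner with a machine-readable report.
    Developed around the refractive-error (myopia) phenotype: spherical
    equivalent, age correction to age 40, and the dominant-model
    selection coefficient s = (change in p)/p per generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
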