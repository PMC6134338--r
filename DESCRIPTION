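Package: sctassoc
Title: Candidate-Gene SNP-Set Association Testing in Sex Chromosome
    Trisomy and Twin Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether candidate-gene SNP sets (CNTNAP2 and
    NRXN1 regions) are associated with a latent neurodevelopmental factor in
    sex-chromosome-trisomy (SCT) and twin comparison cohorts. Implements
    Generalized Structured Component Analysis (GSCA) fitted by alternating
    least squares with permutation inference on gene-to-factor paths, the
    genotype quality-control cascade used in candidate-gene studies (call
    rate, heterozygosity, exact Hardy-Weinberg, minor allele frequency,
    Mendelian errors, pairwise LD reporting), latent-phenotype construction
    from a language test battery, exploratory per-SNP regression and
    gene-based burden and variance-component (SKAT-style) tests, an
    ascertainment-bias power simulator, and a synthetic twin/trisomy cohort
    generator that emulates the statistical structure of the study data so
    the full pipeline is testable without access to individual genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
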