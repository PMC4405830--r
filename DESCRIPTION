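Package: d4z4meth
Title: Allele-Specific D4Z4 DNA Methylation from Bisulfite Clone Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for allele-specific DNA methylation of the
    D4Z4 macrosatellite repeat from cloned bisulfite-PCR Sanger sequences.
    Converts clone sequences into filtered per-clone CpG methylation call
    matrices against an assay reference (bisulfite-aware alignment, identity
    and homolog filters), estimates per-allele methylation with a Bayesian
    two-component beta-binomial mixture (spike-and-slab prior on the allele
    difference, Metropolis-within-Gibbs MCMC with Gelman-Rubin convergence
    checks, and an exhaustive quadrature oracle for validation), and compares
    disease classes at the cohort level (logit-scale linear mixed-effects
    models with likelihood-ratio tests, exact paired sign test, repeat-unit
    calculation from restriction fragment sizes). Includes a synthetic-data
    generator emulating clone counts, clone sequences with sequencing error
    and homolog contaminants, and family-structured cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    lme4,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
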