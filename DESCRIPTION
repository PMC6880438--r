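Package: lcgps
Title: Low-Coverage Whole-Genome Sequencing Imputation and Polygenic Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for genotype imputation from low-coverage
    whole-genome sequencing (lcWGS) and downstream genome-wide polygenic
    score (GPS) calculation. Simulates phased reference haplotype panels
    with population structure and linkage disequilibrium, Poisson-coverage
    sequencing reads with base errors, and a genotyping-array comparison
    arm; computes genotype likelihoods from pileup counts; imputes
    genotypes with a genotype-likelihood-aware diploid Li-Stephens
    haplotype-copying hidden Markov model using per-sample
    identity-by-state-selected custom reference panels; and computes,
    normalizes (principal-component residual z-scores) and associates
    polygenic scores with binary phenotypes. Includes accuracy metrics
    (dosage r-squared by sample, site and minor-allele-frequency bucket),
    a Hardy-Weinberg exact test, coverage-ladder experiments, and VCF,
    pileup and score-file interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
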