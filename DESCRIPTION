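Package: daasel
Title: Deterministic Multi-Allele Viability Selection and Overdominance Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying balancing selection at a single autosomal
    locus with many alleles under deterministic (effectively infinite
    population) viability selection. Implements three overdominance models
    of genotype fitness -- symmetric overdominance, asymmetric overdominance
    (AO) and divergent allele advantage (DAA, where heterozygote fitness is
    the union of the epitope sets recognized by the two alleles -- together
    with an equilibrium solver based on linear solves with iterative
    elimination of non-persisting alleles, a discrete-generation time-step
    validator, equilibrium diversity and epitope-overlap metrics, and a
    scenario-sweep simulation framework for paired comparisons of the AO
    and DAA models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
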