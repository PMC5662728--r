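Package: gsimix
Title: Genetic Stock Identification and Mixture Analysis for
    Microsatellite Baselines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genetic stock identification (GSI) of introduced or
    mixed-origin salmonid populations against a hierarchical microsatellite
    baseline.  Implements Rannala-Mountain conditional-likelihood individual
    assignment with leave-one-out self-assignment, reporting-group
    aggregation, mean-posterior and EM conditional-maximum-likelihood
    mixture-proportion estimation, Weir-Cockerham F-statistics, rarefied
    allelic richness, permutation tests for genic differentiation,
    heterozygote deficit and linkage disequilibrium, a mixed-origin founding
    simulation that quantifies spurious assignment of admixed genotypes, and
    a Balding-Nichols synthetic baseline generator so every stage is testable
    without external reference data.  Genotypes are handled as tidy tibbles
    and read/written in GENEPOP format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stats,
    utils,
    jsonlite,
    yaml,
    digest,
    ggplot2,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
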