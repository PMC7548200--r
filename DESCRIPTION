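Package: rivergsi
Title: Riverine Genetic Structure, Stock Identification, and Isolation by
    Distance on Dendritic Networks
Version: 0.1.0
Authors@R:
    person("Riverine GSI", "Developers", email = "rivergsi@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how hatchery translocations reshape the
    genetic structure of river-dwelling salmonid populations and degrade
    genetic stock identification (GSI). Provides genotype quality control
    (call-rate and exact Hardy-Weinberg filters, permutation tests of
    differentiation across years and detection sites), multilocus pairwise
    Weir-Cockerham theta, EM-based mixture estimation and leave-one-out
    self-assignment against an allele-frequency baseline, Rousset-linearised
    isolation-by-distance regression with Mantel permutation tests and a
    slope-uncertainty equivalence test with population-relocation
    counterfactuals, and Cavalli-Sforza-Edwards chord-distance
    neighbor-joining trees with locus-bootstrap support. Includes a
    synthetic-data generator producing diploid biallelic SNP genotypes on a
    dendritic river network under distance-dependent drift, with an optional
    translocation event.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
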