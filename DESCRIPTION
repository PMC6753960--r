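Package: metapopman
Title: Management of Genetic Diversity in Subdivided Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and evaluating conservation-management
    strategies in subdivided populations. Provides a forward neutral
    Wright-Fisher simulator that builds a structured base population from a
    mutation-drift-equilibrium ancestor, multiallelic marker construction
    from haplotypes of five consecutive SNPs, partitions of total
    heterozygosity (Nei) and of allelic diversity into within- and
    between-subpopulation components, and a simulated-annealing optimiser of
    parental contributions, matings and migration that maximises total
    heterozygosity, total allelic diversity, or allele retention. A
    replication harness runs multi-generation management studies and
    aggregates diversity trajectories over replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
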