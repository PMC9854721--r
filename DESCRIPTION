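Package: wreckpop
Title: Population Genetics of Wreckfish Gene Pools from Mitochondrial
    Haplotypes and Microsatellites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the population-genetic characterization of wreckfish
    (Polyprion spp.) gene pools, and of similarly structured marine species.
    Implements mitochondrial haplotype diversity statistics (haplotype
    diversity, mean pairwise differences, segregating sites, Fu's Fs via the
    Ewens sampling distribution), between-lineage divergence (Dxy, Nei's net
    divergence Da) with a hybrid-lineage net-divergence correction and
    molecular-clock dating, Hudson-Kaplan minimum recombination events,
    median-joining haplotype networks, microsatellite summaries (allelic
    richness, heterozygosities, Hardy-Weinberg exact tests by Markov chain,
    null-allele EM estimation), Weir-Cockerham F-statistics, Jost's D,
    hierarchical AMOVA with permutation tests, distance-based
    neighbor-joining trees (Jukes-Cantor and Cavalli-Sforza chord
    distances), POWSIM-style power simulation, and seed-deterministic
    synthetic-data generators for island-model genotypes and three-lineage
    sequence sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
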