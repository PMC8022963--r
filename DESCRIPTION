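Package: BreedSim
Title: Graph-Based Stochastic Simulation of Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Describe breeding programs as directed graphs of cohorts (nodes) and
    breeding actions (edges) in a versioned JSON dialect, unroll repeated breeding
    cycles into an explicit schedule, and simulate them with a stochastic
    quantitative-genetics engine: founder genomes drawn from per-marker allele
    frequencies, recombination under a Haldane map, correlated multi-trait QTL
    architectures, repeated phenotype records with permanent-environment effects,
    age-based culling, and selection by phenotype index, pedigree BLUP or
    single-step GBLUP. Evaluation utilities cover observed phenotypes, true
    genomic values, accuracy of breeding-value estimation, identity-by-descent
    kinship and inbreeding, major-QTL reports, discounted cost ledgers and
    replicate-averaged scenario comparison. A dairy-cattle herd example with five
    index traits is built in as a programmatic fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, Matrix, MASS
Suggests: testthat (>= 3.0.0), vcfR, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
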