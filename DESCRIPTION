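Package: clonepop
Title: Clonal Structure and Population Genetics of Microsatellite Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clone discrimination and population-genetic analysis for diploid
    multilocus microsatellite genotypes from clonal organisms such as corals.
    Assigns multilocus genotypes (MLGs), evaluates the probability that
    repeated genotypes arise from independent sexual events (Psex), collapses
    MLGs differing by a single allele into multilocus lineages (MLLs), and
    computes clonal richness and Simpson's-complement genotypic evenness.
    Per-locus diversity (allele counts, rarefied allelic richness, private
    alleles, observed and expected heterozygosity, inbreeding coefficients)
    with permutation tests for Hardy-Weinberg and linkage equilibrium and a
    Brookfield null-allele screen; pairwise population differentiation via
    Weir-Cockerham theta and the Nei/Hedrick/Meirmans G-statistics with
    permutation p-values. Includes a synthetic clonal-population generator
    with known truth for validation, readers and writers for GenAlEx-style
    codominant genotype files, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
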