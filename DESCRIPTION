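Package: bacmapr
Title: BAC-End Mate-Pair Anchoring, Comparative Synteny Maps and Genome
    Rearrangement Distances
Version: 0.1.0
Authors@R:
    person("BACmapr", "Developers", email = "bacmapr@example.org",
           role = c("aut", "cre"))
Description: Tools for building a first-generation comparative map between an
    unassembled genome sampled by BAC-end sequences (BES) and an assembled
    reference genome.  Implements BES mate-pair anchoring with concordance
    classification and mate-rescue of multi-mapped reads, BAC library coverage
    statistics (fold coverage, probe-screening depth, GC content, size-weighted
    chromosome-distribution chi-square test), conserved-synteny block calling
    from FISH-anchored marker tables, condensation of marker maps to signed
    segment permutations, and an exact minimum genome-rearrangement distance
    (inversions, translocations, fusions and fissions over multichromosomal
    signed genomes, the GRIMM model) with a parsimonious sorting scenario.  A
    synthetic-data generator emulates the whole data-generating process
    (rearranged genomes, BAC clones, BES reads, alignments, marker tables and
    probe screening) with known ground truth so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
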