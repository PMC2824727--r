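# bacmapr

Comparative-genomics toolkit for first-generation BAC-based genome projects:
anchoring BAC-end-sequence (BES) mate pairs onto an assembled reference
genome, characterising the clone library, building a conserved-synteny
marker map from FISH data, and estimating the minimum number of chromosomal
rearrangements separating the two genomes.

## Who this is for

Labs working on a species **without** an assembled genome who have (i) a BAC
library, (ii) a modest set of BES reads aligned to a related reference
assembly (e.g. mouse), and (iii) FISH placements of selected clones on the
study species' chromosomes. From those three inputs the package produces a
per-clone concordance catalogue, library quality statistics, a comparative
cytogenetic map, and a parsimony estimate of the rearrangement history — the
standard analysis arc of a BAC-resource paper. A synthetic-data generator
emulates the whole process with known ground truth, so every stage is
testable without any external data.

## The statistics and the model

* **Library coverage.** Fold coverage is `c = nL/G` for `n` clones of mean
  insert `L` on a genome of size `G`; the probability that a given locus is
  recovered from the library is the Clarke–Carbon complement `1 − e^(−c)`.
  Observed depth is estimated from gridded-filter probe screening as the
  mean number of clones hybridising per probe.
* **Mate-pair concordance.** Each BES maps to 0, 1 or >1 reference loci.
  Multi-mapped reads are rescued when a uniquely mapped mate singles out
  exactly one candidate forming a proper pair. A resolved pair is
  *concordant* when both ends hit one chromosome, on opposite strands facing
  inward, with an outer span inside the closed 90–200 kb window (the
  expected clone span); violations are categorised as assignable indels
  (span off-window but ≤ 2 Mb), large/complex events (> 2 Mb), inversions
  (orientation violations) or translocations (different chromosomes).
* **Chromosome distribution.** A Pearson chi-square test compares per-
  chromosome BES counts to expectations proportional to chromosome size,
  with X and Y weights halved for a male-derived library (df = k − 1; 21
  categories give df = 20).
* **Synteny and rearrangement distance.** Maximal runs of FISH markers on
  one study chromosome mapping to one reference chromosome form
  conserved-synteny blocks; runs additionally adjacent in reference order
  collapse to signed segments ("strips"). The minimum number of
  **inversions, translocations, fusions and fissions** transforming one
  multichromosomal signed genome into the other (the GRIMM model) is
  computed exactly as the DCJ distance `n − C − I/2` on the adjacency graph
  plus a penalty for unoriented chromosome-confined components, and is
  validated in the test suite against an exhaustive breadth-first-search
  oracle. A deterministic parsimonious scenario decomposes the distance
  into intra- vs inter-chromosomal events; orientation-less singleton
  markers get their signs by explicit minimisation.

## Worked example

```r
library(bacmapr)

## library arithmetic for a 194,267-clone, 139-kb library on a 2.8-Gb genome
library_stats(194267, 139000, 2.8e9)
#> BAC library: 194267 clones x 139000 bp inserts / 2.8e+09 bp genome = 9.64x coverage
#> P(locus recovered) = 0.9999

## simulate a project: 3 chromosomes, 3 rearrangement events, mapping noise
cfg <- sim_config(n_chromosomes = 3, chrom_lengths = c(120e6, 90e6, 60e6),
                  n_clones = 300, n_events = 3, p_unmapped = 0.3,
                  p_multimap = 0.1, seed = 42)
sim <- simulate_dataset(cfg)

## anchor the simulated BES alignments
calls <- anchor_clones(parse_blast_tab(write_blast_tab(sim$alignments, tempfile())))
summarize_anchors(calls)
#>   no_anchor single_end concordant ... anchored_single anchored_both
#> 1        16        103        142 ...             103           142

## comparative map -> signed segments -> rearrangement distance
sg  <- condense(sim$markers)
opt <- optimize_ambiguous_signs(sg$genome_query, sg$genome_target,
                                sg$ambiguous_segments)
classify_scenario(sorting_scenario(opt$genome, sg$genome_target))
#> minimum rearrangements: 1 (0 inversion(s), 1 inter-chromosomal:
#>   1 translocation(s), 0 fusion(s), 0 fission(s))
```

With 300 clones and a ~30-Mb marker grid, only one of the three simulated
events is visible at marker resolution — the parsimony estimate is a lower
bound (`d ≤ k` always), exactly as in real low-resolution cytogenetic maps.
Denser marker grids (`marker_spacing`) recover more of the history.

The same stages are available from the command line
(`inst/cli/bacmap simulate|anchor|stats|synteny|distance|run`), reading and
writing plain TSV/FASTA/JSON and the classic GRIMM genome text format, so
any stage can be run standalone on real data (e.g. real MEGABLAST output
against an assembled reference).

## Further reading

The model, its assumptions, all tunable parameters and the validation
strategy are documented in `vignettes/bacmapr-methods.Rmd`.
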