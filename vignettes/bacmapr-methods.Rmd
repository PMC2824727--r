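---
title: "bacmapr: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bacmapr: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacmapr)
```

# Scope

`bacmapr` implements the analysis arc of a first-generation BAC genome
resource: library characterisation, BES mate-pair anchoring against a
related assembled genome, comparative (cytogenetic) map construction, and a
parsimony estimate of the rearrangement history, together with a
synthetic-data generator that makes every stage testable with known ground
truth. This vignette documents the models, the parameters that matter, the
numerical choices, and what a green test does and does not establish.

# The synthetic world

The generator emulates the data-generating process of a BAC project on a
vole-like rodent mapped against a mouse-like reference:

* an **ancestor** (reference-side) genome with markers on a regular grid of
  `marker_spacing` (default 30 Mb, the typical density of a first-generation
  FISH map) with ±20% jitter;
* a **derived** (study-side) genome produced by `n_events` random
  inversions, reciprocal translocations, fusions and fissions, drawn
  uniformly over kinds by default (`event_weights` is configurable since
  real rodent comparisons are translocation-heavy). Breakpoints fall at
  midpoints **between** markers, never inside one: the map is
  marker-resolution, and this guarantees clean truth labels;
* **BAC clones** with insert sizes from a truncated normal on
  [`insert_min`, `insert_max`] = [100, 200] kb whose *truncated* mean equals
  `insert_mean` = 139 kb (the location parameter is re-centred by root
  finding; naive truncation at an asymmetric window would bias the mean
  upward by ~2.5 kb). `insert_sd` = 25 kb puts ~95% of the untruncated mass
  inside the window, consistent with "the vast majority of inserts in the
  100–200 kb range" phrasing of library QC reports;
* **BES reads** of mean length 728 bp (`read_len_sd` = 70–100 bp class;
  default 100) at GC fraction 0.418, two per clone (`_T7`/`_SP6`), as
  base-composition-only random sequences — there is no positional sequence
  realism, no repeats, no quality values. The FASTA emitter exists to
  exercise GC/length statistics, not alignment;
* **alignments** in 12-column BLAST tabular form at the orthologous
  ancestor coordinates (1-based inclusive, minus strand encoded by
  `sstart > send`), with two independent noise channels: a read is dropped
  with probability `p_unmapped` (default 0.5) or duplicated to a uniformly
  placed decoy locus at *equal bit score* with probability `p_multimap`
  (default 0.17). The defaults reproduce the published regime where roughly
  one third of BESs map uniquely; the true split between unmapped and
  multi-mapped vole reads is not published and both remain free parameters.
  Equal-score decoys make the mate-rescue logic genuinely decisive — a
  score margin would short-circuit it;
* **probe screening** as i.i.d. Poisson(depth) hit counts per probe, the
  natural null for clones hitting a probe independently at rate equal to
  the fold coverage.

A single integer `seed` drives one root generator; each emitter draws from
its own child stream (`child_seed`), so adding an emitter does not perturb
the others, and all emitters are byte-identical across runs at a fixed seed.

Reads crossing a rearrangement junction are assigned to the segment holding
the majority of the read. Since reads (~0.7 kb) are tiny against inserts
(~139 kb), this affects only clones whose junction falls within a read
length of a clone end; truth-label comparisons in the tests therefore
restrict "straddling" checks to clones whose junction is ≥ 2 kb from both
ends — the same resolution limit applies to real BES data.

# Anchoring rules

Mappability is count-based: 0 hits → `unmapped`, 1 → `unique`, ≥2 → `multi`
(a configurable best-vs-second bit-score margin was considered and rejected
as a default because published methods give no margin). One round of
mate-rescue searches a multi-mapped read's candidates with its uniquely
mapped mate: exactly one candidate forming a proper pair upgrades the read;
zero or several keep it `multi` (ambiguity is never resolved by guessing).
Rescue is single-pass — rescued anchors do not themselves rescue others.

A resolved pair is classified by three questions, in order: same
chromosome? opposite strands facing inward? outer span inside the window?

* **Span** is the outer distance (leftmost start to rightmost end): for a
  correctly placed clone it equals the insert length exactly, which is what
  the 90–200 kb window describes.
* The window is **closed**, `[90,000, 200,000]` bp; "90–200 kb" is
  ambiguous at the endpoints and the inclusive reading avoids dropping
  clones at the boundary for a 1-bp technicality.
* Opposite strands facing **outward** cannot arise from a contiguous
  insert; they are orientation violations and classified inversion-type,
  like same-strand pairs.
* Same-chromosome facing pairs with off-window span are assignable indels
  up to `large_indel` = 2 Mb and large/complex beyond — the assignable
  class still localises the clone to a single orthologous interval.

Classification is a total function on resolved pairs and symmetric under
swapping the ends (both are property-tested).

# Library statistics

`fold_coverage(n, L, G) = nL/G`, unrounded. `prob_locus_recovered(c)`
= 1 − e^(−c). `observed_depth` is the mean hit count per probe after
removing excluded clones (false-positive hybridisation is handled by the
caller passing exclusions, mirroring contig-based filtering). `gc_fraction`
counts (G+C)/(A+C+G+T) with N excluded from the denominator and performs no
internal trimming. The chromosome-distribution test is Pearson's chi-square
with expectations proportional to chromosome size; a male library halves
the X and Y weights (one copy each against two per autosome) — df = k − 1,
so the canonical 19-autosome + X + Y table gives df = 20. A female mode
zeroes the Y weight and insists the category be absent or merged (expected
counts of zero make the statistic undefined; the error says so). The
p-value is reported from the chi-square distribution but the statistic is
the tested quantity.

# Comparative map

The query (study) side of the marker table is cytogenetic: integer ranks
with ties allowed for FISH signal pairs that could not be ordered. Two
deterministic conventions resolve the underdetermination:

* **Tie rule:** tied ranks are ordered by target position ascending. This
  is the parsimony choice — it never manufactures a breakpoint that the
  data do not force — and it makes condensation deterministic.
* **Sign rule:** a marker run's sign is the direction of target
  coordinates along the query chromosome. FISH provides no physical
  orientation, so signs are inferential by construction; single-marker
  segments have *no* observable sign and are flagged ambiguous, carried
  with a provisional `+`, and optimised downstream (below).

Blocks are maximal same-target-chromosome runs (block count = 1 + number of
target-chromosome switches per query chromosome). Condensation collapses
maximal strips — runs adjacent in query order and adjacent in target order
— to one signed segment. **Descending runs collapse too**, with sign `−`:
an inverted block reads as a descending run, and collapsing it (rather than
fragmenting it into singletons) is the distance-preserving convention used
when preparing signed input for rearrangement analysis. Condensation is
idempotent, and segment ids are assigned in target order so the target
genome is always the identity.

# Rearrangement distance

The model is the classical multichromosomal signed-permutation model:
reversals (inversions), reciprocal translocations, fusions and fissions at
unit weight, linear chromosomes only, genomes equivalent up to chromosome
order and whole-chromosome flips. Translocations include *tail transfers*
(one empty exchanged piece, the capped formulation's semi-translocations);
without them the four-operation model is strictly weaker than the model
implemented by the standard tools, and early oracle calibration showed
exactly that discrepancy.

`genomic_distance` is computed as

* the **DCJ count** `n − C − I/2` on the adjacency graph (C cycles, I odd
  paths), a lower bound that is tight whenever no obstruction exists, plus
* a **knot penalty** for unoriented components confined to a single
  chromosome, which no legal reversal can split without excising a circular
  intermediate. Real knots (cycle-only components) pay the cover cost of
  their nesting forest — number of leaves, plus one in the fortress
  configuration (odd leaf count, every leaf protected). Telomere-bearing
  semi-knots pay one operation per pair (a single cross-piece operation
  orients two of them). Knots are *rescued* (cost zero) when a crossing
  clean piece orients them or when a freely cuttable black edge (one whose
  cut is itself a sorting fission, tail transfer or translocation)
  separates the knot's elements — cuts inside its span, or between a
  semi-knot's telomere and its blacks.

Correctness is defined operationally, not by formula provenance: an
exhaustive bidirectional breadth-first search over the operation set
(`bfs_oracle`, C++-backed, exact by construction, state-budget-guarded) is
the ground truth. During development the penalty rules were validated
against the oracle on **every** instance with ≤ 5 segments and ≤ 3
chromosomes on each side (21,600 canonical instances, zero mismatches), a 1%-sampled
exhaustive sweep at 6 segments (44,305 instances, zero mismatches), and
several thousand random pairs with up to 7 segments, again with zero
mismatches; the shipped test suite re-runs oracle equivalence on 260+
random instances and the acceptance script on 200 more. A green suite establishes
exact agreement on the sampled universe; instances far larger than
anything validated could in principle contain unoriented structures outside
the calibrated rules, but the workloads this package targets (marker maps
of tens of segments produced by condensation) were checked via the
simulated-history bound `d ≤ k` at 40 segments.

`sorting_scenario` greedily applies the first operation (reversals, then
translocations, fusions, fissions, positionally lexicographic) that reduces
the distance by exactly one; its length always equals the initial distance,
and every prefix is verified during construction. Optimal scenarios are
not unique — alternative optima can trade a reversal for a translocation —
so the reported decomposition refers to the one deterministic scenario.

`optimize_ambiguous_signs` enumerates all 2^k sign assignments of the
ambiguous (singleton) segments for k ≤ 12, returning the first minimum in
enumeration order (all-`+` first); beyond 12 it falls back to a greedy
one-at-a-time hill climb from all-`+` and flags the result approximate.
2^12 = 4,096 distance evaluations is a comfortable exhaustive budget; real
first-generation maps have far fewer singletons.

# Numerical and degenerate-input choices

* Empty alignment files parse to an empty table (not an error); malformed
  rows and unparseable read ids are errors naming line numbers.
* `n_markers = 0` yields an empty genome without error; a fission of a
  one-marker chromosome is illegal and resampled up to a cap of 100, then
  an error.
* `insert_min = insert_max` degenerates to a point mass.
* Distances are integers; there are no tolerances anywhere in the
  rearrangement engine.
* The statistical examples in the tests use the standard-error bounds
  stated with each generator contract (2 SE for means, 3 SE for the
  Poisson depth and chi-square null mean at their stated replicate counts)
  at fixed seeds.

# Known limitations

* No nucleotide-level evolution, repeats, NUMTs or read-quality modelling;
  repeat-content estimation is out of scope (it depends on an external
  masking tool and its library version).
* No split/chimeric alignments within one read; a read crossing a junction
  is assigned to its majority segment.
* The distance engine supports linear chromosomes only (no circular
  chromosomes, no transpositions/block interchanges) — matching the
  four-operation model, not extending it.
* The scenario's kind decomposition is one optimal answer among possibly
  several; treat headline decompositions as "a minimum-length history", not
  "the history".
* Outgroup polarisation of events (assigning rearrangements to lineages)
  and median/ancestor reconstruction are out of scope.
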