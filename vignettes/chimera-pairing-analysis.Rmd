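---
title: "From chimeric AGO CLIP reads to miRNA pairing rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From chimeric AGO CLIP reads to miRNA pairing rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraCLIP)
```

## The problem

Argonaute (AGO) proteins silence mRNAs under the guidance of a bound miRNA.
Conventional AGO CLIP maps where AGO binds, but not *which* miRNA directed
each binding event. Protocols that ligate the miRNA to its bound target
fragment inside purified AGO complexes (CLEAR-CLIP, CLASH) solve this: a
single sequencing read then carries both the mature miRNA and a piece of its
target, joined at a ligation junction. chimeraCLIP turns such reads into
miRNA--target interactions and characterises how each miRNA pairs with its
targets: canonical seed classes, single-mismatch and single-bulge variants,
G:U wobbles, predicted duplex structures, discrete binding modes, enriched
target motifs, and targeting specificity among seed-family paralogues.

Chimeras occur in two orientations. In a miR-first chimera the miRNA sits at
the read 5' end with the target fragment downstream; miR-last is the
reverse. miR-first chimeras are ligase-dependent and track miRNA abundance,
so downstream analyses use them by default (`mir_last_downstream = FALSE` in
`run_pipeline()`).

## Pipeline overview

1. **Read preparation** (`demultiplex_and_trim()`, `collapse_duplicates()`):
   exact 5'-index demultiplexing, 3'-adapter removal (full-length adapter
   occurrences tolerate one mismatch, terminal overlaps of at least 6 nt
   must be exact), an 18-nt minimum insert, and PCR-duplicate collapse by
   full sequence identity within a sample.
2. **Reverse mapping** (`find_mirna_hits()`): each mature miRNA's 5' 8-mer
   is searched in every read with at most one mismatch and extended 3' with
   at most two further mismatches. Full-length spanning is required unless
   truncation mode is on, in which case a matched 5' prefix of at least
   12 nt suffices and the missing 3' bases are recorded. Ties between
   miRNAs (usually seed-family members) are resolved by a seeded random
   draw (`resolve_ambiguous()`); the full candidate set is retained for the
   strict family mode.
3. **Flanks and placement** (`extract_flanks()`, `map_target()`): flanking
   fragments of at least 18 nt become chimeras; each fragment is placed on
   the genome (both strands, up to two substitutions) and kept only when a
   single best-scoring locus exists. Fragments overlapping annotated miRNA
   loci are removed.
4. **Interactions** (`cluster_chimeras()`, `define_target_region()`):
   same-miRNA, same-strand chimeras with overlapping coordinates merge by
   transitive closure. The ligation site is the modal fragment 5' end (ties
   resolve upstream); the target region is 75 nt downstream of it, clusters
   of 76--100 nt are trimmed symmetrically, and clusters over 100 nt are
   dropped. Regions are annotated by midpoint overlap with the priority
   3'UTR > CDS > 5'UTR > noncoding > intron > intergenic, and non-chimeric
   read support yields a biological complexity (BC) and a depth-normalised
   density (pseudo-count 1, per-million scale).
5. **Seed annotation, duplex prediction, binding classes, motifs, family
   specificity and perturbation statistics**, described below.

## Seed-match taxonomy

`classify_seed()` searches the reverse complement of miRNA positions 2--8 in
the target region. Canonical classes: 8mer (perfect 2--8 pairing with a
target A opposite position 1), 7mer-m8 (perfect 2--8), 7mer-A1 (perfect
2--7 plus the A) and 6mer (perfect 2--7); the highest class wins and ties go
to the leftmost occurrence. The A is required to be an A, not a complement
of position 1. When no canonical site exists, single-edit variants are
enumerated: one substitution (mm8/mm7/mm6), one extra target nucleotide
between adjacent seed pairings (target bulge, inserted base recorded), or
one bulged miRNA position. The best variant has the most seed pairs, then a
fixed class order (target bulge > mm8 > mm7 > miRNA bulge > mm6), then the
smallest offset (junction proximity motivates this tie-break).

**Wobble policy.** One G:U pair inside an otherwise Watson--Crick site keeps
its canonical class, with the wobbled position reported; all other positions
must pair Watson--Crick. This bound matters: if G:U counted as pairing at
every position, a random 75-mer would contain a "canonical" 6mer with
probability near 20% and a single-mismatch variant almost surely, and the
seedless category would be empty by construction. With the single-wobble
rule the classifier still has an irreducible chance-match floor on random
sequence (mostly single-mismatch 6mers, roughly one region in four at 75
nt), which is why the synthetic generator verifies each planted site's
label against the classifier before accepting it (see below). A
`allow_wobble = FALSE` switch demotes wobbles to mismatches for sensitivity
analyses.

## The duplex model

`hybrid_mfe()` predicts the intermolecular duplex between a miRNA (position
1 trimmed, as it is buried in AGO and does not pair) and a target region of
at most 100 nt. A structure is a strictly monotone, antiparallel set of
pairs -- no intramolecular pairing, no branching, no pseudoknots.
Consecutive pairs are scored with a 6x6 nearest-neighbour stacking table
over {A:U, U:A, C:G, G:C, G:U, U:G}; interruptions cost affine bulge
(one-sided) or interior-loop (two-sided) penalties, with at most 15
unpaired nt per side between consecutive pairs (`max_bulge`), matching the
75-nt region scale. Closing A:U or G:U pairs pay a terminal penalty. An
optional per-pair term (`pair_bonus`, default 0) is included; setting it to
-1 with all other terms zeroed turns the optimiser into a
longest-noncrossing-complementary-subsequence solver, which the test suite
exploits as a combinatorial cross-check.

The shipped stacking values (`inst/extdata/energy_params.tsv`,
`default_energy_params()`) approximate Turner-style RNA parameters in
kcal/mol. Two deliberate deviations: the mildly positive G:U-on-G:U stacks
of published tables are clamped to small negative values so that every
stack is stabilising, and no duplex-initiation term is used. Numeric
equality with any external folding program is not claimed; correctness is
established against exhaustive enumeration of all non-crossing pairings on
short sequences, and the parameter file is a documented, swappable
interface.

**Constraints.** Canonical sites force the annotated seed helix at its
matched offset (8mer/7mer-m8: positions 2--8; 7mer-A1/6mer: 2--7; a "5mer"
option covers 2--6); anchoring at the matched site is the only
interpretation consistent with near-complete concordance between motif and
structure. Mismatch and bulge sites trigger two runs with positions 3--4 or
5--6 forced paired, keeping the lower-energy structure. Seedless regions
fold unconstrained. Unconstrained folding returns an empty structure at
0 kcal/mol when no negative-energy duplex exists; constrained folding
returns the constrained optimum regardless of sign (otherwise a forced seed
could silently vanish), and an infeasible constraint yields an empty
structure flagged `feasible = FALSE`.

## Binding classes

Binary pairing profiles (1 = paired by Watson--Crick or G:U) over positions
2..Lmax form the rows of `structure_matrix()`; positions beyond a shorter
miRNA are NA and excluded from distances via a column mask rather than
imputed. `kmeans_structures()` runs Euclidean k-means (equivalent to
Hamming on binary rows) with k-means++ seeding and 50 restarts,
deterministic given its seed; classes are relabelled by descending mean
seed pairing so that labels are stable across runs and row orders.
`sweep_k()` reports inertia and mean silhouette over k = 3..12 and never
auto-selects k -- the choice is the analyst's. Inertia monotonicity across
the sweep is guaranteed by warm-starting each k from the previous solution
plus its worst-fitting row. Per-miRNA class preferences use two-sided
Fisher tests on 2x2 tables with no multiple-testing correction by default
(a fixed significance threshold is the convention here; Benjamini-Hochberg
is available).

## Motif confidence

For each miRNA with at least 50 chimeras and 40 sites, 7-mer
presence/absence in its target regions is compared against five-fold
backgrounds drawn from other miRNAs' regions (same-seed paralogues
excluded; three independent draws) by a one-sided hypergeometric test.
Candidates within Hamming distance 1 or a single-offset shift of a
better-ranked candidate are suppressed; survivors are refined into
position-frequency matrices from their (<=1 mismatch) foreground
occurrences. The match score `s` is the maximum over ungapped offsets of
the mean per-column probability of the base complementary to the miRNA --
a normalised quantity in [0, 1], fixed here because the original tool's
score is undocumented. Information content uses log2 against a uniform
background. The combined confidence is

c = (-log10(p) - 10) / 10 + (s - 0.35) * 6.7,

and motifs are retained when s >= 0.35, IC/bp >= 1.75 and c >= 1. With
foregrounds resampled from the background pool, seven iterations retain
nothing (a calibration the acceptance suite re-runs).

## Family specificity

Seed families are defined by identical positions 2--8 computed from the
catalogue. `strict_assignment()` repeats reverse mapping with zero
mismatches and discards reads whose candidate set still spans more than one
miRNA. `pairwise_mfe()` folds every member's target regions against every
member without seed constraints and applies one-tailed Welch t-tests
(variance pooling is unstated in the underlying convention; unequal
variances are the safer default) to ask whether cognate duplexes are more
stable than cross-paralogue ones; mean gaps above 6 kcal/mol are flagged as
strong specificity. Cross-member folding uses each owner's regions
verbatim. Member-specific motifs (lengths 6, 8, 10, 12) are mapped back to
the divergent 3' sequence and displayed reverse-complemented so they read
along the miRNA.

## Perturbation statistics

Probe-level log2 fold-changes collapse to genes after removing genes with
sign-contradictory probes. Gene sets (single vs multiple chimera support,
peak overlap, canonical-only vs non-canonical-only transcripts -- mutually
exclusive at the transcript level, with a bulged-8mer subset) are compared
with control genes (chimeras of other miRNAs only) by two-sample
Kolmogorov--Smirnov tests. For inhibitor designs, clusters require BC >= 4
and a normalised density >= 40 (the density threshold applies to the
pseudo-counted per-million value; the scale is stated in output headers),
and "7-8mer seeds" means {8mer, 7mer-m8, 7mer-A1}, excluding 6mers.

## The synthetic generator

`simulate_experiment()` builds a complete experiment with ground truth:
random genomes (uniform base composition; no repeat structure), a gene
layout with UTRs, a split CDS, introns and noncoding genes, miRNA hairpin
loci embedded in intergenic space, and a catalogue with seed families whose
members share positions 1--12 and diverge 3' of them. Default conditions
encode the emulated biology: miR-first chimeras at 3% of reads in
ligase-treated samples (6 of them) and 10-fold fewer in the 2 no-ligase
samples; miR-last at 1/14 the miR-first rate irrespective of ligase;
truncations mostly 0 or 1 nt; a seed-class mixture with ~45% canonical,
35% mismatch+bulge and 20% seedless sites; six binding archetypes (seed
only; seed + 13--16; seed + extended 3'; seedless 3'-centric; bipartite;
tripartite); 100-nt reads with a 5-nt sample index and the standard
pre-adenylated 3' adapter; 0.2% uniform substitution errors; ~25% PCR
duplicates. The contaminant genome shares no exact 20-mer with the primary
one, making the false-ligation estimate identifiable. Planted sites are
verified against `classify_seed()` before acceptance so that every truth
label is true of its sequence; without this, the chance-match floor on
random backbones would mislabel a fraction of "seedless" and "bulge"
sites. Problem sizes used throughout the tests (50,000 reads, 400 sites,
two 120-kb chromosomes; 8,000 reads for the cached suite fixture; 3,000
pairing vectors for class recovery) were chosen once as the smallest
scales at which the statistical contrasts of interest are comfortably
resolved.

What passing tests on this generator do *not* show: performance on real
genomes with repeats and paralogous loci (unique placement is much harder
there), non-uniform ligation biases, structured RNA accessibility effects,
or adapter chemistry artefacts beyond single substitutions.

## Numerical choices and degenerate inputs

* Reverse-mapping ties break by fewest mismatches, then longest span, then
  a seeded uniform draw; the draw is reproducible and recorded.
* In truncation mode the matched span is extended greedily within the
  mismatch budget and then trimmed back to end on a matching base; a
  1-nt-truncated miRNA whose first flank base happens to match the missing
  miRNA base is recorded as full-length -- an irreducible ambiguity.
* `map_target()` uses exact 12-mer prefix anchoring with bounded-mismatch
  extension, plus an exhaustive fallback for fragments the anchored pass
  leaves unplaced or imperfectly placed, so overall sensitivity equals a
  full Hamming scan.
* Interval clustering merges only on true overlap (>= 1 bp); book-ended
  intervals stay separate. Ligation-site ties resolve to the most upstream
  position on the strand, and the choice is recorded per interaction for
  audit.
* Shuffled-assignment nulls use a derangement (no region keeps its own
  miRNA), repaired deterministically from a seeded permutation. A
  degenerate input in which every interaction shares one miRNA makes the
  shuffle a no-op and returns p = 1 rather than failing.
* The identical-twin paralogue comparison returns p = 0.5 directly (the
  t statistic is 0/0 on identical samples).
* k-means restarts that empty a cluster are discarded and repeated;
  centroid jitter of 1e-9 avoids degenerate duplicate-centre starts.

## Known limitations

* The duplex model ignores target-side intramolecular structure and
  accessibility, ensembles and suboptimal structures; energies are
  comparative, not thermodynamically calibrated.
* Spliced (intron-spanning) target fragments are not placed; indels are not
  modelled at the mapping stage (they are modelled at the seed-annotation
  and duplex stages).
* BC here is computed from non-chimeric read support per biological
  sample -- a simplified stand-in for a dedicated peak caller, which is out
  of scope.
* The single-edit taxonomy has a chance-match floor on random sequence
  (mostly mm6); interpretation of variant-class frequencies should always
  be against a shuffled or background control, as the motif and CDF
  modules do.
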