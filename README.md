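# chimeraCLIP

Analysis of chimeric Argonaute (AGO) CLIP sequencing reads: from raw
multiplexed FASTQ to unambiguous miRNA–target interactions and, from there,
to the pairing rules that govern each miRNA's targeting.

## Who this is for, and what it does

Protocols that ligate a miRNA to its bound target inside purified AGO
complexes (CLEAR-CLIP, CLASH) produce *chimeric* reads: a mature miRNA and a
fragment of its target joined at a ligation junction. Each such read names
both partners of one binding event — something conventional AGO CLIP cannot
do. chimeraCLIP implements the full computational path for such experiments:

- **Read preparation** — sample-index demultiplexing, 3′-adapter trimming,
  PCR-duplicate collapse.
- **Chimera detection** — "reverse mapping" of mature miRNAs into reads
  (≤1 mismatch in the 5′ 8-mer, ≤2 in the extension; optional 3′-truncation
  mode with a 12-nt minimum prefix), flank extraction (miR-first /
  miR-last), unique genomic placement of target fragments, miRNA-locus
  filtering, and false-ligation estimation from genome-mixing designs.
- **Interaction map** — clustering of same-miRNA chimeras into
  interactions with 75-nt target regions, transcript-region annotation, and
  non-chimeric read support (biological complexity, normalised density).
- **Seed taxonomy** — 8mer / 7mer-m8 / 7mer-A1 / 6mer, single-mismatch and
  single-bulge variants, G:U wobble tracking, junction-offset CDFs,
  positional preference profiles.
- **Duplex model** — constrained intermolecular minimum-free-energy
  structures from a nearest-neighbour dynamic program (seed helix forced at
  annotated sites), binary pairing profiles, shuffled-assignment nulls.
- **Binding classes** — k-means over pairing profiles with deterministic
  seeding and per-miRNA Fisher enrichment.
- **Motif confidence** — de-novo enriched 7-mers with a miRNA
  complementarity score `s`, information content, and the combined
  confidence `c = (−log10(p) − 10)/10 + (s − 0.35) × 6.7`, retained at
  `s ≥ 0.35`, `IC/bp ≥ 1.75`, `c ≥ 1`.
- **Family specificity** — strict zero-mismatch assignment, pairwise
  cross-MFE comparisons and member-specific 3′-end motifs for seed-family
  paralogues.
- **Perturbation response** — probe collapsing, Kolmogorov–Smirnov CDF
  comparisons by site class, AGO-binding-change analysis for inhibitor
  experiments.
- **Synthetic experiments** — a fully specified generator (genomes,
  annotations, miRNA families, multiplexed reads with planted chimeras and
  archetypes, expression tables) with byte-reproducible ground truth.

The methods vignette (`vignettes/chimera-pairing-analysis.Rmd`) documents
the models, parameter defaults and numerical choices.

## Worked example

```r
library(chimeraCLIP)

sim <- simulate_experiment(sim_config(reads_total = 8000L, n_sites = 150L,
                                      rng_seed = 42L))
res <- run_pipeline(sim$reads, sim$sheet, sim$catalog, sim$genome,
                    sim$annotation, rng_seed = 7L)
res$accounting
#>         input      assigned    unassigned dropped_short     collapsed
#>          8025          7969            56             0          4639
#>      chimeras       aligned  interactions
#>           132           132            60
round(res$rates$ligase_enrichment, 2)
#> miR_first  miR_last
#>     12.73      2.18
```

8,025 reads demultiplex into 8 samples (56 unassigned), collapse to 4,639
unique inserts, and yield 132 chimeras that place uniquely on the genome,
clustering into 60 interactions. miR-first chimeras are ~13-fold enriched
in ligase-treated over no-ligase samples (the planted enrichment is 10;
the small no-ligase samples make this estimate noisy), the hallmark that
they are genuine ligation products.

```r
ann <- classify_seeds(res$interactions, sim$catalog)
table(ann$class)
#>    6mer 7mer-A1 7mer-m8    8mer bulge_mirna bulge_target  mm7  mm8 none
#>       6       9       6       5           3            8    7    8    8

dup <- predict_duplexes(res$interactions[1:5, ], sim$catalog,
                        seed_ann = ann[1:5, ])
dup$structures[[1]]
#> miRNA-target duplex: mfe = -14.15 kcal/mol, 14 paired positions,
#> constraint = seed_forced
#> ||||||..|||....|||||
```

Canonical classes, single-edit variants and seedless sites appear in the
planted proportions, and the first interaction folds into a seed-anchored
duplex at −14.15 kcal/mol whose pairing string (positions 2..L) shows the
seed helix plus 3′ auxiliary pairing.

A thin command-line front end (`exec/chimeraclip`) exposes the same steps
as `simulate`, `detect`, `seeds`, `duplex` and `classes` subcommands over
standard FASTA/FASTQ/TSV/BED files.

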