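# barcodeOTU

DNA-barcode species delimitation and diversity analysis for cryptic species
complexes, built around the workflow used to resolve whitefly (*Bemisia
tabaci*-type) complexes from mitochondrial COI sequences. The package is
aimed at molecular ecologists and entomologists who have COI barcode
(COI-5′) and/or COI-3′ sequence surveys plus specimen metadata, and who want
a reproducible path from raw FASTA files to delimited operational taxonomic
units (OTUs), species translations, diversity statistics, haplotype networks
and distribution tests.

## What it computes

* **Quality control** — barcode compliance (strictly >500 unambiguous bases
  by default), stop-codon/gap screening under the invertebrate mitochondrial
  genetic code, and a frame-anchored alignment of indel-free coding
  sequences.
* **Kimura 2-parameter distances** with full transition/transversion
  bookkeeping. For proportions of transitions *P* and transversions *Q* at
  comparable sites,

  d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q),

  computed under pairwise deletion; saturated pairs are flagged undefined,
  never clamped. Barcode-gap diagnostics: distance histograms, ranked
  distances, intra/inter summaries.
* **OTU delimitation** — single-linkage clustering at a distance threshold
  (default 0.02 for COI-5′ OTUs, 0.035 for COI-3′ species), per-cluster
  summaries (max intra, nearest-neighbour distance, hosts, countries),
  majority-rule consensus barcodes with IUPAC ties, assignment of query
  sequences to a species reference panel with novel-lineage flagging, and a
  COI-5′ ↔ COI-3′ translation table.
* **Population genetics** — haplotype collapsing under complete deletion and
  the standard indices: segregating sites S, singletons Eta(s), mean
  pairwise differences k, nucleotide diversity π, haplotype diversity Hd,
  Tajima's D, and Fu's Fs computed in log space through unsigned Stirling
  numbers of the first kind (stable for samples in the hundreds).
* **Haplotype networks** — minimum spanning trees over nucleotide
  differences with deterministic tie-breaking, co-minimal alternative edges
  reported, and nodes annotated by country composition.
* **Phylogenetics** — Fitch parsimony scores, random-addition + NNI
  parsimony search (exhaustive for ≤9 taxa), bootstrap support, a
  neighbour-joining companion tree, and Newick I/O.
* **Geography** — species-by-region composition tables, Pearson chi-square
  heterogeneity tests, and presence/absence range comparison between
  surveys.
* **Synthetic data** — a finite-sites Kingman-coalescent simulator with a
  transition/transversion rate bias, deeply divergent cluster ancestors,
  country labels and an optional linked second marker, with full ground
  truth, so every stage is testable without any external data.

## Worked example

Simulate a five-species survey with a linked COI-3′ marker and run the full
pipeline:

```r
library(barcodeOTU)

cfg <- synthetic_config(K = 5, n_per = 10, L = 600, theta = 2,
                        d_between = 0.1, dual_marker = TRUE, seed = 505)
ds  <- emit_dataset(cfg, "survey")

rc <- run_config(coi5_fasta  = "survey/coi5.fasta",
                 metadata    = "survey/metadata.tsv",
                 coi3_fasta  = "survey/coi3.fasta",
                 panel_fasta = "survey/panel_coi3.fasta",
                 coi5_threshold = 0.05, seed = 7)
res <- run_pipeline(rc, "survey_out")

res$partition
#> OTU partition: 5 cluster(s) over 50 sequences at threshold 0.05
summarize_distances(res$distances)[c("min", "max", "mean")]
#> $min  [1] 0
#> $max  [1] 0.1065187
#> $mean [1] 0.0748792
res$translation[, c("coi5_cluster_id", "coi3_species", "status")]
#>   coi5_cluster_id coi3_species   status
#> 1          C1_S01    species_1 assigned
#> 2          C2_S01    species_2 assigned
#> 3          C3_S01    species_3 assigned
#> 4          C4_S01    species_4 assigned
#> 5          C5_S01    species_5 assigned
```

The five generated clusters are recovered exactly (each well below the
threshold internally, separated by ~10% divergence), and each COI-5′ cluster
is translated to its true species through its COI-3′ representatives. The
output directory contains the QC report, long-form distance matrix and
histogram, OTU partition, per-cluster summaries, consensus barcodes,
translation table, diversity report, per-species haplotype network edge/node
tables, a parsimony tree in Newick, composition counts, a run log and a
manifest with the configuration hash.

Statistics can equally be used directly, e.g. Tajima's D and Fu's Fs from a
sample of n = 22 sequences with S = 15, k = 1.82 and 8 haplotypes:

```r
tajimas_d(S = 15, k = 1.82, n = 22)   # -2.010823
fus_fs(n = 22, k_obs = 8, theta = 1.82)  # -2.293096
```

A thin command-line wrapper over the same pipeline lives at
`inst/scripts/barcode_pipeline.R`.

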