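---
title: "Methods: barcode-based delimitation, diversity and networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode-based delimitation, diversity and networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeOTU)
```

## The problem

Morphologically indistinguishable but reproductively isolated lineages —
cryptic species complexes — are common in insect pests such as whiteflies.
Two mitochondrial COI regions carry most of the taxonomic signal: the 5′
"barcode" region used by barcode reference libraries, and the 3′ region on
which the historical nomenclature of several complexes rests. This package
implements the complete analysis path for such surveys: quality-controlled
barcodes are clustered into OTUs, OTUs are translated to named species
through COI-3′ representatives, and within-species variation is summarised
by diversity indices, neutrality tests, haplotype networks and
species-by-region composition tests.

## Sequence QC and alignment

COI amplicons from a single primer pair are indel-free protein-coding
fragments. QC therefore consists of (i) a barcode-compliance length filter —
strictly more than `min_len` (default 500) unambiguous A/C/G/T bases;
ambiguity codes and N do not count toward the length but are retained — and
(ii) a translation screen under the invertebrate mitochondrial genetic code
(NCBI table 5, from `Biostrings`): any gap character or internal stop codon
(TAA/TAG; TGA is tryptophan) fails the record. Frame `"auto"` picks the
lowest stop-free offset and warns when several qualify, since for typical
fragment lengths a wrong frame almost surely contains a stop.

Because the QC rejects gapped sequences, column homology does not require
progressive multiple alignment. `build_alignment()` slides each record
ungapped against the longest record to the offset with the most base
matches, then trims to the intersection window (or pads flanks with N).
For homologous indel-free fragments this is exact, and it removes a
heavyweight alignment dependency. Degenerate input — records with no
overlapping window — is an error rather than a guess.

## Kimura 2-parameter distances and the barcode gap

With transition proportion $P$ and transversion proportion $Q$ over the
sites where both sequences carry an unambiguous base (pairwise deletion),

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).$$

Two numerical choices matter:

* **Pairwise deletion** is the default (the usual default of
  distance-matrix software); complete deletion can be emulated upstream by
  masking columns. The choice is exposed because published tables rarely
  state it.
* **Saturation is flagged, never clamped.** When $1-2P-Q \le 0$ or
  $1-2Q \le 0$ the logarithms are undefined; such pairs are recorded in
  `undefined_pairs` and excluded from summaries (with their count
  reported). Clamping to a ceiling would manufacture spurious structure in
  exactly the region of the distance distribution where the barcode gap is
  read.

The matrix is computed via indicator-matrix cross products, so an
$n \times L$ alignment costs a handful of dense matrix multiplications
rather than $O(n^2)$ string scans. Distance histograms use half-open bins
$[kw, (k+1)w)$; percent values in exported tables are rounded to one
decimal while internal values keep full precision.

## OTU delimitation and species translation

OTUs are single-linkage clusters at a K2P threshold: the transitive closure
of $d \le t$. Single linkage is a transparent, documented proxy for
BIN-style clustering engines; counts can therefore differ from
registry-assigned BINs on real data, and prior BIN labels can be supplied
through metadata instead. Defaults: $t = 0.035$ for COI-3′ (the established
species delimitation distance for the whitefly complex) and $t = 0.02$ for
COI-5′ OTUs, motivated by the observation that intraspecific barcode
distances overwhelmingly fall below 2%. Undefined pairs are treated as
exceeding any threshold. Cluster labels are deterministic (lexicographically
smallest member id), and raising the threshold can only coarsen the
partition — a property the tests exercise.

Consensus barcodes take the strict per-column majority among A/C/G/T,
resolve ties with the minimal covering IUPAC code, and emit N for
all-missing columns; when a column contains only ambiguity codes their base
sets are unioned, which makes the operator idempotent. Assignment of a
query to a species reference panel reports the distance to every consensus;
status is `assigned` at $d_{\min} \le t$, `novel` above it (the distance is
always reported so a stricter novelty margin can be applied), and
`unresolved` on exact ties — a tie is never silently broken. In the
translation table, several COI-5′ clusters may map to one species
(many-to-one is biologically expected); representatives of one cluster
mapping to different species raise a loud conflict error naming both,
because that situation indicates either contamination or a threshold
problem that should not be averaged away.

## Diversity indices and neutrality tests

All population-genetic statistics use complete deletion by default: any
column with a missing or ambiguous symbol in any sequence is dropped, and
haplotype identity is defined on the retained columns (so two sequences
differing only at dropped columns are one haplotype — a documented
consequence of the policy). On $L$ retained columns with $n$ sequences:

* $S$ = polymorphic columns; Eta(s) = biallelic columns whose minor allele
  occurs once.
* $k$ = mean pairwise nucleotide differences, computed from haplotype
  counts ($\sum_{i<j} c_i c_j h_{ij} / \binom n2$), algebraically identical
  to the direct pairwise mean; $\pi = k/L$.
* $Hd = \frac{n}{n-1}\,(1 - \sum p_i^2)$ over haplotype frequencies.
* Tajima's $D = (k - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}$ with the standard
  sample-size constants; $S = 0$ yields an undefined (NA) value rather
  than zero.
* Fu's $F_s = \ln\!\big(S'/(1-S')\big)$ where
  $S' = \Pr(K \ge k_{\mathrm{obs}} \mid \theta)$ under the Ewens sampling
  formula with $\theta$ taken as the observed $k$ (the $\pi$-estimator).
  The allele-count probabilities require unsigned Stirling numbers of the
  first kind, which overflow catastrophically for realistic sample sizes;
  the whole computation therefore runs in log space (`stirling_log_row()`
  with log-sum-exp folds). Rows exponentiate to the exact integers for
  small $n$, which the tests verify, and samples of several hundred
  sequences evaluate stably. $k_{\mathrm{obs}} = 1$ gives $S' = 1$ and an
  undefined $F_s$, reported as NA.

A practical consequence: because $D$ and $F_s$ are deterministic functions
of printed table inputs $(n, S, k, k_{\mathrm{obs}})$, published diversity
tables can be re-derived without the underlying sequences, which the
acceptance script does.

## Haplotype networks

Networks are pure minimum spanning trees over integer nucleotide
differences between haplotypes (no median vectors — inferred intermediates
belong to median-joining methods, which are out of scope). Kruskal's
algorithm runs under a deterministic ordering (weight, then lexicographic
node pair) so output is reproducible, and every non-tree edge whose weight
equals the maximum tree-edge weight on the cycle it closes is reported as a
co-minimal alternative: displayed MSTs among ties are arbitrary, and the
ambiguity should be visible rather than hidden. Nodes carry haplotype
frequencies and a two-country classification (first-only / second-only /
shared / unknown), mirroring the usual display encoding of two-country
surveys.

## Parsimony trees

`fitch_length()` counts minimum state changes with IUPAC bitmasks, so
ambiguity codes and missing data act as partial/wildcard states that never
force a change. Scores are unrooted; the implementation folds children
sequentially, which at the basal trifurcation of an unrooted binary tree
equals binary Fitch rooted on one of that node's child edges. Site patterns
are compressed before scoring. The search uses random-addition starting
trees (stepwise insertion at the best edge) followed by NNI hill-climbing,
repeated over `n_starts`; for up to 9 taxa every unrooted topology is
enumerated instead, guaranteeing the optimum. The datasets this package
targets — consensus sequences of 15–36 clusters — are small enough that
this simple search reliably finds equal-score optima, which is the
scientific object of interest; elaborate search metaheuristics are
deliberately not reimplemented. Bootstrap support resamples columns with
replacement and reports the percentage of replicate best trees containing
each bipartition of the reference tree (values below 50 are conventionally
hidden in figures but are reported here). A neighbour-joining companion
tree (via `ape`, negative branches clamped to zero with a warning) provides
a distance-based cross-check; Bayesian inference is out of scope.

## The synthetic-data generator

The generator emulates the structure such surveys actually show:

* $K$ deeply divergent clusters. Ancestors sit on a star phylogeny so the
  expected pairwise divergence between any two is exactly `d_between`
  (substitution events per site); a star keeps that quantity directly
  controllable. Default `d_between = 0.1`, inside the observed
  nearest-neighbour range (1–17%).
* Within-cluster variation from a neutral constant-size Kingman coalescent
  with $E[S] = \theta a_1(n)$ and $E[k] = \theta$. Default
  $\theta = 2$ on $L = 600$ bp gives $\pi \approx 0.003$, matching the
  within-species diversities such surveys report, and produces one dominant
  haplotype with a tail of rare ones (the observed frequency spectrum).
* Finite-sites mutation with transition/transversion rate ratio
  $\kappa = 4$ (typical insect mtDNA), so the K2P machinery is genuinely
  exercised; $\kappa = 0.5$ recovers the Jukes–Cantor limit, used as a test
  oracle.
* Coding-frame integrity: ancestors are built from non-stop codons, and a
  mutation that would create a frame-0 stop is relocated to a fresh random
  site rather than rejected, preserving the per-branch event count so
  $E[S]$ stays unbiased.
* Country labels drawn from stated weights (default 70/30 across two
  countries) with province labels nested inside, giving shared-haplotype
  structure across countries; and an optional second linked marker evolved
  independently on the *same* genealogy, with the true species panel
  emitted alongside, so the dual-marker translation can be checked against
  ground truth.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: recombination (absent in animal mtDNA but
also absent here by construction), selection and demographic change (so
neutrality tests centre on zero by design), migration structure beyond
random country labels, sequencing error, length variation and chimeras.
Real surveys also contain lineage-specific rate variation that a single
$\kappa$ does not capture.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated data:
1000 neutral-coalescent replicates at $n = 50$, $\theta = 5$, $L = 600$ for
parameter recovery; a $K = 5$, 10-sequences-per-cluster survey for
delimitation and translation recovery; exhaustive oracles at ≤7 network
nodes, ≤9 parsimony taxa and $n \le 12$ for exact Ewens computations. These
sizes were chosen to exercise every code path at full statistical strength
on a single CPU. All stochastic entry points take explicit seeds, use only
R's integer RNG contract, and regenerate byte-identical FASTA/TSV artifacts
for a fixed configuration; the pipeline writes a config hash and per-file
checksums in its manifest.

## Known limitations

* Single-linkage threshold clustering is a proxy for registry BIN
  assignment, not a re-implementation; on borderline clusters the counts
  can differ.
* The full recursive barcode-gap partition inference of ABGD is out of
  scope; only its histogram and ranked-distance diagnostics are provided.
* $D$ and $F_s$ are reported without simulation-based significance bounds.
* Alignment by frame anchoring assumes indel-free fragments of one locus;
  it is not a general-purpose aligner.
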