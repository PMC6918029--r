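---
title: "Comparative genomics, gene-sharing networks, virome recruitment and integration-site detection for phage genomes"
author: "phagenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genomics, gene-sharing networks, virome recruitment and integration-site detection for phage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagenomics)
```

# Scope and model

`phagenomics` implements the computational workflow used to characterize
newly isolated bacteriophages relative to the known phage world, and to
place them in environmental sequence data:

1. **Homology engine** — affine-gap Smith-Waterman local alignment under
   BLOSUM62, Karlin-Altschul bit scores and E-values, and a six-frame
   translated search of nucleotide reads against protein databases.
2. **Comparative genomics** — homolog calling between annotated genomes
   (amino-acid identity >= 30%, alignment coverage >= 50%, E-value
   <= 1e-3, all inclusive) and the genome-by-genome shared-gene
   percentage matrix.
3. **Gene-content network** — all-vs-all protein graph (E <= 1e-5,
   bitscore >= 50), Markov clustering (MCL) into protein clusters,
   hypergeometric genome-genome similarity, and MCL again on the genome
   graph to delimit viral clusters (approximately genus-level groups).
4. **Fragment recruitment** — the four-step reciprocal best-hit
   classification of virome reads onto focal phage genomes with
   group-level RPKM normalization, plus a single-pass best-hit mode for
   very large read sets.
5. **Integration-site detection** — mapping reads from a lysogen against
   phage and host, collecting phage-host hybrid (junction-spanning)
   reads, and reconstructing attL/attR with their shared core sequence.
6. **Synthetic data** — generators for annotated genomes, diverged genome
   families, truth-labeled viromes and planted lysogens, so each stage
   above is testable end to end with known ground truth.

All coordinates are 0-based half-open internally and 1-based inclusive in
every human-readable output (tables, FASTA deflines, call objects).
Translation uses the standard bacterial genetic code.

# The homology engine

Every downstream module consumes `ProteinHit` tables produced by
`homology_search()` (or read from BLAST/DIAMOND "outfmt 6" files with
`read_hits()`, whose 12-column dialect we write and read losslessly at
printed precision).

The aligner is an exact affine-gap Smith-Waterman: a gap of length $k$
costs $11 + k$ under BLOSUM62, the standard gapped parameterization, and
the score statistics use the published gapped Karlin-Altschul constants
$\lambda = 0.267$, $K = 0.041$:

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad
E = m\,n\,2^{-S'}$$

with the effective search space taken as the plain product of the query
length $m$ and the total subject residue count $n$, without edge
correction.  This is deliberate: the thresholds this package applies
(identity/coverage/E-value cut-offs of the comparative and recruitment
stages) are coarse, and a simple, fully documented statistic is more
valuable here than bit-for-bit agreement with any particular external
search tool, which we do not attempt.

In translated mode the query reads are translated in all six frames,
peptides are split at stop codons, and fragments shorter than 10 amino
acids are discarded — fragments that short cannot clear the 40-bit
screening threshold, so removing them only saves time.  Alignment
coverage is measured on the query (for reads, on the translated
fragment), which follows the common tabular convention; note that a
subject-relative reading of "coverage" would make the homolog rule
slightly stricter for short queries.

A k-mer prefilter (k = 4) precedes full dynamic programming: a subject is
aligned only when a cluster of shared 4-mers on nearby diagonals spans at
least two non-overlapping words.  The prefilter loses essentially nothing
at the identity levels where the package's thresholds operate (two exact
non-overlapping 4-mers on one diagonal are expected many times over for
genuine homologs at >= 40% identity over typical protein lengths), and it
reduces the all-vs-all and read-screening searches from hours to seconds.
Its sensitivity does decay toward the 30%-identity floor of the homolog
rule, as seed-based heuristics generally do; `prefilter = FALSE` runs the
exhaustive search, and the test suite verifies on oracle problems that
the two modes agree wherever results clear the reporting thresholds.
The aligner itself is validated against an independent brute-force
dynamic-programming implementation (exact score equality on hundreds of
seeded random peptide pairs, including gapped cases).

# Comparative genomics

`call_homologs()` applies the inclusive three-part homolog rule and keeps
the best supporting hit per unordered gene pair.  For the shared-gene
matrix, the percentage for a pair (A, B) is the larger directional shared
count divided by the smaller genome's gene count.  The denominator is a
genuine design choice — nothing in the underlying definition of "shared
genes" dictates min, mean or query-relative normalization — so the
choice is recorded in the result object and configurable
(`denominator = "min" | "mean" | "query"`); `min` keeps the matrix
symmetric and yields 100% for a genome nested in a larger relative,
which matches how shared-gene heatmaps are usually read.  Directional
counts are preserved alongside.

# The gene-content network

Protein clusters are produced by a complete MCL implementation (add
self-loops at each node's maximum incident weight, column-normalize,
then alternate expansion — the matrix square — with inflation —
elementwise power 2, renormalization and pruning of entries below 1e-5 —
until the maximum entrywise change falls below 1e-8).  Clusters are read
off attractor rows, with every node assigned exactly once; overlaps are
resolved by flow mass, then lexicographically, so the partition is
invariant under permutation of the input.  The implementation is
validated against an independent dense-matrix reference implementation
(numpy) on dozens of seeded random graphs, requiring identical
partitions.

Genome similarity is the negative decadic logarithm of the
hypergeometric tail: with genome profiles $A$ and $B$ (sets of protein
clusters) in a universe of $U$ clusters and $c = |A \cap B|$,

$$P = \sum_{i=c}^{\min(|A|,|B|)}
\frac{\binom{|A|}{i}\binom{U-|A|}{|B|-i}}{\binom{U}{|B|}},
\qquad \text{score} = \min(-\log_{10} P,\ 300).$$

No multiple-comparison correction is applied; tool lineages differ on
whether and how to correct, the uncorrected tail is exactly testable
against hand enumeration, and the network cutoff (score >= 1, inclusive)
operates on the same scale either way.  The universe is the number of
protein clusters formed from the genome set under comparison — a
self-consistent, dataset-local definition.  One consequence worth
knowing: if a set of genomes shares *every* cluster in the universe, the
tail probability is 1 and the score 0, so meaningful scores require a
universe larger than any single family (in practice the analysis always
includes multiple groups, which guarantees this).

Viral clusters are MCL partitions (inflation 2) of the genome graph,
with connected components available as a fallback; single-member
partitions are reported as unclustered rather than as clusters.  Using
one clustering algorithm for both the protein and genome stages — rather
than a second algorithm for genomes — keeps the pipeline fully
implemented and oracle-tested; it is a documented divergence from
pipelines that use ClusterONE-style genome clustering.

Environmental contigs enter the network only if they are at least 20 kb
long and share at least 20% of *their own* genes with some single focal
genome (both thresholds inclusive).  The contig-relative reading of the
shared fraction is a choice; a focal-relative reading would admit short
gene-dense contigs more easily.

# Fragment recruitment and RPKM

The reciprocal pipeline mirrors a conservative read-classification
protocol:

1. *Screen*: translated search of each read against the focal phage
   proteins at E <= 1e-3 and bitscore >= 40 (inclusive).
2. *Reciprocal search*: candidates are searched against the combined
   database of focal + background viral + bacterial decoy proteins.
3. *Best-hit filter*: a read is kept for focal genome G only if its
   single best combined hit (highest bitscore; ties broken by lower
   E-value, then lexicographic subject id, for determinism) lies on G.
   Background and decoy entries exist purely to veto — reads are never
   assigned to them.
4. *RPKM*: per phage group, recruited reads divided by the group's mean
   genome size in kb (arithmetic mean over its focal genomes) and by the
   virome size in millions of reads.  A read recruited by several
   genomes of one group counts once.

The single-pass mode (`gov_assign()`) recruits directly onto the focal
proteins at E <= 1e-10 and resolves multi-genome hits by highest
bitscore; ranking by bitscore in the reciprocal step as well keeps the
two modes consistent.

`make_recruitment_scenario()` freezes the synthetic study conditions
used for validation: three independently generated phage groups (two
genomes each, members diverged 0.15 from their ancestor; between-group
identity at the random-protein baseline), genome-copy abundances 5:3:2,
a 30% admixture of host-derived reads, and a bacterial host that donates
three 25%-diverged AMG-like genes to every group.  The AMG transfer is
the scientifically interesting part: it creates exactly the host-phage
homology that makes naive screening assign cellular reads to phages, and
lets the tests demonstrate that the reciprocal step (with the host
present as a decoy) removes those false assignments entirely while its
ablation strictly increases them.  Read weights are proportional to
abundance times genome length, so RPKM — which divides by genome size —
estimates relative genome-copy abundance directly; the validation
requires group assignment accuracy >= 99% and abundance ratios within
10% relative error on a 50,000-read virome, and both hold with wide
margin (observed: 100% accuracy, ~1% ratio error).

# Integration-site detection

Reads are mapped to the phage and the candidate host by exact 12-mer
seeding plus banded local alignment (match 1, mismatch -2, gap -3, band
half-width 8) on both strands, reporting soft-clipped ends.  A read is a
phage-host hybrid when it splits into a host-aligned and a phage-aligned
segment, each >= 20 bp, jointly covering >= 90% of the read and neither
nested in the other; the bases aligned to both references are recorded
as an att-core candidate, and the junction is labeled attL (host before
phage along the host-forward-oriented read) or attR.

Junctions are clustered by host coordinate within +/- 5 bp per side, and
a call requires >= 2 supporting reads on each side.  Each overlap string
is first trimmed to its longest substring that occurs exactly in both
genomes — this removes both sequencing errors and chance alignment
extensions past the true core — and the core is the candidate supported
on both sides with the highest total read support (ties: longer, then
lexicographic), verified against both genomes before attL/attR sequences
are assembled around the verified positions.  The thresholds (min_flank
20, window 5, min_support 2) are not dictated by any external protocol;
they were chosen so that planted-truth recovery is exact at typical
short-read lengths and are all arguments of the calling functions.

The generator plants integrations Campbell-style: the core is read from
the host attB, inserted into the phage at attP (the att-bearing phage is
returned as the detection reference, as a temperate phage's own genome
carries its attP core), and the lysogen is host-left + core + circularly
permuted phage + core + host-right.  The generator also forces the bases
immediately flanking the core to differ between host and phage.  Without
that, the "true" core is ill-defined: whenever host and phage happen to
agree on a flanking base, the biologically identical region extends past
the planted boundary and any correct detector would (rightly) report the
longer core.  Forcing boundary mismatches makes the planted core the
unique maximal identical stretch, so exact-match scoring is meaningful.
Validation plants cores of 10-50 bp and requires exact recovery in 20/20
error-free replicates and >= 95/100 at 1% substitution error, at 20x
coverage of the lysogen.

# Synthetic data: what it does and does not emulate

`generate_genome()` produces gene-dense replicons in the style of a
40-60 kb podovirus genome: uniform-random proteins (leading methionine),
back-translated with synonymous codons weighted as if bases were drawn
independently at the target G+C, separated by short spacers of the same
composition.  Realized G+C tracks the target within about +/-0.02 at
phage-genome scale.  `evolve_genome()` mutates each protein site
independently (to a uniformly chosen different residue, so expected
identity is one minus the divergence), applies independent gene loss and
appends novel genes, then re-back-translates — synonymous sites diverge
too.  `simulate_virome()` draws reads uniformly from weighted genomes
(both strands) with substitution-only errors and full truth labels.
Defaults of 150 bp reads at 0.5% substitution error are stated choices
in the range of short-read virome data, not derived from any particular
data set.

Deliberate non-goals: no codon-usage bias fitting, no realistic phage
gene-content or modular genome architecture, no indel or quality-profile
error models, no reads across the origin (genomes are treated as
linear).  Consequently, passing tests demonstrate correctness of the
algorithms and their thresholds under controlled homology structure —
they do not demonstrate robustness to indel-rich platforms, repeat-rich
genomes, or the composition biases of real viromes, and the
substitution-only error model is the main reason the translated search
can dispense with frameshift handling.

# Numerical and scale choices

* Protein-mode and translated searches cap nothing: all qualifying hits
  are reported, best-per-(query, subject, frame).
* MCL uses sparse matrices; convergence tolerance 1e-8, pruning 1e-5,
  at most 100 iterations (non-convergence returns the current partition
  with a warning; on the graph sizes used here convergence takes far
  fewer).
* Hypergeometric scores are capped at 300 to keep perfect overlaps
  finite.
* Validation problem sizes — 50,000-read viromes, 17-genome networks
  (~1,000 proteins), 120 planted integrations at 20x coverage — were
  chosen as the smallest sizes at which the binomial/multinomial noise
  terms are comfortably below the tolerances being checked, so that the
  checks measure the algorithms rather than sampling noise.

# Known limitations

* E-values are internally consistent but not calibrated to BLAST or
  DIAMOND output; thresholds ported from protocols tuned on those tools
  carry over in spirit, not to the last decimal.
* The seed-based prefilter and 12-mer read mapper can miss remote
  homology (< ~30% identity) and alignments without any exact 12-mer,
  respectively, as all seed heuristics do.
* `call_att()` assumes a single dominant integration site per
  (phage, host) pair within each junction cluster pair; polylysogeny at
  nearby sites would need smaller clustering windows or downstream
  resolution.
* The shared-gene percentage and the contig filter depend on annotation
  completeness of the input gene tables; genes absent from the
  annotation cannot be shared.
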