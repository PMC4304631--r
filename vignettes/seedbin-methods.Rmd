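---
title: "Two-phase composition-based binning: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase composition-based binning: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedbin)
```

## The problem

A metagenomic sequencing run returns reads from many organisms mixed
together, with no labels. Binning asks: partition the reads into clusters
such that each cluster collects the reads of one species (or a group of
closely related organisms). `seedbin` solves the unsupervised variant —
no reference database, only the reads themselves and a target number of
clusters `k`.

The classical compositional signal is the tetranucleotide frequency
profile: long DNA fragments from one genome have a characteristic 4-mer
distribution that differs between species. A single short read
(~80 bp, 77 four-mer windows spread over 136 frequency bins) is far too
noisy to carry that signature. The idea implemented here is to
*reassemble statistical length without assembling sequence*: collect a
set of reads that provably come from one genome, keep only a subset of
mutually non-overlapping reads (so no genomic region is counted twice),
and compute the signature on that subset. Around 9 kb of such reads
recovers a stable genomic signature.

## The two phases

**Phase 1 — overlap grouping and seed construction.** Two reads are
declared *overlapping* when they share at least `m` distinct q-mers
(substrings of length `q`; default `q = 30`, `m = 5` for short reads and
`m = 45` for long reads). For sufficiently large `q`, different genomes
essentially never share a q-mer, so shared q-mers almost always indicate
reads drawn from overlapping positions of the same genome. The reads and
this relation form an unweighted undirected graph `H`. The graph is
partitioned greedily: a random unvisited node starts a group, and the
group grows through the frontier of neighbors (breadth-first, ties by
ascending index). Every admitted node joins the group; it additionally
joins the group's *seed* exactly when it has no edge to any current seed
member — the seed is therefore an independent set, a collection of
mutually non-overlapping reads. Growth stops when the seed's summed read
length exceeds `S_max` (default 9000 bp) or the frontier empties;
un-admitted frontier nodes return to the pool and later form their own
groups.

**Phase 2 — merging groups by seed signature.** Each seed is summarised
by its normalized l-mer frequency vector (default `l = 4`): every
sliding window of length `l` over the seed reads increments the count of
its canonical class (a word and its reverse complement are one class,
since reads come from both strands), and counts are divided by the total
number of windows so entries sum to 1. For even `l` the collapsed space
has `(4^l + 4^(l/2))/2` dimensions — 136 at `l = 4` (the second term
counts reverse-complement palindromes). Groups are then merged into `k`
clusters by Lloyd k-means on these vectors, minimizing the
within-cluster sum of squares
`sum_j sum_{i in C_j} ||f_i - mean(C_j)||^2` with cluster means the
arithmetic average of member signatures. Every read inherits the cluster
of its group.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `q` | 30 | bp | overlap word length; large enough that cross-genome sharing is rare |
| `m` | 5 (short) / 45 (long) | q-mers | evidence threshold for an overlap edge |
| `l` | 4 | bp | signature word length; 136 collapsed dimensions |
| `S_max` | 9000 | bp | seed size cap; the scale at which signatures stabilise |
| `k` | — | clusters | assumed number of species; supplied by the user |
| `max_iter` | 100 | iterations | k-means cap; convergence is bitwise-stable means |
| `restarts` | 1 | runs | optional best-of-n k-means initializations |

`m = 0` is floored to 1: with a literal "at least 0 shared q-mers" every
pair of reads would overlap and phase 1 would collapse into a single
group, so at least one shared q-mer is always required.

## Numerical and algorithmic choices

Several points are deliberately pinned down where the procedure would
otherwise be ambiguous:

- **Shared q-mers are counted as distinct types** (set intersection),
  not occurrence pairs; this is robust to low-complexity repeats within
  a read.
- **Canonical q-mers by default.** Reads are sequenced from either
  strand; collapsing each q-mer with its reverse complement lets
  opposite-strand reads from the same locus be linked. A flag disables
  it for strand-resolved data.
- **Windows containing N are skipped entirely**, both for overlap
  detection and signature counting, and excluded from the normalizing
  total; the model is a strict 4-letter alphabet.
- **Frontier order is FIFO** with ties broken by ascending node index,
  making phase 1 fully deterministic given the RNG seed that picks group
  start nodes. Breadth-first growth also spreads seed reads along the
  genome rather than piling them at one locus.
- **The `S_max` check runs after each seed admission**; when it trips,
  the whole group stops growing and pending frontier nodes return to the
  pool. A closed seed can therefore exceed `S_max` by at most one read
  length.
- **Seed admission tests adjacency against seed members only** (not
  against non-seed members).
- **k-means initialization** draws `k` row indices without replacement
  from the feature matrix; nearest-mean ties go to the lowest cluster
  index; convergence means exactly stable means (`tol = 0`), bounded by
  `max_iter`. If an assignment step empties a cluster, its mean is
  re-seeded with the point farthest from its own cluster mean, so
  exactly `k` clusters always survive.
- **Distances are plain Euclidean** on the normalized frequency vectors;
  no scaling or whitening.
- **Signature coordinates are fixed**: canonical l-mers in lexicographic
  order (1-based in R), so dumped vectors are comparable across runs.

## Evaluation metrics

With `A[i, j]` the number of reads of species `j` in cluster `i`:

- precision `= sum_i max_j A[i, j] / sum_ij A[i, j]` — purity of the
  clusters; unassigned reads are excluded entirely;
- recall `= sum_j max_i A[i, j] / (sum_ij A[i, j] + #unassigned)` —
  cohesion of the species, with unassigned reads penalised in the
  denominator;
- F-measure `= 2 / (1/precision + 1/recall)`.

Reads present in an assignment table but absent from the truth table are
an error, never silently dropped. Both metrics are invariant to
relabeling clusters or species; merging clusters cannot raise precision
and splitting cannot raise recall — the test suite asserts both against
brute-force recomputation.

## What the simulator emulates — and what it does not

`simulate_community()` generates one genome per species from an order-2
Markov chain over A/C/G/T and samples reads uniformly with uniform
strand choice and substitution errors (default rate 0.01, matching
common short-read benchmark designs; read length defaults to 80 bp).
Truth records species, genome and the 0-based sampling interval, so the
*true* overlap relation (same genome, intersecting intervals) is known
exactly — that is what lets the tests measure how well shared q-mers
approximate true overlap.

Random transition matrices use symmetric Dirichlet(0.3) rows: skewed
enough that two independently drawn species have clearly distinct
compositional signatures, standing in for a substantial phylogenetic
distance. Desk-scale genome lengths (kilobases rather than megabases)
are used throughout the tests; they are chosen by coverage: for the
recovery studies with 1000 x 80 bp reads, 8 kb genomes keep even the
rarer species of a 1:4 mixture at roughly 2x coverage, the regime where
overlap grouping still connects reads.

The simulator does **not** reproduce sequencing-technology error
profiles (no indels, no quality-dependent error rates, no chimeras), and
Markov genomes have no repeat families, mobile elements or horizontally
transferred segments. Consequently, a passing test here shows the
algorithm recovers species under its own model assumptions; it does not
bound performance on real libraries, where shared repeats create
cross-genome q-mer edges and real compositional distances between close
relatives are far smaller than between Dirichlet-drawn models.

## Test problem sizes and designed-in study conditions

The packaged checks run at sizes chosen to keep the whole suite fast on
one core while still exercising every code path: oracle equivalence of
the indexed overlap graph against the all-pairs definition at n = 50
reads; k-means against exhaustive 2-partition search at p = 9 vectors;
end-to-end recovery on 1000 error-free 80 bp reads from two 8 kb
genomes, at 1:1 and 1:4 abundance, with `q = 30, m = 5, S_max = 9000,
k = 2` and pinned seeds — the F-measure must reach 0.90; and the
signature observation analogue on 20+ pairs of disjoint 60 x 150 bp
(~9000 bp) read groups, where mean within-genome distance must fall
below mean cross-genome distance.

## Known limitations

- **Invisible small overlaps.** Two reads whose genomic intersection is
  shorter than `q + m - 1` bases (34 bp at the short-read defaults)
  share no q-mer evidence and cannot be linked — or kept out of the same
  seed. Consecutive seed reads along a well-covered genome therefore
  often overlap by a few bases. The truly-overlapping fraction of seed
  pairs scales like `2/(s - 1)` for seeds of `s` reads, which is why the
  seed-purity check is run at the ~9000 bp operating seed size (roughly
  100 x 80 bp reads), where the fraction is a few percent.
- **Small-p k-means fragility.** With only a handful of groups, a lone
  noisy singleton group (one 80 bp read) can sit so far from everything
  that isolating it minimises the within-cluster sum of squares better
  than splitting the species; `k = 2` then returns one merged cluster
  plus the outlier. At realistic group counts the species split
  dominates the objective. The `restarts` option does not cure this —
  it is a property of the objective, not of the initialization — but
  larger samples, or excluding singleton groups from the feature set,
  do.
- **`k` is an input.** The method assumes the number of species is
  known; there is no abundance-based or model-selection estimate of `k`.
- **Uniform coverage assumption in the simulator**; real libraries have
  GC-coverage bias that changes group sizes along the genome.

## A worked desk-scale example

```{r example, fig.width = 7, fig.height = 6}
set.seed(1)
community <- simulate_community(
  list(species_spec("sp1", 8000, abundance = 1),
       species_spec("sp2", 8000, abundance = 1)),
  n_reads = 1000, read_length = 80, error_rate = 0, seed = 1)

fit <- seedbin(community$reads, k = 2, seed = 1)
fit
summary(fit)
evaluate_binning(fit$assignments, community$reads)
plot(fit)
```
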