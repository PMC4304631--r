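# seedbin

Unsupervised binning of metagenomic sequencing reads into species-level
clusters, for researchers analysing mixed-community shotgun data without
reference genomes.

A single short read is too short to carry a usable genomic signature: its
tetranucleotide profile (77 windows over 136 frequency bins for an 80 bp
read) is mostly noise. `seedbin` works around this in two phases:

1. **Overlap grouping.** Two reads *r*, *s* are called overlapping
   (*r* ⊓ *s*) when they share at least *m* distinct q-mers (default
   *q* = 30, *m* = 5 for ~80 bp reads, *m* = 45 for ~700 bp reads); for
   *q* this large, different genomes essentially never share q-mers, so
   an edge almost always means the reads come from overlapping positions
   of one genome. The resulting graph *H* = (*V*, *E*) is partitioned
   greedily into groups *G₁…G_p*. While a group grows, a **seed**
   *S*(*G_i*) — an independent set, i.e. reads no two of which overlap —
   is built alongside and capped at *S_max* = 9000 bp of summed read
   length.
2. **Signature clustering.** Each seed is summarised by its normalized,
   reverse-complement-collapsed l-mer frequency vector
   *f_i* = *h_i* / |G| (136 entries for *l* = 4). Because seed reads do
   not overlap, ~9 kb of them recovers the genome's signature without
   double-counting any region. Groups are merged into *k* clusters by
   Lloyd k-means minimising the within-cluster sum of squares
   Σⱼ Σ_{Gᵢ∈Cⱼ} ‖f^{S(Gᵢ)} − f̄_{Cⱼ}‖², and every read inherits its
   group's cluster.

The package also ships the matching evaluation metrics
(precision = Σᵢ maxⱼ A<sub>ij</sub> / Σ A<sub>ij</sub>,
recall = Σⱼ maxᵢ A<sub>ij</sub> / (Σ A<sub>ij</sub> + #unassigned),
and their harmonic-mean F-measure) and a Markov-chain community
simulator with recorded ground truth, so the whole pipeline can be
exercised and benchmarked at desk scale.

## Worked example

```r
library(seedbin)

set.seed(1)
community <- simulate_community(
  list(species_spec("sp1", 8000, abundance = 1),
       species_spec("sp2", 8000, abundance = 1)),
  n_reads = 1000, read_length = 80, error_rate = 0, seed = 1)

fit <- seedbin(community$reads, k = 2, seed = 1)
fit
#> Two-phase composition-based read binning
#>
#>   reads: 1000   overlap edges: 10832 (q=30, m>=5)
#>   phase 1: 39 groups (seed cap 9000 bp)
#>   phase 2: k=2 clusters, WCSS 0.337267, 11 iterations
#>   cluster sizes: 1:500  2:500

evaluate_binning(fit$assignments, community$reads)
#> precision: 100.00%
#> recall:    100.00%
#> F-measure: 100.00%
```

Two species with divergent order-2 Markov compositions, 1000 error-free
80 bp reads at 1:1 abundance: phase 1 links the reads into 39 groups via
shared 30-mers, phase 2 separates the group seeds' 4-mer signatures into
two clusters of 500 reads each, matching the ground truth exactly.
`summary(fit)` reports group/seed size distributions, `coef(fit)` the
cluster mean signatures, `plot(fit)` the seed signature profiles by
cluster, and `predict(fit, new_reads)` assigns new reads to the nearest
cluster mean.

A command-line interface wrapping the same functions is installed under
`exec/`, with `simulate`, `bin` and `eval` subcommands; assignments and
truth tables are plain two-column TSV.

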