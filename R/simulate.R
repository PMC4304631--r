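#' Describe a synthetic species
#'
#' A species is modelled by an order-`order` Markov chain over
#' \{A,C,G,T\}: the next base depends on the previous `order` bases. The
#' transition matrix has `4^order` rows (contexts in lexicographic order)
#' and 4 columns (A, C, G, T), each row summing to 1. Distinct transition
#' models stand in for phylogenetic distance: the more two models
#' diverge, the more separable the species' oligonucleotide signatures.
#'
#' @param label species label (string).
#' @param genome_length genome length in bp.
#' @param transitions `4^order` x 4 stochastic matrix; when `NULL` a
#'   random model is drawn with each row from a symmetric
#'   Dirichlet(`alpha`) (small `alpha` gives skewed, strongly
#'   species-specific composition; drawn from the current RNG state).
#' @param order Markov order (default 2).
#' @param abundance positive relative abundance weight (default 1).
#' @param alpha Dirichlet concentration for random models (default 0.3).
#' @return list of class `species_spec`.
#' @export
species_spec <- function(label, genome_length, transitions = NULL,
                         order = 2L, abundance = 1, alpha = 0.3) {
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  if (abundance <= 0) stop("abundance must be positive")
  nctx <- 4L^order
  if (is.null(transitions)) {
    g <- matrix(stats::rgamma(nctx * 4L, shape = alpha), nctx, 4L)
    g[g == 0] <- .Machine$double.xmin
    transitions <- g / rowSums(g)
  }
  transitions <- as.matrix(transitions)
  if (!all(dim(transitions) == c(nctx, 4L)))
    stop("transitions must be ", nctx, " x 4 for order ", order)
  if (any(transitions < 0) || any(abs(rowSums(transitions) - 1) > 1e-8))
    stop("transition rows must be non-negative and sum to 1")
  structure(list(label = as.character(label),
                 genome_length = as.integer(genome_length),
                 transitions = transitions, order = order,
                 abundance = abundance),
            class = "species_spec")
}

#' Generate a genome from a species model
#'
#' The first `order` bases are drawn uniformly, then each base is sampled
#' from the transition row of its preceding context.
#'
#' @param spec a [species_spec].
#' @return a nucleotide string of length `spec$genome_length`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "species_spec"))
  L <- spec$genome_length
  o <- spec$order
  if (L < o) stop("genome_length must be at least the Markov order")
  base_int <- integer(L)
  base_int[seq_len(o)] <- sample.int(4L, o, replace = TRUE)
  # context index: 1 + sum_{j} (b_j - 1) * 4^(o - j), rolled incrementally
  ctx <- 0L
  for (j in seq_len(o)) ctx <- ctx * 4L + (base_int[j] - 1L)
  tr <- spec$transitions
  mod <- 4L^(o - 1L)
  u <- stats::runif(L)
  cum <- t(apply(tr, 1L, cumsum))
  for (i in (o + 1L):L) {
    b <- findInterval(u[i], cum[ctx + 1L, ]) + 1L
    if (b > 4L) b <- 4L
    base_int[i] <- b
    ctx <- (ctx %% mod) * 4L + (b - 1L)
  }
  paste(c("A", "C", "G", "T")[base_int], collapse = "")
}

#' Sample reads from a genome with known coordinates
#'
#' Start positions are uniform over the genome, each read's strand is
#' chosen uniformly (the stored sequence is the genome substring or its
#' reverse complement), and each base is substituted with probability
#' `error_rate` by a uniformly chosen different base. True coordinates
#' are always recorded on the forward strand, so two reads truly overlap
#' exactly when their intervals intersect on the same genome. In paired
#' mode each fragment emits two reads, `<id>/1` and `<id>/2`, from the
#' two ends of an insert.
#'
#' @param genome nucleotide string.
#' @param n number of fragments (reads, or read pairs when `paired`).
#' @param read_length read length in bp (default 80).
#' @param error_rate per-base substitution probability (default 0.01).
#' @param label species label recorded in the truth.
#' @param genome_id genome identifier recorded in the truth.
#' @param id_prefix prefix for read ids.
#' @param paired emit read pairs (default FALSE).
#' @param insert_size outer distance between mates in paired mode
#'   (default `3 * read_length`).
#' @return a [read_set] with truth columns filled.
#' @export
sample_reads <- function(genome, n, read_length = 80L, error_rate = 0.01,
                         label = "sp", genome_id = label,
                         id_prefix = label, paired = FALSE,
                         insert_size = 3L * read_length) {
  G <- nchar(genome)
  read_length <- as.integer(read_length)
  if (read_length > G) stop("read_length exceeds genome length")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (n < 1L) stop("n must be >= 1")
  if (paired) {
    insert_size <- max(as.integer(insert_size), 2L * read_length)
    if (insert_size > G) stop("insert_size exceeds genome length")
    frag <- sample.int(G - insert_size + 1L, n, replace = TRUE) - 1L
    start <- c(frag, frag + insert_size - read_length)
    ids <- c(paste0(id_prefix, "_", seq_len(n), "/1"),
             paste0(id_prefix, "_", seq_len(n), "/2"))
  } else {
    start <- sample.int(G - read_length + 1L, n, replace = TRUE) - 1L
    ids <- paste0(id_prefix, "_", seq_len(n))
  }
  end <- start + read_length
  seqs <- substring(genome, start + 1L, end)
  rc <- stats::runif(length(seqs)) < 0.5
  if (any(rc)) seqs[rc] <- reverse_complement(seqs[rc])
  if (error_rate > 0) seqs <- vapply(seqs, mutate_seq, character(1),
                                     rate = error_rate, USE.NAMES = FALSE)
  read_set(ids, seqs,
           truth = data.frame(read_id = ids, species = label,
                              genome = genome_id, start = start, end = end))
}

mutate_seq <- function(seq, rate) {
  L <- nchar(seq)
  hit <- which(stats::runif(L) < rate)
  if (!length(hit)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    alt <- bases[bases != ch[i]]
    ch[i] <- alt[sample.int(3L, 1L)]
  }
  paste(ch, collapse = "")
}

#' Simulate a multi-species read community
#'
#' Generates one genome per species and samples reads in proportion to
#' the species' abundance weights (largest-remainder apportionment of
#' `n_reads`). Defaults mirror common short-read benchmark designs:
#' 80 bp reads with a 1 percent substitution error rate.
#'
#' @param species list of [species_spec] objects.
#' @param n_reads total number of reads (fragments when `paired`).
#' @param read_length read length in bp (default 80).
#' @param error_rate per-base substitution probability (default 0.01).
#' @param paired emit read pairs (default FALSE).
#' @param seed optional integer for a locally-set RNG state.
#' @return list of class `sim_community`: `reads` (a [read_set] with
#'   truth), `genomes` (named character vector), `counts` (reads per
#'   species).
#' @export
simulate_community <- function(species, n_reads, read_length = 80L,
                               error_rate = 0.01, paired = FALSE,
                               seed = NULL) {
  stopifnot(length(species) >= 1L,
            all(vapply(species, inherits, logical(1), "species_spec")))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  w <- vapply(species, `[[`, numeric(1), "abundance")
  counts <- apportion(n_reads, w / sum(w))
  genomes <- vapply(species, generate_genome, character(1))
  labels <- vapply(species, `[[`, character(1), "label")
  names(genomes) <- labels
  parts <- vector("list", length(species))
  for (i in seq_along(species)) {
    if (counts[i] == 0L) next
    parts[[i]] <- sample_reads(genomes[i], counts[i], read_length,
                               error_rate, label = labels[i],
                               genome_id = labels[i],
                               id_prefix = labels[i], paired = paired)
  }
  reads <- do.call(concat_reads, parts[counts > 0L])
  structure(list(reads = reads, genomes = genomes,
                 counts = stats::setNames(counts, labels)),
            class = "sim_community")
}

# integer apportionment by largest remainders; preserves the total
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(left)]] <- base[o[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Do two reads truly overlap?
#'
#' Truth-based overlap: the reads were sampled from the same genome and
#' their recorded intervals intersect. This is the relation the shared
#' q-mer test is meant to detect.
#'
#' @param reads a [read_set] carrying truth.
#' @param i,j read indices.
#' @return logical.
#' @export
true_overlap <- function(reads, i, j) {
  if (is.null(reads$truth)) stop("read set carries no truth")
  t <- reads$truth
  t$genome[i] == t$genome[j] & t$start[i] < t$end[j] & t$start[j] < t$end[i]
}

#' Phase-1 grouping precision
#'
#' The fraction of reads whose group's majority species matches their own
#' species (read-weighted; the convention used to judge how pure the
#' phase-1 groups are).
#'
#' @param groups a `read_groups` list.
#' @param reads a [read_set] carrying truth (or a named species vector
#'   indexed by read position).
#' @return numeric in `[0, 1]`.
#' @export
grouping_precision <- function(groups, reads) {
  sp <- if (inherits(reads, "read_set")) {
    if (is.null(reads$truth)) stop("read set carries no truth")
    reads$truth$species
  } else as.character(reads)
  good <- 0L; total <- 0L
  for (g in groups) {
    tab <- table(sp[g$members])
    good <- good + max(tab)
    total <- total + length(g$members)
  }
  good / total
}

#' Sample a group of mutually non-overlapping reads
#'
#' Draws `n` error-free forward-strand reads from non-intersecting
#' positions of one genome (used to study how well seed signatures
#' approximate genome signatures). Positions are a random choice of `n`
#' disjoint slots.
#'
#' @param genome nucleotide string.
#' @param n number of reads (default 60).
#' @param read_length read length in bp (default 150; 60 x 150 = 9000 bp
#'   per group).
#' @param label,genome_id truth annotations.
#' @param id_prefix prefix for read ids.
#' @return a [read_set] with truth; reads pairwise non-overlapping.
#' @export
sample_nonoverlapping_group <- function(genome, n = 60L, read_length = 150L,
                                        label = "sp", genome_id = label,
                                        id_prefix = label) {
  G <- nchar(genome)
  n <- as.integer(n); read_length <- as.integer(read_length)
  nslots <- G %/% read_length
  if (nslots < n)
    stop("genome too short for ", n, " non-overlapping reads of ",
         read_length, " bp")
  slots <- sort(sample.int(nslots, n))
  start <- (slots - 1L) * read_length
  seqs <- substring(genome, start + 1L, start + read_length)
  ids <- paste0(id_prefix, "_", seq_len(n))
  read_set(ids, seqs,
           truth = data.frame(read_id = ids, species = label,
                              genome = genome_id, start = start,
                              end = start + read_length))
}
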