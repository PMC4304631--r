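#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences over A/C/G/T.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement(c("AAAA", "ACCC", "GCGC"))
#' @export
reverse_complement <- function(x) {
  if (length(x) && any(grepl("[^ACGT]", x)))
    stop("reverse_complement requires sequences over {A,C,G,T}")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical (strand-collapsed) form of k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer
#' and its reverse complement, so a k-mer and its mate on the opposite
#' strand map to the same representative.
#'
#' @param x character vector of k-mers over A/C/G/T.
#' @return character vector of canonical k-mers.
#' @examples
#' canonical_kmer(c("TTTT", "ACGT", "GGGT"))
#' @export
canonical_kmer <- function(x) {
  if (!length(x)) return(character())
  unname(pmin(x, reverse_complement(x)))
}

#' Extract the distinct q-mers of a sequence
#'
#' Slides a window of length `q` along `seq`; a sequence of length L has
#' L - q + 1 windows. Windows containing an N are skipped; with
#' `canonical = TRUE` each window is collapsed with its reverse
#' complement. Duplicated q-mers within the read are counted once.
#'
#' @param seq a single nucleotide string.
#' @param q window length (default 30).
#' @param canonical collapse reverse complements (default TRUE).
#' @return character vector of distinct q-mers (empty when the sequence is
#'   shorter than `q`).
#' @export
extract_qmers <- function(seq, q = 30L, canonical = TRUE) {
  q <- as.integer(q)
  if (q < 1L) stop("q must be >= 1")
  L <- nchar(seq)
  if (L < q) return(character())
  w <- substring(seq, 1:(L - q + 1L), q:L)
  w <- w[!grepl("N", w, fixed = TRUE)]
  if (!length(w)) return(character())
  if (canonical) w <- canonical_kmer(w)
  unique(w)
}

#' Overlap-detection parameters
#'
#' @param q q-mer length used to detect sequence overlap (default 30).
#' @param m minimum number of shared q-mers for two reads to be called
#'   overlapping (default 5, the short-read setting; use 45 for ~700 bp
#'   reads). `m = 0` is floored to 1: at least one shared q-mer is always
#'   required, otherwise every pair would trivially "overlap".
#' @param canonical collapse q-mers with their reverse complements so
#'   reads from opposite strands can still be linked (default TRUE).
#' @return a list of class `overlap_params`.
#' @export
overlap_params <- function(q = 30L, m = 5L, canonical = TRUE) {
  q <- as.integer(q); m <- as.integer(m)
  if (q < 1L) stop("q must be >= 1")
  if (m < 0L) stop("m must be >= 0")
  structure(list(q = q, m = max(m, 1L), canonical = isTRUE(canonical)),
            class = "overlap_params")
}

#' Number of distinct q-mers shared by two reads
#'
#' Shared q-mers are counted as distinct q-mer types (set intersection);
#' multiplicity is ignored, which keeps the count robust to repeats.
#'
#' @param r,s nucleotide strings.
#' @param params an [overlap_params].
#' @return integer count.
#' @export
shared_qmer_count <- function(r, s, params = overlap_params()) {
  length(intersect(extract_qmers(r, params$q, params$canonical),
                   extract_qmers(s, params$q, params$canonical)))
}

#' Do two reads overlap?
#'
#' Two reads are regarded as overlapping when they share at least `m`
#' q-mers (and always at least one).
#'
#' @inheritParams shared_qmer_count
#' @return logical.
#' @export
overlaps <- function(r, s, params = overlap_params()) {
  shared_qmer_count(r, s, params) >= max(params$m, 1L)
}

#' Build the read overlap graph
#'
#' Nodes are reads (in input order); an undirected edge joins two reads
#' that share at least `m` distinct q-mers. The graph is built through a
#' q-mer index (q-mer to the list of reads containing it) rather than
#' all-pairs comparison, but is identical to the all-pairs definition.
#'
#' @param reads a [read_set].
#' @param params an [overlap_params].
#' @return an object of class `overlap_graph`: `n` (node count), `adj`
#'   (list of sorted integer neighbor vectors), `edges` (two-column
#'   matrix, u < v) and `shared` (the shared-q-mer count per edge).
#' @export
build_overlap_graph <- function(reads, params = overlap_params()) {
  n <- length(reads)
  m_min <- max(params$m, 1L)
  qsets <- lapply(reads$seq, extract_qmers, q = params$q,
                  canonical = params$canonical)
  kmer <- unlist(qsets, use.names = FALSE)
  rid <- rep.int(seq_len(n), lengths(qsets))

  edges <- matrix(integer(), 0L, 2L)
  shared <- integer()
  if (length(kmer)) {
    # restrict to q-mers seen in >= 2 reads before splitting
    dup <- kmer %in% kmer[duplicated(kmer)]
    kmer <- kmer[dup]; rid <- rid[dup]
    if (length(kmer)) {
      posting <- split(rid, kmer)
      pair_u <- vector("list", length(posting))
      pair_v <- vector("list", length(posting))
      for (i in seq_along(posting)) {
        v <- sort.int(posting[[i]])
        k <- length(v)
        pair_u[[i]] <- rep.int(v, (k - 1L):0L)
        pair_v[[i]] <- v[sequence((k - 1L):0L, from = 2:(k + 1L))]
      }
      u <- unlist(pair_u, use.names = FALSE)
      v <- unlist(pair_v, use.names = FALSE)
      key <- (u - 1) * n + v        # double-precision pair key, u < v
      cnt <- sort.int(key, method = "radix")
      r <- rle(cnt)
      keep <- r$lengths >= m_min
      if (any(keep)) {
        kk <- r$values[keep]
        eu <- as.integer((kk - 1) %/% n) + 1L
        ev <- as.integer((kk - 1) %% n) + 1L
        edges <- cbind(eu, ev, deparse.level = 0)
        shared <- r$lengths[keep]
      }
    }
  }
  adj <- rep(list(integer()), n)
  if (nrow(edges)) {
    nb <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
    adj[as.integer(names(nb))] <- lapply(nb, sort.int)
  }
  structure(list(n = n, adj = adj, edges = edges, shared = shared,
                 params = params),
            class = "overlap_graph")
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat(sprintf("overlap_graph: %d reads, %d edges (q=%d, m>=%d, %s q-mers)\n",
              x$n, nrow(x$edges), x$params$q, max(x$params$m, 1L),
              if (x$params$canonical) "canonical" else "stranded"))
  invisible(x)
}

#' Dump an overlap graph as an edge-list TSV
#'
#' @param graph an `overlap_graph`.
#' @param path output path; columns are u, v (1-based read indices, u < v)
#'   and the shared q-mer count.
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(graph, path) {
  utils::write.table(cbind(graph$edges, graph$shared), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
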