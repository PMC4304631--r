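#' Dimension of the collapsed l-mer feature space
#'
#' Collapsing every l-mer with its reverse complement leaves
#' \eqn{4^l/2} canonical classes when l is odd and
#' \eqn{(4^l + 4^{l/2})/2} when l is even (the extra term counts the
#' reverse-complement palindromes, which exist only for even l). For the
#' default l = 4 this is 136.
#'
#' @param l word length (>= 1).
#' @return integer dimension.
#' @examples
#' signature_dim(4)  # 136
#' @export
signature_dim <- function(l) {
  l <- as.integer(l)
  if (l < 1L) stop("l must be >= 1")
  if (l %% 2L == 1L) 4L^l / 2L else (4L^l + 4L^(l %/% 2L)) / 2L
}

# cache of canonical-class tables per l
.lmer_cache <- new.env(parent = emptyenv())

# For word length l: all 4^l l-mers in lexicographic order, the canonical
# class (1-based, ordered by canonical l-mer) of each, and the class names.
lmer_classes <- function(l) {
  key <- as.character(l)
  if (!is.null(.lmer_cache[[key]])) return(.lmer_cache[[key]])
  if (l > 8L) stop("l > 8 is not supported")
  bases <- c("A", "C", "G", "T")
  g <- do.call(expand.grid,
               c(rep(list(bases), l), KEEP.OUT.ATTRS = FALSE,
                 stringsAsFactors = FALSE))
  # expand.grid varies the first column fastest; reverse for lexicographic order
  all_lmers <- do.call(paste0, rev(g))
  canon <- canonical_kmer(all_lmers)
  classes <- sort(unique(canon))
  out <- list(lmers = all_lmers, class_of = match(canon, classes),
              classes = classes)
  .lmer_cache[[key]] <- out
  out
}

#' Index of an l-mer in the canonical feature vector
#'
#' Each l-mer is canonicalized (lexicographic minimum with its reverse
#' complement) and ranked among all canonical l-mers in lexicographic
#' order, giving a fixed 1-based coordinate in `[1, signature_dim(l)]`
#' that is stable across runs. An l-mer and its reverse complement map to
#' the same index.
#'
#' @param lmer character vector of l-mers (all the same length, over
#'   A/C/G/T).
#' @return integer vector of indices.
#' @export
lmer_index <- function(lmer) {
  if (!length(lmer)) return(integer())
  l <- unique(nchar(lmer))
  if (length(l) != 1L) stop("l-mers must all have the same length")
  tab <- lmer_classes(l)
  i <- match(canonical_kmer(lmer), tab$classes)
  if (anyNA(i)) stop("invalid l-mer(s): ", paste(lmer[is.na(i)], collapse = ", "))
  i
}

#' Count canonical l-mers over a collection of reads
#'
#' Slides a window of length `l` along every read; each read of length
#' \eqn{|r|} contributes \eqn{|r| - l + 1} windows. Windows containing an
#' N are skipped and excluded from the total. Each window increments the
#' count of its canonical class.
#'
#' @param seqs character vector of nucleotide sequences.
#' @param l word length (default 4).
#' @return list with `counts` (integer vector of length
#'   `signature_dim(l)`, named by canonical l-mer) and `total` (number of
#'   valid windows).
#' @export
count_lmers <- function(seqs, l = 4L) {
  l <- as.integer(l)
  if (l < 1L) stop("l must be >= 1")
  tab <- lmer_classes(l)
  d <- length(tab$classes)
  counts <- integer(d)
  names(counts) <- tab$classes
  if (!length(seqs))
    return(list(counts = counts, total = 0L))
  # one pass over all reads: join with an N so no window spans two reads
  joined <- paste(seqs, collapse = "N")
  code <- match(strsplit(joined, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  nw <- length(code) - l + 1L
  if (nw < 1L)
    return(list(counts = counts, total = 0L))
  idx <- integer(nw)
  for (j in 0:(l - 1L))
    idx <- idx * 4L + (code[(1L + j):(nw + j)] - 1L)   # NA poisons the window
  idx <- idx[!is.na(idx)]
  counts <- counts + tabulate(tab$class_of[idx + 1L], nbins = d)
  names(counts) <- tab$classes
  list(counts = counts, total = length(idx))
}

#' Normalized l-mer frequency signature
#'
#' The genomic signature of a collection of reads: canonical l-mer counts
#' divided by the total number of valid windows, so the entries sum to 1.
#' In the pipeline this is computed on each group's seed — a set of
#' mutually non-overlapping reads — where it approximates the source
#' genome's signature without double-counting any genomic region.
#'
#' @param seqs character vector of nucleotide sequences (or a [read_set]).
#' @param l word length (default 4, giving a 136-entry vector).
#' @return object of class `lmer_signature`: a named numeric vector with
#'   attributes `l` and `total_lmers`. All-zero with `total_lmers = 0`
#'   when there is no valid window.
#' @examples
#' sig <- lmer_signature(c("CCTAA", "AAGAA"))
#' sum(sig)           # 1
#' attr(sig, "total_lmers")  # 4 windows
#' @export
lmer_signature <- function(seqs, l = 4L) {
  if (inherits(seqs, "read_set")) seqs <- seqs$seq
  ct <- count_lmers(seqs, l)
  v <- if (ct$total > 0L) ct$counts / ct$total else as.numeric(ct$counts)
  structure(v, l = as.integer(l), total_lmers = ct$total,
            class = "lmer_signature")
}

#' @export
print.lmer_signature <- function(x, ...) {
  cat(sprintf("lmer_signature: l=%d, %d entries, %d windows\n",
              attr(x, "l"), length(x), attr(x, "total_lmers")))
  top <- sort(unclass(x), decreasing = TRUE)
  top <- top[top > 0][seq_len(min(5, sum(x > 0)))]
  if (length(top))
    cat("  top:", paste(sprintf("%s=%.4f", names(top), top), collapse = " "), "\n")
  invisible(x)
}

#' Euclidean distance between two signatures
#'
#' @param a,b numeric vectors of equal length (signatures).
#' @return the L2 distance.
#' @export
signature_distance <- function(a, b) {
  if (length(a) != length(b)) stop("signature dimensions differ")
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' Signature matrix of group seeds
#'
#' One row per group: the l-mer signature of the group's seed reads.
#'
#' @param groups a `read_groups` list from [build_groups].
#' @param reads the corresponding [read_set].
#' @param l word length (default 4).
#' @return numeric matrix, `length(groups)` x `signature_dim(l)`, columns
#'   named by canonical l-mer.
#' @export
seed_signatures <- function(groups, reads, l = 4L) {
  tab <- lmer_classes(as.integer(l))
  out <- matrix(0, nrow = length(groups), ncol = length(tab$classes),
                dimnames = list(NULL, tab$classes))
  for (i in seq_along(groups))
    out[i, ] <- lmer_signature(reads$seq[groups[[i]]$seed], l)
  out
}
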