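#' Construct a read set
#'
#' A `read_set` is the container every stage of the pipeline consumes: an
#' ordered collection of uppercase nucleotide sequences over \{A,C,G,T,N\}
#' with unique ids, optionally carrying per-read ground truth (source
#' species, genome id and 0-based half-open genome interval) when the reads
#' come from the simulator or an annotated dataset.
#'
#' @param id character vector of unique read identifiers.
#' @param seq character vector of nucleotide sequences, same length as `id`.
#'   Sequences are uppercased and any character outside A/C/G/T is mapped
#'   to N.
#' @param truth optional `data.frame` with columns `read_id`, `species`,
#'   `genome`, `start`, `end` (start 0-based inclusive, end exclusive).
#' @return An object of class `read_set` with elements `id`, `seq` and
#'   (possibly `NULL`) `truth`.
#' @examples
#' rs <- read_set(c("r1", "r2"), c("CCTAA", "AAGAA"))
#' length(rs)
#' read_length(rs)
#' @export
read_set <- function(id, seq, truth = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq))
    stop("'id' and 'seq' must have the same length")
  if (anyDuplicated(id))
    stop("duplicate read id(s): ", paste(unique(id[duplicated(id)]), collapse = ", "))
  if (length(seq) && any(!nzchar(seq)))
    stop("empty sequence(s) at record(s): ", paste(which(!nzchar(seq)), collapse = ", "))
  seq <- gsub("[^ACGT]", "N", seq)
  if (!is.null(truth)) {
    truth <- as.data.frame(truth)
    need <- c("read_id", "species", "genome", "start", "end")
    if (!all(need %in% names(truth)))
      stop("truth must have columns: ", paste(need, collapse = ", "))
    if (!all(id %in% truth$read_id))
      stop("truth table does not cover all reads")
    truth <- truth[match(id, truth$read_id), need, drop = FALSE]
    rownames(truth) <- NULL
    bad <- !is.na(truth$start) & !(truth$start >= 0 & truth$start < truth$end)
    if (any(bad))
      stop("invalid truth interval(s) for: ", paste(truth$read_id[bad], collapse = ", "))
  }
  structure(list(id = id, seq = seq, truth = truth), class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' Read lengths in base pairs
#' @param x a `read_set`.
#' @return integer vector of sequence lengths.
#' @export
read_length <- function(x) nchar(x$seq)

#' @export
`[.read_set` <- function(x, i) {
  idx <- seq_along(x$id)[i]
  tr <- if (is.null(x$truth)) NULL else x$truth[idx, , drop = FALSE]
  read_set(x$id[idx], x$seq[idx], tr)
}

#' @export
print.read_set <- function(x, ...) {
  n <- length(x)
  cat(sprintf("read_set: %d read%s", n, if (n == 1) "" else "s"))
  if (n) {
    len <- read_length(x)
    cat(sprintf(", length %d-%d bp (median %d)", min(len), max(len),
                as.integer(stats::median(len))))
  }
  cat(if (is.null(x$truth)) ", no truth\n" else ", with truth\n")
  invisible(x)
}

#' Combine read sets
#' @param ... `read_set` objects; truth is kept only if present on all of them.
#' @return a single `read_set`.
#' @export
concat_reads <- function(...) {
  xs <- list(...)
  truths <- lapply(xs, `[[`, "truth")
  tr <- if (any(vapply(truths, is.null, logical(1)))) NULL else do.call(rbind, truths)
  read_set(unlist(lapply(xs, `[[`, "id")), unlist(lapply(xs, `[[`, "seq")), tr)
}
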