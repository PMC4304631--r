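#' Read sequencing reads from FASTA or FASTQ
#'
#' Parses a multi-record FASTA or FASTQ file into a [read_set]. FASTQ
#' quality strings are discarded: binning uses base identity only.
#' Characters outside A/C/G/T (IUPAC ambiguity codes, gaps, lowercase
#' leftovers) are normalized to N; downstream k-mer extraction skips any
#' window containing an N.
#'
#' @param path path to the sequence file.
#' @param format `"auto"` (default, sniffed from the first record
#'   character), `"fasta"` or `"fastq"`.
#' @return a [read_set]; an empty file yields a zero-read set.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "CCTAA", ">r2", "AAGAA"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    head1 <- readLines(path, n = 1L)
    format <- if (!length(head1) || !nzchar(head1)) "fasta"
              else if (startsWith(head1, "@")) "fastq" else "fasta"
  }
  ss <- if (format == "fastq")
    Biostrings::readDNAStringSet(path, format = "fastq")
  else
    Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(ss))
  read_set(ids, as.character(ss))
}

#' Write a read set to FASTA
#'
#' @param reads a [read_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write and read cluster assignment tables
#'
#' The assignment table is a two-column TSV, one row per read in input
#' order: `read_id <TAB> cluster_id`. Unassigned reads (`NA` cluster) are
#' written as `-1`.
#'
#' @param assignments `data.frame` with columns `read_id` and `cluster`
#'   (integer, `NA` = unassigned).
#' @param path file path.
#' @return `write_assignments()` returns `path` invisibly;
#'   `read_assignments()` returns the assignment `data.frame` with `-1`
#'   mapped back to `NA`.
#' @export
write_assignments <- function(assignments, path) {
  stopifnot(is.data.frame(assignments),
            all(c("read_id", "cluster") %in% names(assignments)))
  if (anyDuplicated(assignments$read_id))
    stop("duplicate read_id in assignment table")
  cl <- assignments$cluster
  cl[is.na(cl)] <- -1L
  utils::write.table(data.frame(assignments$read_id, as.integer(cl)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(data.frame(read_id = character(), cluster = integer()))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer"),
                          col.names = c("read_id", "cluster"))
  if (anyDuplicated(df$read_id))
    stop("duplicate read_id in assignment table: ",
         df$read_id[duplicated(df$read_id)][1])
  df$cluster[df$cluster < 0] <- NA_integer_
  df
}

#' Read a ground-truth species table
#'
#' Two-column TSV of `read_id <TAB> species_label`. Used only for
#' evaluation; the binning itself never sees it.
#'
#' @param path file path.
#' @return named character vector mapping read id to species label.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(stats::setNames(character(), character()))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("truth table needs two columns (read_id, species)")
  if (anyDuplicated(df[[1]]))
    stop("duplicate read_id in truth table: ", df[[1]][duplicated(df[[1]])][1])
  stats::setNames(df[[2]], df[[1]])
}

#' Write a ground-truth table
#'
#' Writes `read_id <TAB> species` (the form [read_truth] reads back);
#' with `full = TRUE` adds the genome id and sampling coordinates recorded
#' by the simulator.
#'
#' @param reads a [read_set] carrying truth.
#' @param path file path.
#' @param full write genome/start/end columns too.
#' @return `path`, invisibly.
#' @export
write_truth <- function(reads, path, full = FALSE) {
  if (is.null(reads$truth)) stop("read set carries no truth")
  cols <- if (full) reads$truth else reads$truth[c("read_id", "species")]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
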