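#' Cluster-by-species confusion matrix
#'
#' Tallies `A[i, j]`, the number of reads from species `j` assigned to
#' cluster `i`. Unassigned reads (cluster `NA`) are counted separately;
#' they enter the recall denominator but never the matrix. Every read in
#' the assignment table must have a truth label — silent dropping would
#' corrupt the metrics.
#'
#' @param assignments `data.frame` with `read_id` and `cluster`
#'   (`NA` = unassigned), as produced by [propagate_labels] or
#'   [read_assignments].
#' @param truth named character vector mapping read id to species label
#'   (see [read_truth]), or a [read_set] carrying truth.
#' @return list of class `bin_confusion`: `a` (k x m integer matrix with
#'   cluster/species dimnames) and `unassigned`.
#' @export
bin_confusion <- function(assignments, truth) {
  if (inherits(truth, "read_set")) {
    if (is.null(truth$truth)) stop("read set carries no truth")
    truth <- stats::setNames(truth$truth$species, truth$truth$read_id)
  }
  missing <- setdiff(assignments$read_id, names(truth))
  if (length(missing))
    stop("no truth label for read(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  sp <- truth[assignments$read_id]
  assigned <- !is.na(assignments$cluster)
  a <- table(cluster = factor(assignments$cluster[assigned]),
             species = factor(sp[assigned]))
  a <- unclass(as.matrix(a))
  storage.mode(a) <- "integer"
  structure(list(a = a, unassigned = sum(!assigned)),
            class = "bin_confusion")
}

#' @export
print.bin_confusion <- function(x, ...) {
  cat(sprintf("bin_confusion: %d cluster(s) x %d species, %d unassigned\n",
              nrow(x$a), ncol(x$a), x$unassigned))
  print(x$a)
  invisible(x)
}

#' Binning precision
#'
#' The fraction of assigned reads that agree with the dominant species of
#' their cluster: `sum_i max_j A_ij / sum_ij A_ij`. Unassigned reads are
#' excluded from both numerator and denominator.
#'
#' @param cm a `bin_confusion`.
#' @return numeric in `[0, 1]`.
#' @export
bin_precision <- function(cm) {
  tot <- sum(cm$a)
  if (tot == 0) stop("precision undefined: no assigned reads")
  sum(apply(cm$a, 1L, max)) / tot
}

#' Binning recall
#'
#' The fraction of reads kept together with the bulk of their species:
#' `sum_j max_i A_ij / (sum_ij A_ij + #unassigned)`. Unassigned reads
#' inflate the denominator only.
#'
#' @param cm a `bin_confusion`.
#' @return numeric in `[0, 1]`.
#' @export
bin_recall <- function(cm) {
  denom <- sum(cm$a) + cm$unassigned
  if (denom == 0) stop("recall undefined: no reads")
  sum(apply(cm$a, 2L, max)) / denom
}

#' F-measure
#'
#' Harmonic mean of precision and recall, `2 / (1/p + 1/r)`; defined as 0
#' when either is 0.
#'
#' @param p,r precision and recall in `[0, 1]`.
#' @return numeric in `[0, 1]`.
#' @examples
#' f_measure(0.558, 0.8809)   # ~0.6832
#' @export
f_measure <- function(p, r) {
  stopifnot(p >= 0, p <= 1, r >= 0, r <= 1)
  if (p == 0 || r == 0) return(0)
  2 / (1 / p + 1 / r)
}

#' Evaluate a binning against ground truth
#'
#' @inheritParams bin_confusion
#' @return list of class `bin_eval` with `precision`, `recall`,
#'   `f_measure` and the `confusion` object.
#' @export
evaluate_binning <- function(assignments, truth) {
  cm <- bin_confusion(assignments, truth)
  p <- bin_precision(cm)
  r <- bin_recall(cm)
  structure(list(precision = p, recall = r, f_measure = f_measure(p, r),
                 confusion = cm),
            class = "bin_eval")
}

#' @export
print.bin_eval <- function(x, ...) {
  cat(sprintf("precision: %6.2f%%\nrecall:    %6.2f%%\nF-measure: %6.2f%%\n",
              100 * x$precision, 100 * x$recall, 100 * x$f_measure))
  invisible(x)
}
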