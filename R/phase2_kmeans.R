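#' Within-cluster sum of squares
#'
#' The objective minimized in phase 2: the sum over clusters of squared
#' Euclidean distances between each member signature and its cluster
#' mean.
#'
#' @param x numeric feature matrix (one row per group).
#' @param labels integer cluster labels in `1..k`, one per row of `x`.
#' @param means optional k x ncol(x) matrix of cluster means; recomputed
#'   from `labels` when omitted.
#' @return non-negative numeric scalar.
#' @export
kmeans_objective <- function(x, labels, means = NULL) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) stop("one label per feature row required")
  if (is.null(means)) means <- cluster_means(x, labels, max(labels))
  sum((x - means[labels, , drop = FALSE])^2)
}

cluster_means <- function(x, labels, k) {
  mns <- matrix(NA_real_, k, ncol(x))
  for (j in seq_len(k)) {
    rows <- labels == j
    if (any(rows)) mns[j, ] <- colMeans(x[rows, , drop = FALSE])
  }
  mns
}

squared_dist_to <- function(x, means) {
  # p x k matrix of squared Euclidean distances
  outer(rowSums(x^2), rep(1, nrow(means))) +
    outer(rep(1, nrow(x)), rowSums(means^2)) - 2 * x %*% t(means)
}

#' Lloyd k-means on seed signatures
#'
#' Standard Lloyd iteration with the conventions the pipeline relies on:
#' initial means are `k` feature vectors sampled without replacement;
#' each assignment step sends every vector to its nearest mean (ties to
#' the lowest cluster index); each update step recomputes means; the loop
#' stops when the means stop moving (exactly, with the default
#' `tol = 0`) or after `max_iter` iterations. If an assignment step
#' empties a cluster, its mean is re-seeded with the feature vector
#' farthest from its own cluster's mean, so exactly `k` clusters survive.
#' `restarts > 1` repeats the whole run and keeps the solution with the
#' lowest within-cluster sum of squares.
#'
#' @param x numeric matrix of feature vectors (p rows); p >= k required.
#' @param k number of clusters.
#' @param max_iter iteration cap (default 100).
#' @param tol mean-movement threshold for convergence; 0 means exact
#'   stability.
#' @param restarts independent initializations (default 1).
#' @param seed optional integer for a locally-set RNG state.
#' @return list of class `seed_kmeans`: `labels` (1..k per row), `means`,
#'   `objective`, `iterations`, `converged`.
#' @export
run_kmeans <- function(x, k, max_iter = 100L, tol = 0, restarts = 1L,
                       seed = NULL) {
  x <- as.matrix(x)
  p <- nrow(x)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > p) stop("k = ", k, " exceeds the number of feature vectors (", p,
                  "); use a smaller k or a smaller m")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  best <- NULL
  for (r in seq_len(max(1L, as.integer(restarts)))) {
    fit <- lloyd_once(x, k, max_iter, tol)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best
}

lloyd_once <- function(x, k, max_iter, tol) {
  p <- nrow(x)
  means <- x[sample.int(p, k), , drop = FALSE]
  labels <- integer(p)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    d2 <- squared_dist_to(x, means)
    labels <- max.col(-d2, ties.method = "first")
    old_means <- means
    means <- cluster_means(x, labels, k)
    empty <- which(is.na(means[, 1L]))
    if (length(empty)) {
      own <- d2[cbind(seq_len(p), labels)]
      for (j in empty) {
        far <- which.max(own)
        means[j, ] <- x[far, ]
        labels[far] <- j
        own[far] <- -Inf
      }
      means <- cluster_means(x, labels, k)
    }
    if (max(abs(means - old_means)) <= tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(labels = labels, means = means,
                 objective = kmeans_objective(x, labels, means),
                 iterations = iter, converged = converged),
            class = "seed_kmeans")
}

#' @export
print.seed_kmeans <- function(x, ...) {
  cat(sprintf("seed_kmeans: k=%d, objective %.6g, %d iteration%s%s\n",
              nrow(x$means), x$objective, x$iterations,
              if (x$iterations == 1) "" else "s",
              if (x$converged) " (converged)" else " (iteration cap hit)"))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Propagate group cluster labels to reads
#'
#' Every read inherits the cluster of the group that contains it.
#'
#' @param groups a `read_groups` list.
#' @param model a `seed_kmeans` fit over the same groups.
#' @param reads the [read_set].
#' @return `data.frame` with `read_id` and `cluster` (1..k), one row per
#'   read in input order.
#' @export
propagate_labels <- function(groups, model, reads) {
  if (length(model$labels) != length(groups))
    stop("model labels do not match the number of groups")
  cl <- integer(length(reads))
  for (i in seq_along(groups))
    cl[groups[[i]]$members] <- model$labels[i]
  data.frame(read_id = reads$id, cluster = cl)
}
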