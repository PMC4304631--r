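#' Bin metagenomic reads into species-level clusters
#'
#' Runs the full two-phase binning pipeline. Phase 1 builds the read
#' overlap graph (an edge joins two reads sharing at least `m` q-mers of
#' length `q`) and greedily partitions it into groups, each with a seed
#' of mutually non-overlapping reads capped at `s_max` bp. Phase 2
#' computes the normalized canonical l-mer frequency signature of every
#' seed and merges the groups into `k` clusters by Lloyd k-means on these
#' signatures; every read inherits its group's cluster.
#'
#' @param reads a [read_set] (or a path to a FASTA/FASTQ file).
#' @param k number of clusters, typically the number of species expected
#'   in the sample; must not exceed the number of phase-1 groups.
#' @param q q-mer length for overlap detection (default 30; long enough
#'   that different genomes rarely share q-mers).
#' @param m minimum shared q-mers for an overlap; defaults to the `mode`
#'   preset (5 for short ~80 bp reads, 45 for long ~700 bp reads).
#' @param mode `"short"` or `"long"`; only sets the default of `m`.
#' @param l signature word length (default 4: tetranucleotides, a
#'   136-entry collapsed vector).
#' @param s_max seed size cap in bp (default 9000).
#' @param canonical collapse q-mers with reverse complements during
#'   overlap detection (default TRUE).
#' @param max_iter k-means iteration cap (default 100).
#' @param restarts k-means restarts keeping the lowest objective
#'   (default 1).
#' @param seed optional integer making the run fully reproducible (group
#'   construction and k-means initialization).
#' @return an object of class `seedbin` with components `assignments`
#'   (data.frame `read_id`, `cluster`), `groups`, `graph`, `features`
#'   (seed signature matrix), `model` (the k-means fit), `params`,
#'   `n`, and `call`. See [print.seedbin], [summary.seedbin],
#'   [predict.seedbin].
#' @examples
#' set.seed(7)
#' com <- simulate_community(
#'   list(species_spec("A", 6000), species_spec("B", 6000)),
#'   n_reads = 300, error_rate = 0, seed = 7)
#' fit <- seedbin(com$reads, k = 2, seed = 7)
#' fit
#' evaluate_binning(fit$assignments, com$reads)
#' @export
seedbin <- function(reads, k, q = 30L, m = NULL,
                    mode = c("short", "long"), l = 4L, s_max = 9000L,
                    canonical = TRUE, max_iter = 100L, restarts = 1L,
                    seed = NULL) {
  cl <- match.call()
  mode <- match.arg(mode)
  if (is.character(reads) && length(reads) == 1L)
    reads <- read_sequences(reads)
  stopifnot(inherits(reads, "read_set"))
  if (length(reads) < 1L) stop("empty read set")
  if (is.null(m)) m <- if (mode == "short") 5L else 45L
  params <- overlap_params(q = q, m = m, canonical = canonical)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  graph <- build_overlap_graph(reads, params)
  groups <- build_groups(graph, reads, s_max = s_max)
  features <- seed_signatures(groups, reads, l = l)
  if (k > length(groups))
    stop("k = ", k, " exceeds the number of phase-1 groups (",
         length(groups), "); use a smaller k or a smaller m")
  model <- run_kmeans(features, k, max_iter = max_iter, restarts = restarts)
  assignments <- propagate_labels(groups, model, reads)
  structure(list(assignments = assignments, groups = groups, graph = graph,
                 features = features, model = model,
                 params = list(k = as.integer(k), q = params$q, m = params$m,
                               l = as.integer(l), s_max = as.integer(s_max),
                               canonical = params$canonical, mode = mode,
                               max_iter = as.integer(max_iter),
                               restarts = as.integer(restarts),
                               seed = seed),
                 n = length(reads), call = cl),
            class = "seedbin")
}

#' @export
print.seedbin <- function(x, ...) {
  cat("Two-phase composition-based read binning\n\n")
  cat(sprintf("  reads: %d   overlap edges: %d (q=%d, m>=%d)\n",
              x$n, nrow(x$graph$edges), x$params$q, x$params$m))
  cat(sprintf("  phase 1: %d groups (seed cap %d bp)\n",
              length(x$groups), x$params$s_max))
  cat(sprintf("  phase 2: k=%d clusters, WCSS %.6g, %d iteration%s\n",
              x$params$k, x$model$objective, x$model$iterations,
              if (x$model$iterations == 1) "" else "s"))
  sizes <- table(x$assignments$cluster)
  cat("  cluster sizes:", paste(sprintf("%s:%d", names(sizes), sizes),
                                collapse = "  "), "\n")
  invisible(x)
}

#' Summarise a seedbin fit
#'
#' @param object a `seedbin` object.
#' @param ... unused.
#' @return a list of class `summary.seedbin` with group/seed statistics,
#'   per-cluster sizes and the clustering objective.
#' @method summary seedbin
#' @export
summary.seedbin <- function(object, ...) {
  seed_bp <- vapply(object$groups, `[[`, numeric(1), "seed_size_bp")
  out <- list(n = object$n,
              edges = nrow(object$graph$edges),
              p = length(object$groups),
              group_sizes = lengths(lapply(object$groups, `[[`, "members")),
              seed_bp = seed_bp,
              cluster_sizes = table(object$assignments$cluster),
              objective = object$model$objective,
              iterations = object$model$iterations,
              converged = object$model$converged,
              params = object$params)
  class(out) <- "summary.seedbin"
  out
}

#' @export
print.summary.seedbin <- function(x, ...) {
  p <- x$params
  cat(sprintf("seedbin fit: n=%d reads, q=%d, m=%d, l=%d, S_max=%d, k=%d\n",
              x$n, p$q, p$m, p$l, p$s_max, p$k))
  cat(sprintf("overlap graph: %d edges\n", x$edges))
  cat(sprintf("phase 1: p=%d groups; group size ", x$p))
  print(summary(as.numeric(x$group_sizes)))
  cat("seed size (bp): ")
  print(summary(x$seed_bp))
  cat(sprintf("phase 2: WCSS %.6g after %d iteration(s)%s\n", x$objective,
              x$iterations, if (x$converged) "" else " [cap hit]"))
  cat("cluster sizes:\n")
  print(x$cluster_sizes)
  invisible(x)
}

#' Cluster mean signatures
#'
#' @param object a `seedbin` fit.
#' @param ... unused.
#' @return k x `signature_dim(l)` matrix of cluster mean l-mer
#'   frequencies.
#' @method coef seedbin
#' @export
coef.seedbin <- function(object, ...) {
  m <- object$model$means
  dimnames(m) <- list(cluster = seq_len(nrow(m)), colnames(object$features))
  m
}

#' @export
fitted.seedbin <- function(object, ...) {
  stats::setNames(object$assignments$cluster, object$assignments$read_id)
}

#' Assign new reads to existing clusters
#'
#' Each new read is summarised by its own l-mer signature and assigned to
#' the nearest cluster mean. Single short reads carry a much noisier
#' signature than a ~9000 bp seed, so out-of-sample assignment is
#' indicative rather than definitive.
#'
#' @param object a `seedbin` fit.
#' @param newdata a [read_set] (or character vector of sequences).
#' @param ... unused.
#' @return integer vector of cluster labels, named by read id when
#'   available.
#' @method predict seedbin
#' @export
predict.seedbin <- function(object, newdata, ...) {
  seqs <- if (inherits(newdata, "read_set")) newdata$seq else as.character(newdata)
  ids <- if (inherits(newdata, "read_set")) newdata$id else names(newdata)
  sig <- t(vapply(seqs, function(s) as.numeric(lmer_signature(s, object$params$l)),
                  numeric(ncol(object$features))))
  d2 <- squared_dist_to(sig, object$model$means)
  stats::setNames(max.col(-d2, ties.method = "first"), ids)
}

#' Plot a seedbin fit
#'
#' Two base-graphics panels: seed signatures of all groups overlaid as
#' profiles coloured by final cluster (well-separated species show as
#' distinct profile families), and cluster sizes in reads.
#'
#' @param x a `seedbin` fit.
#' @param ... passed to [graphics::matplot].
#' @return `x`, invisibly.
#' @method plot seedbin
#' @export
plot.seedbin <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- grDevices::hcl.colors(max(2L, x$params$k), "Dark 3")
  graphics::matplot(t(x$features), type = "l", lty = 1,
                    col = cols[x$model$labels],
                    xlab = sprintf("canonical %d-mer index", x$params$l),
                    ylab = "frequency", main = "seed signatures by cluster",
                    ...)
  sizes <- table(x$assignments$cluster)
  graphics::barplot(sizes, col = cols[as.integer(names(sizes))],
                    xlab = "cluster", ylab = "reads",
                    main = "cluster sizes")
  invisible(x)
}
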