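#' Phase 1: partition the overlap graph into groups with seeds
#'
#' Greedy constructive partitioning of the read overlap graph. A group is
#' started from a uniformly random remaining node and grown breadth-first
#' through its neighborhood (first-in-first-out frontier, ties by
#' ascending node index). Every admitted node joins the group; it also
#' joins the group's seed exactly when it is not adjacent to any current
#' seed member, so the seed is an independent set: a collection of reads
#' no two of which overlap. When the seed's total length in base pairs
#' exceeds `s_max` the group stops growing and un-admitted frontier nodes
#' return to the pool for later groups. Isolated nodes become singleton
#' groups whose seed is the read itself.
#'
#' Capping seeds at `s_max` limits the damage a spurious edge (sequencing
#' error, a q-mer shared across genomes) can do, and keeps every seed
#' about the size at which oligonucleotide signatures are reliably
#' species-specific (~9000 bp).
#'
#' @param graph an [build_overlap_graph] result.
#' @param reads the [read_set] the graph was built from.
#' @param s_max seed size cap in base pairs (default 9000).
#' @param seed optional integer; when given, the RNG state is set locally
#'   for reproducible group construction.
#' @return a list of class `read_groups`; each element has `members`,
#'   `seed`, `nonseed` (integer read indices, admission order) and
#'   `seed_size_bp`.
#' @export
build_groups <- function(graph, reads, s_max = 9000L, seed = NULL) {
  n <- graph$n
  if (n != length(reads))
    stop("graph has ", n, " nodes but read set has ", length(reads), " reads")
  s_max <- as.integer(s_max)
  if (s_max < 1L) stop("s_max must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }

  len <- read_length(reads)
  adj <- graph$adj
  in_pool <- rep(TRUE, n)
  queued <- logical(n)
  pool_left <- n
  groups <- list()

  while (pool_left > 0L) {
    start <- sample_remaining(in_pool, pool_left)
    in_pool[start] <- FALSE
    pool_left <- pool_left - 1L
    members <- start
    seed_idx <- start
    nonseed <- integer()
    seed_bp <- len[start]

    frontier <- adj[[start]][in_pool[adj[[start]]]]
    queued[frontier] <- TRUE
    head <- 1L
    while (seed_bp <= s_max && head <= length(frontier)) {
      u <- frontier[head]; head <- head + 1L
      queued[u] <- FALSE
      if (!in_pool[u]) next
      in_pool[u] <- FALSE
      pool_left <- pool_left - 1L
      members <- c(members, u)
      if (!any(adj[[u]] %in% seed_idx)) {
        seed_idx <- c(seed_idx, u)
        seed_bp <- seed_bp + len[u]
      } else {
        nonseed <- c(nonseed, u)
      }
      nxt <- adj[[u]]
      nxt <- nxt[in_pool[nxt] & !queued[nxt]]
      if (length(nxt)) {
        queued[nxt] <- TRUE
        frontier <- c(frontier, nxt)   # FIFO; adj lists are pre-sorted
      }
    }
    queued[frontier] <- FALSE          # un-admitted nodes stay in the pool
    groups[[length(groups) + 1L]] <-
      list(members = members, seed = seed_idx, nonseed = nonseed,
           seed_size_bp = sum(len[seed_idx]))
  }
  structure(groups, class = "read_groups", n_reads = n)
}

# uniform draw over TRUE positions without materialising which() each time
sample_remaining <- function(in_pool, pool_left) {
  j <- if (pool_left == 1L) 1L else sample.int(pool_left, 1L)
  which(in_pool)[j]
}

#' Seed size of a group in base pairs
#'
#' @param group one element of a `read_groups` list.
#' @param reads the corresponding [read_set].
#' @return total length of the seed reads.
#' @export
seed_size_bp <- function(group, reads) {
  sum(read_length(reads)[group$seed])
}

#' @export
print.read_groups <- function(x, ...) {
  p <- length(x)
  sz <- lengths(lapply(x, `[[`, "members"))
  sbp <- vapply(x, `[[`, numeric(1), "seed_size_bp")
  cat(sprintf("read_groups: %d group%s over %d reads\n", p,
              if (p == 1) "" else "s", attr(x, "n_reads")))
  cat(sprintf("  group size: %d-%d reads; seed size: %d-%d bp\n",
              min(sz), max(sz), as.integer(min(sbp)), as.integer(max(sbp))))
  invisible(x)
}

#' Dump groups as TSV (read_id, group index, in_seed flag)
#'
#' @param groups a `read_groups` list.
#' @param reads the corresponding [read_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, reads, path) {
  rows <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    data.frame(read_id = reads$id[g$members], group = i,
               in_seed = as.integer(g$members %in% g$seed))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
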