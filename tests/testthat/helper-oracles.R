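# Independent brute-force oracles used across tests. These deliberately
# avoid the package's optimised code paths.

# reverse complement by explicit per-character table lookup
rc_oracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# all windows of length k (with multiplicity), skipping any containing N
windows_oracle <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character())
  w <- vapply(1:(L - k + 1), function(i) substr(s, i, i + k - 1), "")
  w[!grepl("N", w, fixed = TRUE)]
}

# overlap graph by direct all-pairs set intersection
graph_oracle <- function(seqs, q, m, canonical) {
  n <- length(seqs)
  qs <- lapply(seqs, function(s) {
    w <- unique(windows_oracle(s, q))
    if (canonical) w <- unique(pmin(w, vapply(w, rc_oracle, "")))
    w
  })
  edges <- NULL
  if (n >= 2) for (u in 1:(n - 1)) for (v in (u + 1):n)
    if (length(intersect(qs[[u]], qs[[v]])) >= max(m, 1))
      edges <- rbind(edges, c(u, v))
  if (is.null(edges)) matrix(integer(), 0, 2) else edges
}

# optimal 2-cluster WCSS by exhaustive search over all 2-partitions
best_2partition <- function(x) {
  p <- nrow(x)
  wcss <- function(rows) {
    if (!length(rows)) return(0)
    xm <- x[rows, , drop = FALSE]
    sum(sweep(xm, 2, colMeans(xm))^2)
  }
  best <- Inf; best_lab <- NULL
  for (code in 1:(2^(p - 1) - 1)) {     # fix point 1 in cluster 1
    lab <- c(1L, 1L + as.integer(intToBits(code)[1:(p - 1)] == 1))
    val <- wcss(which(lab == 1)) + wcss(which(lab == 2))
    if (val < best) { best <- val; best_lab <- lab }
  }
  list(objective = best, labels = best_lab)
}

# precision/recall by direct per-read tallying from raw label vectors
metrics_oracle <- function(cluster, species) {
  assigned <- !is.na(cluster)
  num_p <- 0
  for (cl in unique(cluster[assigned])) {
    tab <- table(species[assigned & cluster == cl])
    num_p <- num_p + max(tab)
  }
  num_r <- 0
  for (sp in unique(species)) {
    inside <- cluster[assigned & species == sp]
    num_r <- num_r + if (length(inside)) max(table(inside)) else 0
  }
  list(precision = num_p / sum(assigned),
       recall = num_r / length(cluster))
}

# a deterministic pinned two-species community for pipeline tests
pinned_community <- function(seed, n_reads = 1000, weights = c(1, 1),
                             genome_length = 8000, read_length = 80,
                             error_rate = 0) {
  set.seed(seed)
  sp <- list(species_spec("spA", genome_length, abundance = weights[1]),
             species_spec("spB", genome_length, abundance = weights[2]))
  simulate_community(sp, n_reads = n_reads, read_length = read_length,
                     error_rate = error_rate, seed = seed)
}

# random small read set over a fixed alphabet for property tests
random_reads <- function(n, len_range = c(35, 60)) {
  seqs <- vapply(seq_len(n), function(i) {
    L <- sample(len_range[1]:len_range[2], 1)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
  read_set(paste0("r", seq_len(n)), seqs)
}
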