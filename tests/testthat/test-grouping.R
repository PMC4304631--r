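# small helper: build an overlap_graph-shaped object from an explicit edge list
manual_graph <- function(n, edges) {
  edges <- lapply(edges, as.integer)
  adj <- rep(list(integer()), n)
  for (e in edges) {
    adj[[e[1]]] <- sort.int(c(adj[[e[1]]], e[2]))
    adj[[e[2]]] <- sort.int(c(adj[[e[2]]], e[1]))
  }
  em <- if (length(edges)) t(vapply(edges, sort.int, integer(2))) else
    matrix(integer(), 0, 2)
  structure(list(n = n, adj = adj, edges = em,
                 shared = rep(1L, length(edges)),
                 params = overlap_params()),
            class = "overlap_graph")
}

fixed_reads <- function(n, len = 80) {
  read_set(paste0("r", seq_len(n)),
           vapply(seq_len(n), function(i)
             paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = ""), ""))
}

test_that("an edgeless graph yields singleton groups, each its own seed", {
  set.seed(1)
  rs <- fixed_reads(6)
  grp <- build_groups(manual_graph(6, list()), rs, s_max = 9000, seed = 1)
  expect_length(grp, 6L)
  for (g in grp) {
    expect_length(g$members, 1L)
    expect_identical(g$seed, g$members)
    expect_length(g$nonseed, 0L)
    expect_equal(g$seed_size_bp, 80)
  }
})

test_that("a clique collapses into one group whose seed is the start node", {
  set.seed(2)
  rs <- fixed_reads(5)
  edges <- combn(5, 2, simplify = FALSE)
  grp <- build_groups(manual_graph(5, edges), rs, s_max = 1e6, seed = 3)
  expect_length(grp, 1L)
  expect_setequal(grp[[1]]$members, 1:5)
  expect_length(grp[[1]]$seed, 1L)           # everyone else touches the seed
  expect_length(grp[[1]]$nonseed, 4L)
})

test_that("a path graph seeds the two endpoints when started at an end", {
  set.seed(3)
  rs <- fixed_reads(3)
  g <- manual_graph(3, list(c(1, 2), c(2, 3)))
  # find a seed whose random start is node 1 (a, in a-b-c)
  starts <- vapply(1:50, function(s) {
    grp <- build_groups(g, rs, s_max = 1e6, seed = s)
    grp[[1]]$members[1]
  }, integer(1))
  s1 <- which(starts == 1L)[1]
  expect_false(is.na(s1))
  grp <- build_groups(g, rs, s_max = 1e6, seed = s1)
  expect_length(grp, 1L)
  expect_identical(grp[[1]]$members, c(1L, 2L, 3L))
  expect_identical(grp[[1]]$seed, c(1L, 3L))  # b adjacent to a; c is not
  expect_identical(grp[[1]]$nonseed, 2L)
})

test_that("seed_size_bp sums seed read lengths", {
  rs <- read_set(c("a", "b", "c"),
                 c(strrep("A", 80), strrep("C", 80), strrep("G", 40)))
  g <- list(members = 1:3, seed = c(1L, 2L), nonseed = 3L)
  expect_equal(seed_size_bp(g, rs), 160)
  expect_equal(seed_size_bp(list(members = integer(), seed = integer(),
                                 nonseed = integer()), rs), 0)
})

test_that("sixty 150 bp seed reads give the 9000 bp operating seed size", {
  set.seed(4)
  rs <- fixed_reads(60, len = 150)
  grp <- build_groups(manual_graph(60, list()), rs, s_max = 1e6, seed = 1)
  expect_equal(sum(vapply(grp, `[[`, numeric(1), "seed_size_bp")), 9000)
})

test_that("grouping satisfies partition, independence, cap and connectivity", {
  for (trial in 1:3) {
    set.seed(200 + trial)
    com <- pinned_community(200 + trial, n_reads = 400,
                            genome_length = 6000)
    graph <- build_overlap_graph(com$reads, overlap_params())
    s_max <- 2000L
    grp <- build_groups(graph, com$reads, s_max = s_max, seed = trial)
    # partition
    all_members <- unlist(lapply(grp, `[[`, "members"))
    expect_setequal(all_members, seq_len(graph$n))
    expect_equal(length(all_members), graph$n)
    maxlen <- max(read_length(com$reads))
    for (g in grp) {
      # seed/nonseed partition the members
      expect_setequal(c(g$seed, g$nonseed), g$members)
      expect_length(intersect(g$seed, g$nonseed), 0L)
      expect_equal(g$members[1], g$seed[1])   # first member always seeded
      # independence: no edge within the seed
      for (u in g$seed)
        expect_length(intersect(graph$adj[[u]], g$seed), 0L)
      # cap with one-read slack
      expect_lte(g$seed_size_bp, s_max + maxlen)
      # connectivity: each non-first member touches an earlier member
      if (length(g$members) > 1)
        for (j in 2:length(g$members)) {
          u <- g$members[j]
          expect_gt(length(intersect(graph$adj[[u]], g$members[1:(j - 1)])), 0L)
        }
    }
  }
})

test_that("grouping is deterministic given a seed and validates inputs", {
  set.seed(5)
  com <- pinned_community(50, n_reads = 200, genome_length = 4000)
  graph <- build_overlap_graph(com$reads, overlap_params())
  g1 <- build_groups(graph, com$reads, 9000, seed = 99)
  g2 <- build_groups(graph, com$reads, 9000, seed = 99)
  expect_identical(unclass(g1), unclass(g2))
  expect_error(build_groups(graph, com$reads[1:10], 9000), "nodes but")
  expect_error(build_groups(graph, com$reads, 0), "s_max")
})

test_that("groups are species-pure when components do not cross genomes", {
  com <- pinned_community(60, n_reads = 600, genome_length = 6000)
  graph <- build_overlap_graph(com$reads, overlap_params())
  spv <- com$reads$truth$species
  cross <- spv[graph$edges[, 1]] != spv[graph$edges[, 2]]
  expect_equal(sum(cross), 0L)        # divergent models share no 30-mers here
  grp <- build_groups(graph, com$reads, 9000, seed = 1)
  expect_equal(grouping_precision(grp, com$reads), 1.0)
})

test_that("groups dump lists every read once with its seed flag", {
  com <- pinned_community(70, n_reads = 100, genome_length = 4000)
  graph <- build_overlap_graph(com$reads, overlap_params())
  grp <- build_groups(graph, com$reads, 9000, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_groups(grp, com$reads, f)
  dumped <- utils::read.table(f, sep = "\t",
                              col.names = c("read_id", "group", "in_seed"))
  expect_setequal(dumped$read_id, com$reads$id)
  expect_equal(nrow(dumped), length(com$reads))
  expect_true(all(dumped$in_seed %in% 0:1))
})
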