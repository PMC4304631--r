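test_that("species_spec validates and draws stochastic transition models", {
  set.seed(61)
  sp <- species_spec("A", 5000)
  expect_equal(dim(sp$transitions), c(16L, 4L))
  expect_equal(unname(rowSums(sp$transitions)), rep(1, 16), tolerance = 1e-9)
  sp1 <- species_spec("B", 5000, order = 1)
  expect_equal(dim(sp1$transitions), c(4L, 4L))
  expect_error(species_spec("C", 5000, transitions = matrix(1, 2, 4)),
               "must be 16 x 4")
  expect_error(species_spec("D", 5000, abundance = 0), "positive")
})

test_that("a degenerate all-A model produces a homopolymer genome", {
  tr <- matrix(rep(c(1, 0, 0, 0), each = 4), 4, 4)
  sp <- species_spec("mono", 50, transitions = tr, order = 1)
  set.seed(62)
  g <- generate_genome(sp)
  # after the uniform first base the chain locks onto A
  expect_equal(substr(g, 2, 50), strrep("A", 49))
  expect_equal(nchar(g), 50L)
})

test_that("genome length is exact and dinucleotides track an order-1 model", {
  set.seed(63)
  tr <- matrix(stats::rgamma(16, 1), 4, 4)
  tr <- tr / rowSums(tr)
  sp <- species_spec("m1", 100000, transitions = tr, order = 1)
  g <- generate_genome(sp)
  expect_equal(nchar(g), 100000L)
  # empirical conditional frequencies within +-0.02 of the model
  ch <- strsplit(g, "")[[1]]
  from <- ch[-length(ch)]; to <- ch[-1]
  emp <- prop.table(table(factor(from, c("A","C","G","T")),
                          factor(to,   c("A","C","G","T"))), margin = 1)
  expect_lt(max(abs(emp - tr)), 0.02)
})

test_that("error-free forward reads are exact genome substrings at their truth", {
  set.seed(64)
  g <- generate_genome(species_spec("A", 4000))
  rs <- sample_reads(g, 50, read_length = 80, error_rate = 0, label = "A")
  expect_equal(length(rs), 50L)
  tr <- rs$truth
  for (i in seq_len(50)) {
    sub <- substr(g, tr$start[i] + 1, tr$end[i])
    expect_true(rs$seq[i] == sub || rs$seq[i] == reverse_complement(sub))
  }
})

test_that("substitution errors hit roughly the requested rate", {
  set.seed(65)
  g <- generate_genome(species_spec("A", 3000))
  rs <- sample_reads(g, 200, read_length = 80, error_rate = 0.05, label = "A")
  tr <- rs$truth
  mism <- vapply(seq_len(200), function(i) {
    sub <- substr(g, tr$start[i] + 1, tr$end[i])
    d_f <- sum(strsplit(rs$seq[i], "")[[1]] != strsplit(sub, "")[[1]])
    rc <- reverse_complement(sub)
    d_r <- sum(strsplit(rs$seq[i], "")[[1]] != strsplit(rc, "")[[1]])
    min(d_f, d_r)
  }, numeric(1))
  rate <- sum(mism) / (200 * 80)
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})

test_that("paired mode emits mate pairs with /1 and /2 suffixes", {
  set.seed(66)
  g <- generate_genome(species_spec("A", 4000))
  rs <- sample_reads(g, 30, read_length = 80, error_rate = 0, label = "A",
                     paired = TRUE)
  expect_equal(length(rs), 60L)
  expect_equal(sum(grepl("/1$", rs$id)), 30L)
  expect_equal(sum(grepl("/2$", rs$id)), 30L)
  # mates come from the same fragment: /2 interval sits insert-length away
  t1 <- rs$truth[grepl("/1$", rs$id), ]
  t2 <- rs$truth[grepl("/2$", rs$id), ]
  expect_equal(t2$start - t1$start, rep(240 - 80, 30))
})

test_that("community counts follow abundance weights exactly", {
  set.seed(67)
  sp <- list(species_spec("A", 4000, abundance = 1),
             species_spec("B", 4000, abundance = 4))
  com <- simulate_community(sp, n_reads = 1000, error_rate = 0, seed = 67)
  expect_equal(unname(com$counts), c(200L, 800L))
  expect_equal(length(com$reads), 1000L)
  expect_equal(sort(unique(com$reads$truth$species)), c("A", "B"))
  # pinned seed reproduces byte-identical reads
  com2 <- simulate_community(sp, n_reads = 1000, error_rate = 0, seed = 67)
  expect_identical(com$reads$seq, com2$reads$seq)
})

test_that("true_overlap requires same genome and intersecting intervals", {
  tr <- data.frame(read_id = paste0("r", 1:4),
                   species = c("A", "A", "A", "B"),
                   genome = c("g1", "g1", "g1", "g2"),
                   start = c(1, 4, 7, 1), end = c(6, 9, 12, 6))
  rs <- read_set(paste0("r", 1:4), rep(strrep("A", 5), 4), truth = tr)
  expect_true(true_overlap(rs, 1, 2))    # [1,6) meets [4,9)
  expect_false(true_overlap(rs, 1, 3))   # [1,6) vs [7,12): disjoint
  expect_false(true_overlap(rs, 1, 4))   # different genomes
  rs2 <- read_set("x", "ACGTA")
  expect_error(true_overlap(rs2, 1, 1), "no truth")
})

test_that("grouping precision counts majority-species reads", {
  sp <- c(rep("A", 9), "B", rep("B", 10))
  grp <- c(list(list(members = 1:10)),
           lapply(11:20, function(i) list(members = i)))
  expect_equal(grouping_precision(grp, sp), 0.95)   # (9 + 10) / 20
  expect_equal(grouping_precision(rev(grp), sp), 0.95)
  pure <- lapply(1:20, function(i) list(members = i))
  expect_equal(grouping_precision(pure, sp), 1.0)
})

test_that("non-overlapping groups are pairwise disjoint on the genome", {
  set.seed(68)
  g <- generate_genome(species_spec("A", 15000))
  rs <- sample_nonoverlapping_group(g, 60, 150, label = "A")
  expect_equal(length(rs), 60L)
  expect_equal(sum(read_length(rs)), 9000L)
  cb <- utils::combn(60, 2)
  expect_false(any(true_overlap(rs, cb[1, ], cb[2, ])))
  expect_error(sample_nonoverlapping_group(g, 200, 150), "too short")
})

test_that("cross-genome overlap edges are rare for divergent models at q = 30", {
  rates <- vapply(1:3, function(s) {
    com <- pinned_community(s, n_reads = 600, genome_length = 6000)
    g <- build_overlap_graph(com$reads, overlap_params())
    spv <- com$reads$truth$species
    if (!nrow(g$edges)) return(0)
    mean(spv[g$edges[, 1]] != spv[g$edges[, 2]])
  }, numeric(1))
  expect_lt(mean(rates), 0.02)
})

test_that("seeds built from error-free data are mostly truly non-overlapping", {
  # at the operating seed size (~9000 bp of 80 bp reads) only consecutive
  # seed reads can intersect invisibly (< q + m - 1 bases), so the
  # truly-overlapping fraction of seed pairs stays small
  fracs <- vapply(1:2, function(s) {
    com <- pinned_community(s, n_reads = 2400, genome_length = 8000)
    g <- build_overlap_graph(com$reads, overlap_params())
    grp <- build_groups(g, com$reads, 9000, seed = s)
    bad <- 0; tot <- 0
    for (gr in grp) if (length(gr$seed) > 1) {
      cb <- utils::combn(gr$seed, 2)
      tot <- tot + ncol(cb)
      bad <- bad + sum(true_overlap(com$reads, cb[1, ], cb[2, ]))
    }
    bad / tot
  }, numeric(1))
  expect_lt(mean(fracs), 0.05)
})

test_that("truly-overlapping same-strand reads with enough shared bases get an edge", {
  set.seed(69)
  g <- generate_genome(species_spec("A", 2000))
  q <- 30; m <- 5
  # two forward reads sharing exactly q + m - 1 = 34 genome bases
  a <- substr(g, 101, 180)
  b <- substr(g, 147, 226)
  p <- overlap_params(q, m)
  expect_gte(shared_qmer_count(a, b, p), m)
  expect_true(overlaps(a, b, p))
})
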