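# Bin-graph construction: the four structural conditions, shared-reference
# splitting, worst-case equivalence with the basic splice graph.

test_that("a single transcript's bins collapse to one maximal edge", {
  bins <- list(mkbin(c(1, 2, 3), 4, n_exons = 5),
               mkbin(c(2, 3, 4), 6, n_exons = 5),
               mkbin(c(3, 4, 5), 5, n_exons = 5))
  gb <- graph_of_bins(bins)
  ed <- bin_graph_edges(gb$bg)
  exon_edges <- ed[ed$from > 0 & ed$to > 0, ]
  expect_equal(nrow(exon_edges), 1L)
  expect_equal(exon_edges$chain, "1,2,3,4,5")
  expect_equal(bin_graph_nodes(gb$bg), c(1L, 5L))
  expect_length(check_conditions(gb$bg, retained_chains(gb$am, gb$bg)), 0L)
})

test_that("a shared internal exon with crossing bins becomes a node", {
  # three transcripts (1,3,4), (2,3,5), (1,3,5): the shared sub-bins (1,3)
  # and (3,5) sit in two containers each, forcing the joins at exon 3
  bins <- list(mkbin(c(1, 3, 4), 3, n_exons = 5),
               mkbin(c(2, 3, 5), 3, n_exons = 5),
               mkbin(c(1, 3, 5), 3, n_exons = 5),
               mkbin(c(1, 3), 2, n_exons = 5),
               mkbin(c(3, 5), 2, n_exons = 5))
  gb <- graph_of_bins(bins)
  expect_true(3L %in% bin_graph_nodes(gb$bg))
  expect_length(check_conditions(gb$bg, retained_chains(gb$am, gb$bg)), 0L)
})

test_that("unambiguous sharing keeps exons inside maximal edges", {
  # (1,3,4) and (2,3,5) both use exon 3, but nothing crosses: exon 3 stays
  # inside both edges (distinct chains through the same exon)
  bins <- list(mkbin(c(1, 3, 4), 3, n_exons = 5),
               mkbin(c(2, 3, 5), 3, n_exons = 5))
  gb <- graph_of_bins(bins)
  expect_false(3L %in% bin_graph_nodes(gb$bg))
  ed <- bin_graph_edges(gb$bg)
  expect_setequal(ed$chain[ed$from > 0 & ed$to > 0], c("1,3,4", "2,3,5"))
  expect_length(check_conditions(gb$bg, retained_chains(gb$am, gb$bg)), 0L)
})

test_that("splits land on existing nodes without duplicating edges", {
  # (1,2,3) forks into (3,4) and (3,5): its last exon is already the node
  bins <- list(mkbin(c(1, 2, 3), 4, n_exons = 5),
               mkbin(c(3, 4), 3, n_exons = 5),
               mkbin(c(3, 5), 3, n_exons = 5))
  gb <- graph_of_bins(bins)
  ed <- bin_graph_edges(gb$bg)
  expect_true(3L %in% bin_graph_nodes(gb$bg))
  expect_false(anyDuplicated(ed$chain[ed$from > 0 & ed$to > 0]) > 0)
  expect_length(check_conditions(gb$bg, retained_chains(gb$am, gb$bg)), 0L)
})

test_that("with only short bins the graph equals the basic splice graph", {
  # dense alternative structure: adjacent and skip-one pairs everywhere
  for (n in 4:7) {
    bins <- list()
    for (i in seq_len(n - 1L))
      bins <- c(bins, list(mkbin(c(i, i + 1L), 3, n_exons = n)))
    for (i in seq_len(n - 2L))
      bins <- c(bins, list(mkbin(c(i, i + 2L), 3, n_exons = n)))
    gb <- graph_of_bins(bins)
    expect_equal(bin_graph_nodes(gb$bg), seq_len(n))
    ed <- bin_graph_edges(gb$bg)
    exon_edges <- ed[ed$from > 0 & ed$to > 0, ]
    want <- sort(c(sprintf("%d,%d", 1:(n - 1), 2:n),
                   sprintf("%d,%d", 1:(n - 2), 3:n)))
    expect_equal(sort(exon_edges$chain), want)
    expect_length(check_conditions(gb$bg, retained_chains(gb$am, gb$bg)), 0L)
  }
})

test_that("random loci satisfy all four conditions with minimal nodes", {
  set.seed(99)
  for (rep in 1:40) {
    rl <- random_bin_locus()
    gb <- graph_of_bins(rl$bins)
    viol <- check_conditions(gb$bg, retained_chains(gb$am, gb$bg))
    expect_length(viol, 0L)
  }
})

test_that("node labels stay injective and the graph acyclic", {
  set.seed(7)
  for (rep in 1:15) {
    rl <- random_bin_locus()
    gb <- graph_of_bins(rl$bins)
    expect_false(anyDuplicated(gb$bg$nodes) > 0)
    expect_true(binflow:::.bg_is_acyclic(gb$bg))
  }
})

test_that("the worked three-isoform example keeps E and F inside edges", {
  # isoforms (A,C,D,E,F,G), (B,D,E,F,G), (A,C,D,H): the ambiguous exon D
  # must become a node; E and F stay inside the shared suffix edge
  loc <- fig_locus()
  recs <- sample_reads(loc, seed = 7)
  sam <- tempfile(fileext = ".sam")
  emit_sam(recs, sam)
  st <- stream_fragments(sam)
  cl <- cluster_splice_sites(st$junctions)
  loci <- partition_loci(st$deltas, cl$junctions)
  er <- build_exon_ranges(cl$junctions, st$deltas, "chrF",
                          loci$start[1], loci$end[1])
  bb <- build_locus_bins(st$fragments$id, st$fragments$qname,
                         st$fragments$strand, st$fragments$spliced,
                         st$blocks, er$ranges, er$junctions, cl$map, "+")
  gb <- graph_of_bins(bb$bins)
  nodes <- bin_graph_nodes(gb$bg)
  expect_true(4L %in% nodes)    # D
  expect_false(5L %in% nodes)   # E
  expect_false(6L %in% nodes)   # F
  expect_length(check_conditions(gb$bg, retained_chains(gb$am, gb$bg)), 0L)
})

test_that("the minimal-node oracle agrees with first principles", {
  # a bin's terminal exons must be nodes, nothing else is needed here
  chains <- list(c(1L, 2L, 3L), c(1L, 3L))
  expect_equal(minimal_node_count(chains), 2L)
  chains2 <- list(c(1L, 2L), c(2L, 3L))
  expect_equal(minimal_node_count(chains2), 3L)
})
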