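# Coverage pre-correction, guided correction and the convex-cost flow solve.

test_that("uniform coverage with zero overheads is left unchanged", {
  bins <- list(mkbin(c(1, 2, 3), 4), mkbin(c(2, 3, 4), 6))
  gb <- graph_of_bins(bins)
  node_cov <- list(`1` = 10, `4` = 10)
  ed <- bin_graph_edges(gb$bg)
  edge_cov <- as.list(stats::setNames(rep(10, nrow(ed)), ed$name))
  oh <- list(`1` = list(bp = 0, bm = 0), `4` = list(bp = 0, bm = 0))
  cc <- precorrect_coverage(gb$bg, node_cov, edge_cov, oh)
  expect_equal(unlist(cc$node_cov), unlist(node_cov))
  for (nm in ed$name[ed$from > 0 & ed$to > 0])
    expect_equal(cc$edge_cov[[nm]], 10)
})

test_that("forward overheads propagate downstream as hand-computed", {
  # node 1 forks to 3 and 4 via node 2; b+(1)=2 feeds node 2 and is split
  # over the out-edges by their relative coverage
  bins <- list(mkbin(c(1, 2), 4, n_exons = 4),
               mkbin(c(2, 3), 4, n_exons = 4),
               mkbin(c(2, 4), 4, n_exons = 4))
  gb <- graph_of_bins(bins)  # nodes 1..4
  ed <- bin_graph_edges(gb$bg)
  node_cov <- list(`1` = 11, `2` = 10, `3` = 5, `4` = 5)
  edge_cov <- list()
  for (i in seq_len(nrow(ed)))
    edge_cov[[ed$name[i]]] <- switch(ed$chain[i], "1,2" = 10, "2,3" = 5,
                                     "2,4" = 5, 0)
  oh <- list(`1` = list(bp = 2, bm = 0), `2` = list(bp = 0, bm = 0),
             `3` = list(bp = 0, bm = 0), `4` = list(bp = 0, bm = 0))
  cc <- precorrect_coverage(gb$bg, node_cov, edge_cov, oh)
  # cov_f(2) = (cov_f(1) + b1+) * 1 - b2- = 2; downstream nodes each see the
  # full correction of their unique predecessor, edges get the split share
  expect_equal(cc$node_cov[["2"]], 12)
  expect_equal(cc$node_cov[["3"]], 7)
  expect_equal(cc$node_cov[["4"]], 7)
  expect_equal(cc$node_cov[["1"]], 11)  # source node: no incoming mass
  nm23 <- ed$name[ed$chain == "2,3"]
  expect_equal(cc$edge_cov[[nm23]], 6)  # 5 + 2 * 5/10
})

test_that("incoming mass is apportioned by relative edge coverage", {
  # two in-edges with cov 30 and 10 split contributions 3:1
  bins <- list(mkbin(c(1, 3), 30, n_exons = 4), mkbin(c(2, 3), 10,
                                                      n_exons = 4),
               mkbin(c(3, 4), 40, n_exons = 4))
  gb <- graph_of_bins(bins)
  ed <- bin_graph_edges(gb$bg)
  nm13 <- ed$name[ed$chain == "1,3"]
  nm23 <- ed$name[ed$chain == "2,3"]
  nm34 <- ed$name[ed$chain == "3,4"]
  node_cov <- list(`1` = 30, `2` = 10, `3` = 40, `4` = 40)
  edge_cov <- list(); edge_cov[[nm13]] <- 30; edge_cov[[nm23]] <- 10
  edge_cov[[nm34]] <- 40
  for (nm in ed$name[!(ed$name %in% c(nm13, nm23, nm34))]) edge_cov[[nm]] <- 0
  oh <- list(`1` = list(bp = 4, bm = 0), `2` = list(bp = 0, bm = 0),
             `3` = list(bp = 0, bm = 0), `4` = list(bp = 0, bm = 0))
  cc <- precorrect_coverage(gb$bg, node_cov, edge_cov, oh)
  # cov_f(3) = (0+4) * 30/40 + (0+0) * 10/40 = 3
  expect_equal(cc$node_cov[["3"]], 43)
})

test_that("pre-correction never decreases coverage", {
  set.seed(44)
  for (rep in 1:10) {
    rl <- random_bin_locus()
    gb <- graph_of_bins(rl$bins)
    ed <- bin_graph_edges(gb$bg)
    node_cov <- as.list(stats::setNames(
      sample(5:40, length(gb$bg$nodes), replace = TRUE),
      as.character(sort(gb$bg$nodes))))
    edge_cov <- as.list(stats::setNames(sample(5:40, nrow(ed),
                                               replace = TRUE), ed$name))
    oh <- lapply(node_cov, function(x)
      list(bp = sample(0:5, 1), bm = sample(0:5, 1)))
    cc <- precorrect_coverage(gb$bg, node_cov, edge_cov, oh)
    expect_true(all(unlist(cc$node_cov) >= unlist(node_cov) - 1e-9))
    expect_true(all(unlist(cc$edge_cov) >= unlist(edge_cov) - 1e-9))
  }
})

test_that("noise-discounted overheads vanish on uniform coverage", {
  deltas <- coverage_deltas(data.frame(chrom = "c", start = rep(0L, 20),
                                       end = rep(200L, 20)))
  ranges <- data.frame(index = 1L, start = 0L, end = 200L,
                       left_kind = "coverage_edge",
                       right_kind = "coverage_edge")
  oh <- node_overheads(1L, ranges, deltas, "c")
  expect_equal(oh[["1"]]$bp, 0)
  expect_equal(oh[["1"]]$bm, 0)
  # a strong step up: left boundary far below the maximum
  st <- coverage_deltas(data.frame(
    chrom = "c", start = c(rep(0L, 10), rep(100L, 40)),
    end = rep(200L, 50)))
  oh2 <- node_overheads(1L, ranges, st, "c")
  expect_gt(oh2[["1"]]$bm, 10)
  expect_equal(oh2[["1"]]$bp, 0)
})

test_that("a consistent single path carries its coverage as flow", {
  arcs <- data.frame(id = c("n5", "es", "et"),
                     tail = c("5.in", "s", "5.out"),
                     head = c("5.out", "5.in", "t"),
                     cov = c(10, 0, 0), w = c(1, 0, 0),
                     free = c(FALSE, TRUE, TRUE), stringsAsFactors = FALSE)
  sol <- solve_utec(mknet(arcs))
  expect_equal(unname(sol$flow["n5"]), 10)
  expect_equal(sol$objective, 0)
})

test_that("the Y-split solve matches exhaustive enumeration", {
  arcs <- data.frame(
    id = c("na", "nb", "nc", "eab", "eac", "es", "ebt", "ect"),
    tail = c("a.in", "b.in", "c.in", "a.out", "a.out", "s", "b.out", "c.out"),
    head = c("a.out", "b.out", "c.out", "b.in", "c.in", "a.in", "t", "t"),
    cov = c(10, 6, 3, 6, 3, 0, 0, 0), w = c(1, 1, 1, 1, 1, 0, 0, 0),
    free = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  net <- mknet(arcs)
  sol <- solve_utec(net)
  brute <- utec_brute_objective(net, max_flow = 25)
  expect_equal(sol$objective, brute$objective)
  # conservation at every internal vertex
  verts <- setdiff(unique(c(arcs$tail, arcs$head)), c("s", "t"))
  for (v in verts) {
    fin <- sum(sol$flow[arcs$id[arcs$head == v]])
    fout <- sum(sol$flow[arcs$id[arcs$tail == v]])
    expect_equal(fin, fout)
  }
})

test_that("solver matches the brute-force oracle on random networks", {
  set.seed(15)
  for (rep in 1:25) {
    net <- rand_flow_net()
    sol <- solve_utec(net)
    brute <- utec_brute_objective(net, max_flow = 45)
    expect_equal(sol$objective, brute$objective, tolerance = 1e-9)
  }
})

test_that("deviation costs scale with degree-one homogeneity", {
  set.seed(16)
  for (rep in 1:10) {
    net <- rand_flow_net()
    sol <- solve_utec(net)
    net10 <- net; net10$arcs$cov <- net$arcs$cov * 10
    # the identity c(kx; kc) = k c(x; c): the scaled flow costs exactly 10x
    expect_equal(utec_cost(net10, 10 * sol$flow), 10 * sol$objective,
                 tolerance = 1e-9)
    # and the scaled problem can only do at least as well
    sol10 <- solve_utec(net10)
    expect_lte(sol10$objective, 10 * sol$objective + 1e-9)
  }
})

test_that("guided correction allocates shared coverage between guides", {
  # two transcripts (1,3) and (2,3) share their last exon 3 (cov 10);
  # private first exons carry 6 and 4
  bins <- list(mkbin(c(1, 3), 6, n_exons = 3), mkbin(c(2, 3), 4,
                                                     n_exons = 3))
  gb <- graph_of_bins(bins)
  ed <- bin_graph_edges(gb$bg)
  nm13 <- ed$name[ed$chain == "1,3"]; nm23 <- ed$name[ed$chain == "2,3"]
  node_cov <- list(`1` = 6, `2` = 4, `3` = 10)
  edge_cov <- list(); edge_cov[[nm13]] <- 6; edge_cov[[nm23]] <- 4
  for (nm in setdiff(ed$name, c(nm13, nm23))) edge_cov[[nm]] <- 0
  gc <- guided_correct(gb$bg, node_cov, edge_cov,
                       list(c(1L, 3L), c(2L, 3L)), trust_threshold = 0.9)
  expect_equal(gc$n_used, 2L)
  expect_equal(gc$F, 1)           # guides explain all coverage
  expect_equal(gc$node_cov[["3"]], 10)  # 6 + 4 summed on the shared exon
  expect_equal(gc$node_cov[["1"]], 6)
  expect_equal(gc$node_cov[["2"]], 4)
  # empty guide set leaves everything untouched
  gc0 <- guided_correct(gb$bg, node_cov, edge_cov, list(), 0.5)
  expect_equal(gc0$node_cov, node_cov)
  expect_equal(gc0$n_used, 0L)
})

test_that("incompatible guides are dropped", {
  bins <- list(mkbin(c(1, 2), 5, n_exons = 3))
  gb <- graph_of_bins(bins)
  ed <- bin_graph_edges(gb$bg)
  node_cov <- list(`1` = 5, `2` = 5)
  edge_cov <- as.list(stats::setNames(rep(5, nrow(ed)), ed$name))
  gc <- guided_correct(gb$bg, node_cov, edge_cov, list(c(1L, 3L)), 0.5)
  expect_equal(gc$n_dropped, 1L)
})
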