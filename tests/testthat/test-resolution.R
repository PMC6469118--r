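# Simplification, phasing evidence, two-step LP, noise filters and
# transcript extraction.

test_that("linear chains contract to a single edge with flow preserved", {
  bins <- list(mkbin(c(1, 2, 3), 5))
  gb <- graph_of_bins(bins)
  ed <- bin_graph_edges(gb$bg)
  fl <- stats::setNames(rep(7, nrow(ed)), ed$name)
  cov <- stats::setNames(rep(7, nrow(ed)), ed$name)
  sg <- simplify_graph(gb$bg, as.list(fl), cov)
  expect_equal(length(sg$edges), 1L)
  e <- sg$edges[[1]]
  expect_equal(e$from, 0L); expect_equal(e$to, -1L)
  expect_equal(e$chain, 1:3)
  expect_equal(e$fl, 7)
})

test_that("tree nodes contract, 2x2 diamonds stay unresolved", {
  sg <- mksg(list(
    list(from = 0L, to = 1L, chain = integer(0), fl = 20),
    list(from = 0L, to = 2L, chain = integer(0), fl = 20),
    list(from = 1L, to = 3L, chain = c(1L, 3L), fl = 20),
    list(from = 2L, to = 3L, chain = c(2L, 3L), fl = 20),
    list(from = 3L, to = 4L, chain = c(3L, 4L), fl = 20),
    list(from = 3L, to = 5L, chain = c(3L, 5L), fl = 20),
    list(from = 4L, to = -1L, chain = integer(0), fl = 20),
    list(from = 5L, to = -1L, chain = integer(0), fl = 20)))
  binflow:::.sg_contract(sg)
  un <- unresolved_nodes(sg)
  expect_equal(un$node, 3L)
  expect_equal(un$n_in, 2L)
  expect_equal(un$n_out, 2L)
})

test_that("conservation violations are fatal in strict simplification", {
  sg <- mksg(list(
    list(from = 0L, to = 1L, chain = integer(0), fl = 10),
    list(from = 1L, to = 2L, chain = c(1L, 2L), fl = 10),
    list(from = 2L, to = -1L, chain = integer(0), fl = 4)))
  expect_error(binflow:::.sg_contract(sg, strict = TRUE), "conservation")
})

test_that("sub-bins of spanning bins are dropped from the evidence", {
  sg <- mksg(list(
    list(from = 0L, to = 3L, chain = c(1L, 3L), fl = 10),
    list(from = 0L, to = 3L, chain = c(2L, 3L), fl = 10),
    list(from = 3L, to = -1L, chain = c(3L, 4L), fl = 10),
    list(from = 3L, to = -1L, chain = c(3L, 5L), fl = 10)))
  bins <- list(mkbin(c(1, 3, 4), 6, n_exons = 5),
               mkbin(c(1, 3), 3, n_exons = 5))   # prefix of the longer bin
  evs <- collect_evidence(sg, bins, list())
  ev <- evs[["3"]]$specific
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n, 6)  # the sub-bin added nothing
})

test_that("evidence explainable by a bypass edge is not counted", {
  sg <- mksg(list(
    list(from = 0L, to = 3L, chain = c(1L, 2L, 3L), fl = 10),
    list(from = 0L, to = 3L, chain = c(1L, 3L), fl = 10),
    list(from = 3L, to = -1L, chain = c(3L, 4L, 5L), fl = 10),
    list(from = 3L, to = -1L, chain = c(3L, 5L), fl = 10),
    list(from = 0L, to = -1L, chain = c(1L, 2L, 4L, 5L), fl = 10)))
  # pair (1,2) x (4,5) fits inside the bypass edge: must not appear at node 3
  links <- list(list(left = c(1L, 2L), right = c(4L, 5L), count = 9))
  evs <- collect_evidence(sg, list(), links)
  if (!is.null(evs[["3"]])) {
    expect_equal(nrow(evs[["3"]]$specific), 0L)
    expect_length(evs[["3"]]$ambiguous, 0L)
  } else succeed()
})

test_that("a mate beyond an internal edge keeps the pairing ambiguous", {
  # out-edges: (3,5,6) to sink and (3,4) to node 4; a right mate (6) fits
  # inside the first but could also continue past node 4
  sg <- mksg(list(
    list(from = 0L, to = 3L, chain = c(1L, 3L), fl = 10),
    list(from = 0L, to = 3L, chain = c(2L, 3L), fl = 10),
    list(from = 3L, to = -1L, chain = c(3L, 5L, 6L), fl = 10),
    list(from = 3L, to = 4L, chain = c(3L, 4L), fl = 10),
    list(from = 4L, to = -1L, chain = c(4L, 6L), fl = 6),
    list(from = 4L, to = -1L, chain = c(4L, 7L), fl = 4)))
  links <- list(list(left = c(1L), right = c(6L), count = 5))
  evs <- collect_evidence(sg, list(), links)
  ev3 <- evs[["3"]]
  expect_equal(nrow(ev3$specific), 0L)
  expect_true(length(ev3$ambiguous) >= 1L)
})

test_that("perfect phasing resolves a 2x2 node exactly", {
  fl <- list(e1 = 10, e2 = 2, f1 = 10, f2 = 2)
  ev <- data.frame(e = c("e1", "e2"), ep = c("f1", "f2"), n = c(10, 2),
                   stringsAsFactors = FALSE)
  r <- resolve_node(fl, ev)
  expect_equal(r$x$x, c(10, 2))
  expect_equal(unname(r$y[c("e1", "e2", "f1", "f2")]), c(0, 0, 0, 0))
  expect_equal(r$obj1, 0)
  expect_equal(r$obj2, 0, tolerance = 1e-6)
})

test_that("two-step objectives match the integer-grid oracle", {
  set.seed(5)
  n_done <- 0
  while (n_done < 25) {
    nS <- sample(1:3, 1); nT <- sample(1:3, 1)
    S <- paste0("i", seq_len(nS)); T_ <- paste0("o", seq_len(nT))
    fl <- as.list(stats::setNames(sample(1:12, nS + nT, replace = TRUE),
                                  c(S, T_)))
    pairs <- expand.grid(e = S, ep = T_, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(pairs)) < 0.6
    if (!any(keep) || sum(keep) > 4) next
    ev <- pairs[keep, , drop = FALSE]
    ev$n <- sample(0:12, nrow(ev), replace = TRUE)
    r <- resolve_node(fl, ev)
    if (is.null(r)) next
    b1 <- brute_resolve(fl, ev)
    expect_equal(r$obj1, b1$obj1, tolerance = 1e-4)
    b2 <- brute_resolve(fl, ev, lb = round(r$x1))
    expect_equal(r$obj2, b2$obj2, tolerance = 1e-4)
    n_done <- n_done + 1
  }
})

test_that("evidence covering one in-edge leaves the other's flow intact", {
  sg <- mksg(list(
    list(from = 0L, to = 3L, chain = c(1L, 3L), fl = 10),
    list(from = 0L, to = 3L, chain = c(2L, 3L), fl = 7),
    list(from = 3L, to = -1L, chain = c(3L, 4L), fl = 10),
    list(from = 3L, to = -1L, chain = c(3L, 5L), fl = 7)))
  bins <- list(mkbin(c(1, 3, 4), 9, n_exons = 5))
  resolve_graph(sg, bins, list())
  chains <- vapply(sg$edges, function(e) chain_key(e$chain), character(1))
  expect_true("1,3,4" %in% chains)
  # the unevidenced in-edge (2,3) kept its flow for decomposition
  leftover <- vapply(sg$edges, function(e) e$fl, numeric(1))
  expect_true(any(grepl("^2,3", chains) | chains == "2,3,5"))
  expect_equal(sum(leftover[chains != "1,3,4"]), 7)
})

test_that("weak unevidenced edges fall to the 30%/75% filter", {
  build <- function(weak_fl, weak_evid) {
    sg <- mksg(list(
      list(from = 0L, to = 1L, chain = integer(0), fl = 100 + weak_fl),
      list(from = 1L, to = 2L, chain = c(1L, 2L), fl = 100, evid = TRUE),
      list(from = 1L, to = 2L, chain = c(1L, 3L, 2L)[c(1, 3)], fl = weak_fl,
           evid = weak_evid),
      list(from = 2L, to = -1L, chain = integer(0), fl = 100 + weak_fl)))
    sg
  }
  spec_row <- data.frame(e = "r2", ep = "r2", n = 5, rank = 2L)
  evs <- list(`1` = list(specific = spec_row, ambiguous = list()),
              `2` = list(specific = spec_row, ambiguous = list()))
  sg <- build(20, FALSE)
  expect_equal(filter_edges(sg, evs), 1L)   # 20 < 0.30 * 100: removed
  sg2 <- build(40, FALSE)
  expect_equal(filter_edges(sg2, evs), 0L)  # 40 >= 30: kept
  sg3 <- build(10, TRUE)
  expect_equal(filter_edges(sg3, evs), 0L)  # evidence-backed: immune
  # nodes without any evidence apply the stricter 75% rule
  expect_equal(filter_edges(build(70, FALSE), list()), 1L)
  expect_equal(filter_edges(build(80, FALSE), list()), 0L)
})

test_that("the edge filter is idempotent", {
  set.seed(61)
  for (rep in 1:5) {
    k <- sample(3:6, 1)
    edges <- lapply(seq_len(k), function(i)
      list(from = 0L, to = -1L, chain = c(1L, i + 1L, 8L),
           fl = sample(5:60, 1), evid = FALSE))
    sg <- mksg(edges)
    evs <- collect_evidence(sg, list(), list())
    filter_edges(sg, evs)
    snapshot <- vapply(sg$edges, function(e) chain_key(e$chain), character(1))
    expect_equal(filter_edges(sg, evs), 0L)
    expect_equal(vapply(sg$edges, function(e) chain_key(e$chain),
                        character(1)), snapshot)
  }
})

test_that("unsupported retained introns are filtered by coverage", {
  ranges <- data.frame(index = 1:3, start = c(0L, 100L, 200L),
                       end = c(100L, 200L, 300L),
                       left_kind = "splice", right_kind = "splice")
  mk <- function(intron_depth) {
    blocks <- data.frame(chrom = "c",
                         start = c(rep(0L, 20), rep(200L, 20),
                                   rep(100L, intron_depth)),
                         end = c(rep(100L, 20), rep(300L, 20),
                                 rep(200L, intron_depth)))
    coverage_deltas(blocks)
  }
  build <- function() mksg(list(
    list(from = 0L, to = 1L, chain = integer(0), fl = 25),
    list(from = 1L, to = 3L, chain = c(1L, 3L), fl = 20),      # splice
    list(from = 1L, to = 3L, chain = c(1L, 2L, 3L), fl = 5),   # retention
    list(from = 3L, to = -1L, chain = integer(0), fl = 25)))
  sg_low <- build()
  expect_equal(filter_intron_retention(sg_low, ranges, mk(1L), "c"), 1L)
  sg_high <- build()
  expect_equal(filter_intron_retention(sg_high, ranges, mk(16L), "c"), 0L)
  # no intron-spanning chains: nothing happens
  sg_none <- mksg(list(
    list(from = 0L, to = 1L, chain = integer(0), fl = 20),
    list(from = 1L, to = 3L, chain = c(1L, 3L), fl = 20),
    list(from = 3L, to = -1L, chain = integer(0), fl = 20)))
  expect_equal(filter_intron_retention(sg_none, ranges, mk(1L), "c"), 0L)
})

test_that("decomposition prefers the longest path, then bottleneck", {
  sg <- mksg(list(
    list(from = 0L, to = -1L, chain = c(1L, 2L, 3L, 4L), fl = 3),
    list(from = 0L, to = -1L, chain = c(1L, 4L), fl = 10)))
  txs <- extract_transcripts(sg)
  expect_equal(length(txs), 2L)
  expect_equal(txs[[1]]$chain, 1:4)    # longest first despite lower flow
  expect_equal(txs[[1]]$flow, 3)
  expect_equal(txs[[2]]$chain, c(1L, 4L))
  expect_equal(txs[[2]]$flow, 10)
})

test_that("parallel disjoint paths decompose exactly", {
  sg <- mksg(list(
    list(from = 0L, to = -1L, chain = c(1L, 2L), fl = 7),
    list(from = 0L, to = -1L, chain = c(3L, 4L), fl = 3)))
  txs <- extract_transcripts(sg)
  expect_equal(length(txs), 2L)
  expect_equal(sort(vapply(txs, `[[`, numeric(1), "flow")), c(3, 7))
})

test_that("decomposition drains all source outflow", {
  set.seed(17)
  sg <- mksg(list(
    list(from = 0L, to = 1L, chain = integer(0), fl = 12),
    list(from = 0L, to = 2L, chain = integer(0), fl = 8),
    list(from = 1L, to = 3L, chain = c(1L, 3L), fl = 12),
    list(from = 2L, to = 3L, chain = c(2L, 3L), fl = 8),
    list(from = 3L, to = -1L, chain = c(3L, 4L), fl = 20)))
  total_out <- 20
  txs <- extract_transcripts(sg)
  expect_equal(sum(vapply(txs, `[[`, numeric(1), "flow")), total_out)
})

test_that("guided transcripts are extracted first and protected", {
  sg <- mksg(list(
    list(from = 0L, to = -1L, chain = c(1L, 2L, 3L), fl = 50),
    list(from = 0L, to = -1L, chain = c(1L, 3L), fl = 4)))
  txs <- extract_transcripts(sg, guided_chains = list(c(1L, 3L)))
  expect_true(txs[[1]]$guided)
  expect_equal(txs[[1]]$chain, c(1L, 3L))
  kept <- guided_abundance_filter(txs, trust = 100)
  # threshold at trust 100 is 25% of the maximum: the guided 4 < 12.5 stays,
  # an unguided one would have been dropped
  expect_true(any(vapply(kept, `[[`, logical(1), "guided")))
  txs2 <- list(list(chain = 1:3, flow = 100, guided = FALSE),
               list(chain = c(1L, 3L), flow = 1, guided = FALSE))
  expect_length(guided_abundance_filter(txs2, 100), 1L)
  expect_length(guided_abundance_filter(txs2, 0), 2L)
})
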