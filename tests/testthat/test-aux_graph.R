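# Auxiliary overlap/containment graph: edge construction, stripping,
# transitive reduction, unique-chain merging and absorption.

test_that("overlap and containment edges follow suffix/prefix semantics", {
  bins <- list(mkbin(c(1, 2, 3), 4), mkbin(c(2, 3, 4), 4),
               mkbin(c(2, 3), 2, n_exons = 4))
  g <- build_aux_edges(bins)
  ov <- g$overlap
  expect_true(any(ov$from == 1 & ov$to == 2 & ov$olap == 2))
  expect_true(any(g$contained$from == 3 & g$contained$to == 1))
  expect_true(any(g$contained$from == 3 & g$contained$to == 2))
})

test_that("containment means contiguous infix, not arbitrary subset", {
  bins <- list(mkbin(c(1, 3), 2, n_exons = 4), mkbin(c(1, 2, 3, 4), 5))
  g <- build_aux_edges(bins)
  expect_equal(nrow(g$contained), 0L)  # (1,3) skips 2: not an infix
})

test_that("contained bins lose their overlap edges", {
  bins <- list(mkbin(c(1, 2), 3, n_exons = 4), mkbin(c(2, 3), 3, n_exons = 4),
               mkbin(c(1, 2, 3), 9, n_exons = 4))
  g <- strip_and_reduce(build_aux_edges(bins))
  contained <- unique(g$contained$from)
  expect_true(all(!g$overlap$from %in% contained))
  expect_true(all(!g$overlap$to %in% contained))
})

test_that("transitive reduction matches the brute-force oracle", {
  set.seed(12)
  for (rep in 1:20) {
    n_exons <- sample(5:9, 1)
    nb <- sample(4:10, 1)
    bins <- unique(lapply(seq_len(nb), function(i) {
      len <- sample(2:4, 1)
      start <- sample(n_exons - len + 1L, 1)
      seq(start, start + len - 1L)
    }))
    bins <- lapply(bins, function(ch) mkbin(ch, 2, n_exons = n_exons))
    g0 <- build_aux_edges(bins)
    g <- strip_and_reduce(g0)
    # oracle applied to the same stripped edge set
    contained <- unique(g0$contained$from)
    ov0 <- g0$overlap[!(g0$overlap$from %in% contained |
                          g0$overlap$to %in% contained), , drop = FALSE]
    oracle <- brute_transitive_reduction(ov0, length(bins))
    got <- g$overlap[order(g$overlap$from, g$overlap$to), c("from", "to")]
    want <- oracle[order(oracle$from, oracle$to), c("from", "to")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("no transitive edges means the graph is untouched", {
  bins <- list(mkbin(c(1, 2), 3, n_exons = 4), mkbin(c(2, 4), 3, n_exons = 4))
  g0 <- build_aux_edges(bins)
  g <- strip_and_reduce(g0)
  expect_equal(g$overlap, g0$overlap)
})

test_that("uniquely chained bins merge; diamonds do not", {
  # unique chain: a -> b only
  bins <- list(mkbin(c(1, 2, 3), 4), mkbin(c(2, 3, 4), 6))
  am <- merge_unique_chains(strip_and_reduce(build_aux_edges(bins)))
  expect_equal(length(am$maximal), 1L)
  expect_equal(am$maximal[[1]]$chain, 1:4)
  expect_equal(am$maximal[[1]]$count, 10)
  # diamond a -> {b, c} -> d: every overlap path shares a and d, no merge
  dia <- list(mkbin(c(1, 2), 1, n_exons = 6),
              mkbin(c(2, 3, 5), 1, n_exons = 6),
              mkbin(c(2, 4, 5), 1, n_exons = 6),
              mkbin(c(5, 6), 1, n_exons = 6))
  am2 <- merge_unique_chains(strip_and_reduce(build_aux_edges(dia)))
  expect_equal(length(am2$maximal), 4L)
})

test_that("bins inside one maximal bin are absorbed with their counts", {
  bins <- list(mkbin(c(1, 2, 3, 4), 5), mkbin(c(2, 3), 7))
  am <- merge_unique_chains(strip_and_reduce(build_aux_edges(bins)))
  expect_equal(length(am$maximal), 1L)
  expect_equal(am$maximal[[1]]$count, 12)
  expect_equal(length(am$multi_contained), 0L)
})

test_that("read counts are conserved across merging and absorption", {
  set.seed(19)
  for (rep in 1:10) {
    rl <- random_bin_locus()
    total <- sum(vapply(rl$bins, `[[`, numeric(1), "count"))
    am <- merge_unique_chains(strip_and_reduce(build_aux_edges(rl$bins)))
    kept <- sum(vapply(am$maximal, `[[`, numeric(1), "count")) +
      sum(vapply(am$multi_contained, `[[`, numeric(1), "count"))
    expect_equal(kept, total)
  }
})

test_that("remaining overlap edges always mark genuine ambiguity", {
  set.seed(23)
  n_edges_seen <- 0L
  fork <- list(mkbin(c(1, 2, 3), 4), mkbin(c(2, 3, 4), 3),
               mkbin(c(2, 3, 5), 3))
  bin_sets <- c(list(fork),
                lapply(1:9, function(i) random_bin_locus()$bins))
  for (bins in bin_sets) {
    am <- merge_unique_chains(strip_and_reduce(build_aux_edges(bins)))
    ov <- am$overlap
    n_edges_seen <- n_edges_seen + nrow(ov)
    for (k in seq_len(nrow(ov))) {
      out_deg <- sum(ov$from == ov$from[k])
      in_deg <- sum(ov$to == ov$to[k])
      expect_true(out_deg >= 2L || in_deg >= 2L)
    }
  }
  expect_gte(n_edges_seen, 1L)
})
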