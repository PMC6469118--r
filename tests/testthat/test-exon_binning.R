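# Splice-site clustering, exon-range derivation, bin assignment, mate
# combination and coverage queries.

test_that("splice-site clustering merges near-identical junctions", {
  jn <- data.frame(chrom = "chr1", strand = "+",
                   donor = c(1000L, 1002L), acceptor = c(2000L, 2002L),
                   support = c(50L, 1L), stringsAsFactors = FALSE)
  cl <- cluster_splice_sites(jn, bandwidth = 3L)
  expect_equal(nrow(cl$junctions), 1L)
  expect_equal(cl$junctions$donor, 1000L)   # canonical = max support
  expect_equal(cl$junctions$support, 51L)
  expect_equal(cl$map$c_donor, c(1000L, 1000L))
})

test_that("distant junctions and empty input pass through clustering", {
  jn <- data.frame(chrom = "chr1", strand = "+",
                   donor = c(1000L, 2000L), acceptor = c(1500L, 2500L),
                   support = c(5L, 5L), stringsAsFactors = FALSE)
  cl <- cluster_splice_sites(jn, bandwidth = 3L)
  expect_equal(nrow(cl$junctions), 2L)
  cl0 <- cluster_splice_sites(jn[0, ], bandwidth = 3L)
  expect_equal(nrow(cl0$junctions), 0L)
})

test_that("exon ranges split fully covered loci at every splice site", {
  # full coverage on [0,300) with junctions 100->200 and 150->250:
  # boundaries {0,100,150,200,250,300} give five ranges
  deltas <- coverage_deltas(data.frame(chrom = "c", start = 0L, end = 300L))
  jn <- data.frame(chrom = "c", strand = "+", donor = c(100L, 150L),
                   acceptor = c(200L, 250L), support = c(5L, 5L),
                   stringsAsFactors = FALSE)
  er <- build_exon_ranges(jn, deltas, "c", 0L, 300L)
  expect_equal(er$ranges$start, c(0L, 100L, 150L, 200L, 250L))
  expect_equal(er$ranges$end, c(100L, 150L, 200L, 250L, 300L))
})

test_that("intronic gaps yield disjoint ranges and stray junctions drop", {
  deltas <- coverage_deltas(data.frame(chrom = "c",
                                       start = c(0L, 200L),
                                       end = c(100L, 300L)))
  jn <- data.frame(chrom = "c", strand = "+", donor = c(100L, 5000L),
                   acceptor = c(200L, 6000L), support = c(5L, 1L),
                   stringsAsFactors = FALSE)
  expect_warning(er <- build_exon_ranges(jn, deltas, "c", 0L, 300L),
                 "outside covered region")
  expect_equal(nrow(er$ranges), 2L)
  expect_equal(nrow(er$junctions), 1L)
})

test_that("fragments map to the ordered overlapping exon ranges", {
  ranges <- data.frame(index = 1:3, start = c(0L, 100L, 300L),
                       end = c(100L, 200L, 400L),
                       left_kind = "splice", right_kind = "splice",
                       stringsAsFactors = FALSE)
  jk <- c("200:300")
  contiguous <- data.frame(start = c(50L), end = c(150L))
  expect_equal(bin_of_fragment(contiguous, ranges, jk)$chain, c(1L, 2L))
  spliced <- data.frame(start = c(150L, 300L), end = c(200L, 350L))
  expect_equal(bin_of_fragment(spliced, ranges, jk)$chain, c(2L, 3L))
  # junction skipping range 2 entirely is not canonical here: rejected
  bad <- data.frame(start = c(50L, 300L), end = c(100L, 350L))
  expect_null(bin_of_fragment(bad, ranges, jk))
})

test_that("mate combination merges overlap and adjacency, links gaps", {
  expect_equal(combine_mates(c(1L, 2L, 3L), c(3L, 4L))$chain, 1:4)
  expect_equal(combine_mates(c(1L, 2L), c(3L, 4L))$chain, 1:4)
  lk <- combine_mates(c(1L, 2L), c(4L, 5L))
  expect_equal(lk$kind, "link")
  expect_equal(lk$left, c(1L, 2L))
  expect_equal(lk$right, c(4L, 5L))
  # disagreeing overlap is rejected as noise
  expect_equal(combine_mates(c(1L, 2L, 4L), c(2L, 3L, 5L))$kind, "reject")
})

test_that("mate combination is symmetric in mate order", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    a <- sort(sample(n, sample(2:3, 1)))
    b <- sort(sample(n, sample(2:3, 1)))
    r1 <- combine_mates(a, b)
    r2 <- combine_mates(b, a)
    expect_identical(r1, r2)
  }
})

test_that("coverage queries report mean, boundary and max depth", {
  # 10 reads of length 100 fully covering a 100 bp exon
  deltas <- coverage_deltas(data.frame(chrom = "c", start = rep(0L, 10),
                                       end = rep(100L, 10)))
  expect_equal(exon_cov(deltas, "c", 0L, 100L), 10)
  bc <- boundary_cov(deltas, "c", 0L, 100L)
  expect_equal(bc$left, 10)
  expect_equal(bc$right, 10)
  expect_equal(bc$max, 10)
  # staircase: depth 5 on [0,50), 8 on [50,100)
  st <- coverage_deltas(data.frame(chrom = "c",
                                   start = c(rep(0L, 5), rep(50L, 3)),
                                   end = c(rep(100L, 5), rep(100L, 3))))
  bc2 <- boundary_cov(st, "c", 0L, 100L)
  expect_equal(bc2$left, 5)
  expect_equal(bc2$right, 8)
  expect_equal(bc2$max, 8)
  expect_equal(exon_cov(st, "c", 0L, 100L), 6.5)
  expect_error(region_stats(st, "c", 10L, 10L), "zero-length")
})

test_that("every accepted fragment lands in exactly one bin chain", {
  set.seed(8)
  loc <- random_locus(n_isoforms = 3)
  recs <- sample_reads(loc, seed = 3)
  sam <- tempfile(fileext = ".sam")
  emit_sam(recs, sam)
  st <- stream_fragments(sam)
  cl <- cluster_splice_sites(st$junctions)
  loci <- partition_loci(st$deltas, cl$junctions)
  er <- build_exon_ranges(cl$junctions, st$deltas, loc$chrom,
                          loci$start[1], loci$end[1])
  bb <- build_locus_bins(st$fragments$id, st$fragments$qname,
                         st$fragments$strand, st$fragments$spliced,
                         st$blocks, er$ranges, er$junctions, cl$map, "+")
  expect_equal(bb$assigned + bb$rejected, nrow(st$fragments))
  # ranges tile the covered locus without straddling a splice site
  expect_true(all(er$ranges$end[-nrow(er$ranges)] <=
                    er$ranges$start[-1]))
  for (d in er$junctions$donor)
    expect_true(d %in% er$ranges$end || d <= min(er$ranges$start))
})
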