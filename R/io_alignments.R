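#' Read spliced paired-end alignments into fragments, junctions and coverage
#'
#' Streams a coordinate-sorted SAM/BAM file (SAM input is converted and
#' indexed on the fly), skipping secondary, supplementary and unmapped
#' records, and decomposes each primary record's CIGAR into aligned reference
#' blocks: M/=/X/D consume reference into blocks, N splits blocks, I/S consume
#' none.  Reference gaps shorter than `min_intron` are treated as deletions
#' and merged into a single block; the remaining gaps are splice junctions.
#' Junction strand is taken from the XS tag; spliced reads without the tag get
#' strand "*" and are resolved downstream against the locus strand.
#'
#' @param path SAM or BAM file (coordinate sorted)
#' @param region optional `GRanges` restricting the scan
#' @param min_intron minimum intron length in bp (default 30); shorter
#'   reference skips are merged into their flanking blocks
#' @return list with elements `fragments` (data.frame: id, qname, chrom,
#'   strand, spliced), `blocks` (data.frame: id, chrom, start, end; 0-based
#'   half-open), `junctions` (data.frame: chrom, strand, donor, acceptor,
#'   support), `deltas` (a [coverage_deltas()] store over all fragments) and
#'   `n_templates` (number of distinct read names)
#' @export
stream_fragments <- function(path, region = NULL, min_intron = 30L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressWarnings(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                             indexDestination = TRUE))
  } else if (!file.exists(paste0(path, ".bai")) &&
             !file.exists(sub("\\.bam$", ".bai", path))) {
    Rsamtools::indexBam(path)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- if (is.null(region))
    Rsamtools::ScanBamParam(what = "qname", tag = "XS", flag = flag)
  else
    Rsamtools::ScanBamParam(what = "qname", tag = "XS", flag = flag,
                            which = region)
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(aln) == 0L) {
    return(list(fragments = data.frame(id = integer(0), qname = character(0),
                                       chrom = character(0),
                                       strand = character(0),
                                       spliced = logical(0)),
                blocks = data.frame(id = integer(0), chrom = character(0),
                                    start = integer(0), end = integer(0)),
                junctions = .empty_junctions(),
                deltas = coverage_deltas(data.frame(chrom = character(0),
                                                    start = integer(0),
                                                    end = integer(0))),
                n_templates = 0L))
  }
  chroms <- as.character(GenomicAlignments::seqnames(aln))
  starts1 <- GenomicRanges::start(aln)  # 1-based
  # sortedness check (BAM input only claims it; converted SAM is sorted by us)
  for (chr in unique(chroms)) {
    s <- starts1[chroms == chr]
    if (is.unsorted(s)) {
      i <- which(diff(s) < 0)[1L]
      stop(sprintf(
        "input not coordinate-sorted: records %d and %d on %s (pos %d > %d)",
        i, i + 1L, chr, s[i], s[i + 1L]))
    }
  }
  rng <- GenomicAlignments::extractAlignmentRangesOnReference(
    GenomicAlignments::cigar(aln), pos = starts1, drop.D.ranges = FALSE)
  xs <- S4Vectors::mcols(aln)$XS
  if (is.null(xs)) xs <- rep(NA_character_, length(aln))
  ids <- seq_along(aln)
  n_per <- S4Vectors::elementNROWS(rng)
  bl <- data.frame(id = rep(ids, n_per),
                   chrom = rep(chroms, n_per),
                   start = unlist(IRanges::start(rng)) - 1L,
                   end = unlist(IRanges::end(rng)))
  # merge sub-intron gaps (treated as deletions)
  bl <- .merge_short_gaps(bl, min_intron)
  n_bl <- tabulate(bl$id, nbins = length(aln))
  frags <- data.frame(id = ids,
                      qname = S4Vectors::mcols(aln)$qname,
                      chrom = chroms,
                      strand = ifelse(is.na(xs), "*", xs),
                      spliced = n_bl > 1L,
                      stringsAsFactors = FALSE)
  frags$strand[!frags$spliced] <- "*"
  junctions <- .junctions_from_blocks(bl, frags)
  deltas <- coverage_deltas(bl)
  list(fragments = frags, blocks = bl, junctions = junctions, deltas = deltas,
       n_templates = length(unique(frags$qname)))
}

.empty_junctions <- function() {
  data.frame(chrom = character(0), strand = character(0), donor = integer(0),
             acceptor = integer(0), support = integer(0),
             stringsAsFactors = FALSE)
}

.merge_short_gaps <- function(bl, min_intron) {
  if (!nrow(bl)) return(bl)
  o <- order(bl$id, bl$start)
  bl <- bl[o, , drop = FALSE]
  same <- c(FALSE, diff(bl$id) == 0L)
  gap <- c(Inf, bl$start[-1L] - bl$end[-nrow(bl)])
  new_block <- !(same & gap < min_intron)
  grp <- cumsum(new_block)
  data.frame(id = bl$id[new_block],
             chrom = bl$chrom[new_block],
             start = as.integer(tapply(bl$start, grp, min)),
             end = as.integer(tapply(bl$end, grp, max)),
             row.names = NULL)
}

.junctions_from_blocks <- function(bl, frags) {
  if (!nrow(bl)) return(.empty_junctions())
  o <- order(bl$id, bl$start)
  bl <- bl[o, , drop = FALSE]
  same <- c(diff(bl$id) == 0L, FALSE)
  i <- which(same)
  if (!length(i)) return(.empty_junctions())
  j <- data.frame(chrom = bl$chrom[i],
                  strand = frags$strand[match(bl$id[i], frags$id)],
                  donor = bl$end[i],
                  acceptor = bl$start[i + 1L],
                  stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(support = rep(1L, nrow(j))),
                          j[c("chrom", "strand", "donor", "acceptor")], sum)
  agg[order(agg$chrom, agg$donor, agg$acceptor, agg$strand), , drop = FALSE]
}

#' Partition the genome into independent loci
#'
#' Loci are maximal intervals of non-zero coverage, merged whenever a splice
#' junction bridges a zero-coverage gap between two covered intervals.
#'
#' @param deltas a [coverage_deltas()] store
#' @param junctions junction table as returned by [stream_fragments()]
#' @return data.frame(chrom, start, end), disjoint and sorted
#' @export
partition_loci <- function(deltas, junctions) {
  out <- list()
  for (chr in names(deltas)) {
    iv <- covered_intervals(deltas, chr)
    if (!nrow(iv)) next
    grp <- seq_len(nrow(iv))  # union-find over intervals
    find <- function(x) { while (grp[x] != x) x <- grp[x]; x }
    jc <- junctions[junctions$chrom == chr, , drop = FALSE]
    for (k in seq_len(nrow(jc))) {
      a <- which(iv$start < jc$donor[k] & iv$end >= jc$donor[k])
      b <- which(iv$start <= jc$acceptor[k] & iv$end > jc$acceptor[k])
      if (length(a) == 1L && length(b) == 1L && a != b)
        grp[find(max(a, b))] <- find(min(a, b))
    }
    root <- vapply(seq_len(nrow(iv)), find, integer(1))
    merged <- data.frame(
      chrom = chr,
      start = as.integer(tapply(iv$start, root, min)),
      end = as.integer(tapply(iv$end, root, max)))
    out[[chr]] <- merged[order(merged$start), , drop = FALSE]
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
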