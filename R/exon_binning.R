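#' Cluster splice sites to absorb alignment jitter
#'
#' 1D clustering of junctions: two junctions on the same chromosome and strand
#' are merged when both their donor and acceptor coordinates lie within
#' `bandwidth` bases of a canonical junction.  The canonical member of a
#' cluster is the one with maximal support (ties: leftmost); all member
#' support is reassigned to it.
#'
#' @param junctions junction table (chrom, strand, donor, acceptor, support)
#' @param bandwidth clustering bandwidth in bp
#' @return list with `junctions` (canonical table) and `map` (original
#'   coordinates and their canonical replacements)
#' @export
cluster_splice_sites <- function(junctions, bandwidth = 3L) {
  if (!nrow(junctions))
    return(list(junctions = junctions,
                map = cbind(junctions, c_donor = integer(0),
                            c_acceptor = integer(0))))
  out <- list(); maps <- list()
  for (grp in split(junctions,
                    paste(junctions$chrom, junctions$strand, sep = "\r"))) {
    o <- order(-grp$support, grp$donor, grp$acceptor)
    grp <- grp[o, , drop = FALSE]
    cd <- integer(0); ca <- integer(0); cs <- numeric(0)
    assign_to <- integer(nrow(grp))
    for (i in seq_len(nrow(grp))) {
      hit <- which(abs(cd - grp$donor[i]) <= bandwidth &
                     abs(ca - grp$acceptor[i]) <= bandwidth)
      if (length(hit)) {
        k <- hit[1L]  # canonicals are stored best-support-first
      } else {
        cd <- c(cd, grp$donor[i]); ca <- c(ca, grp$acceptor[i])
        cs <- c(cs, 0); k <- length(cd)
      }
      assign_to[i] <- k
      cs[k] <- cs[k] + grp$support[i]
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = grp$chrom[1L], strand = grp$strand[1L], donor = cd,
      acceptor = ca, support = as.integer(cs), stringsAsFactors = FALSE)
    maps[[length(maps) + 1L]] <- data.frame(
      chrom = grp$chrom, strand = grp$strand, donor = grp$donor,
      acceptor = grp$acceptor, c_donor = cd[assign_to],
      c_acceptor = ca[assign_to], stringsAsFactors = FALSE)
  }
  jn <- do.call(rbind, out)
  jn <- jn[order(jn$chrom, jn$donor, jn$acceptor), , drop = FALSE]
  rownames(jn) <- NULL
  list(junctions = jn, map = do.call(rbind, maps))
}

#' Derive the minimal exon-range partition of a locus
#'
#' Boundaries are the locus's coverage edges (transitions to zero depth) plus
#' every canonical donor/acceptor site; exon ranges are the maximal covered
#' intervals between consecutive boundaries.  This is the smallest ordered set
#' of ranges that can explain all observed splice sites.  Junctions with an
#' endpoint in uncovered sequence are noise and dropped with a warning.
#'
#' @param junctions canonical junction table for this locus (one strand)
#' @param deltas coverage store
#' @param chrom,start,end the locus interval
#' @return list with `ranges` (data.frame: index, start, end, left_kind,
#'   right_kind) and `junctions` (the kept junction table)
#' @export
build_exon_ranges <- function(junctions, deltas, chrom, start, end) {
  iv <- covered_intervals(deltas, chrom)
  iv <- iv[iv$end > start & iv$start < end, , drop = FALSE]
  keep <- rep(TRUE, nrow(junctions))
  for (k in seq_len(nrow(junctions))) {
    d <- junctions$donor[k]; a <- junctions$acceptor[k]
    d_ok <- any(iv$start < d & iv$end >= d)   # base d-1 covered
    a_ok <- any(iv$start <= a & iv$end > a)   # base a covered
    if (!d_ok || !a_ok) {
      warning(sprintf("junction %s:%d-%d outside covered region; dropped",
                      chrom, d, a))
      keep[k] <- FALSE
    }
  }
  junctions <- junctions[keep, , drop = FALSE]
  rs <- integer(0); re <- integer(0); lk <- character(0); rk <- character(0)
  for (i in seq_len(nrow(iv))) {
    cs <- iv$start[i]; ce <- iv$end[i]
    dons <- junctions$donor[junctions$donor > cs & junctions$donor < ce]
    accs <- junctions$acceptor[junctions$acceptor > cs &
                                 junctions$acceptor < ce]
    pts <- sort(unique(c(cs, ce, dons, accs)))
    spl <- pts %in% c(junctions$donor, junctions$acceptor)
    for (p in seq_len(length(pts) - 1L)) {
      rs <- c(rs, pts[p]); re <- c(re, pts[p + 1L])
      lk <- c(lk, if (spl[p]) "splice" else "coverage_edge")
      rk <- c(rk, if (spl[p + 1L]) "splice" else "coverage_edge")
    }
  }
  o <- order(rs)
  list(ranges = data.frame(index = seq_along(rs), start = rs[o], end = re[o],
                           left_kind = lk[o], right_kind = rk[o],
                           stringsAsFactors = FALSE),
       junctions = junctions)
}

# snap a fragment's junction coordinates to their canonical cluster values
.snap_blocks <- function(bl, jmap, strand) {
  n <- nrow(bl)
  if (n < 2L || !nrow(jmap)) return(bl)
  for (i in seq_len(n - 1L)) {
    hit <- which(jmap$donor == bl$end[i] & jmap$acceptor == bl$start[i + 1L] &
                   (jmap$strand == strand | strand == "*"))
    if (length(hit)) {
      bl$end[i] <- jmap$c_donor[hit[1L]]
      bl$start[i + 1L] <- jmap$c_acceptor[hit[1L]]
    }
  }
  bl
}

#' Assign one fragment to its exon bin
#'
#' The bin is the ordered list of exon-range indices overlapping any aligned
#' block.  A fragment whose splice junctions contradict the canonical
#' junction/boundary set is rejected (returns NULL).
#'
#' @param bl data.frame of the fragment's blocks (start, end), snapped
#' @param ranges exon-range table from [build_exon_ranges()]
#' @param junction_keys character keys "donor:acceptor" of canonical junctions
#' @return list(chain, bases) or NULL when rejected; `bases` gives the aligned
#'   bases falling into each chain exon
#' @export
bin_of_fragment <- function(bl, ranges, junction_keys) {
  n <- nrow(bl)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      key <- paste0(bl$end[i], ":", bl$start[i + 1L])
      if (!key %in% junction_keys) return(NULL)
      # junction must coincide with range boundaries
      if (!any(ranges$end == bl$end[i]) || !any(ranges$start == bl$start[i + 1L]))
        return(NULL)
    }
  }
  chain <- integer(0); bases <- numeric(0)
  for (r in seq_len(nrow(ranges))) {
    ov <- pmin(bl$end, ranges$end[r]) - pmax(bl$start, ranges$start[r])
    w <- sum(ov[ov > 0])
    if (w > 0) { chain <- c(chain, ranges$index[r]); bases <- c(bases, w) }
  }
  if (!length(chain)) return(NULL)
  list(chain = chain, bases = bases)
}

#' Merge two mate bin chains or record a paired link
#'
#' Mates are merged into one bin when their chains overlap (the shared region
#' must agree exactly, otherwise both mates are rejected as noise) or when the
#' upstream chain's last exon index immediately precedes the downstream
#' chain's first.  Otherwise the pairing is kept as a `PairedLink` for the
#' phasing step.  The contract is symmetric in mate order.
#'
#' @param c1,c2 integer exon chains of the two mates
#' @return list(kind = "bin"|"link"|"reject", ...)
#' @export
combine_mates <- function(c1, c2) {
  # order mates along the genome
  if (chain_compare(c2, c1) < 0) { tmp <- c1; c1 <- c2; c2 <- tmp }
  i <- c1[length(c1)]; j <- c2[1L]
  if (i >= j) {
    suf <- c1[c1 >= j]; pre <- c2[c2 <= i]
    if (length(suf) != length(pre) || !all(suf == pre))
      return(list(kind = "reject"))
    return(list(kind = "bin", chain = c(c1, c2[c2 > i])))
  }
  if (i + 1L == j) return(list(kind = "bin", chain = c(c1, c2)))
  list(kind = "link", left = c1, right = c2)
}

#' Mean and boundary coverage of an exon range
#'
#' `cov` is total per-base depth divided by length; `boundary_cov` returns the
#' depth at the leftmost and rightmost base and the maximum, read from the
#' coverage prefix sums.
#' @inheritParams region_stats
#' @export
exon_cov <- function(deltas, chrom, start, end) {
  region_stats(deltas, chrom, start, end)$mean
}

#' @rdname exon_cov
#' @export
boundary_cov <- function(deltas, chrom, start, end) {
  s <- region_stats(deltas, chrom, start, end)
  list(left = s$left, right = s$right, max = s$max)
}

#' Bin all fragments of one locus strand
#'
#' Streams the locus's fragments through [bin_of_fragment()], merges mates
#' with [combine_mates()], and accumulates per-bin support counts, per-exon
#' aligned bases, and compressed start/end position counts.
#'
#' @param frag_ids,frag_qnames,frag_strands,frag_spliced parallel fragment
#'   vectors for this locus
#' @param blocks block table (id, start, end) for these fragments
#' @param ranges exon-range table
#' @param junctions canonical junction table for this strand
#' @param jmap junction snap map from [cluster_splice_sites()]
#' @param locus_strand strand being assembled
#' @return list(bins, links, rejected, assigned)
#' @export
build_locus_bins <- function(frag_ids, frag_qnames, frag_strands, frag_spliced,
                             blocks, ranges, junctions, jmap, locus_strand) {
  junction_keys <- if (nrow(junctions))
    paste0(junctions$donor, ":", junctions$acceptor) else character(0)
  usable <- !frag_spliced | frag_strands == locus_strand |
    frag_strands == "*"
  chains <- new.env(parent = emptyenv())   # key -> list(count, bases, ...)
  links <- new.env(parent = emptyenv())
  jx <- new.env(parent = emptyenv())       # "donor:acceptor" -> crossing reads
  rejected <- 0L; assigned <- 0L
  n_ranges <- max(ranges$index)
  add_bin <- function(chain, bases, start_pos, end_pos) {
    key <- chain_key(chain)
    cur <- chains[[key]]
    if (is.null(cur))
      cur <- list(chain = chain, count = 0, bases = numeric(n_ranges),
                  left_starts = integer(0), right_ends = integer(0))
    cur$count <- cur$count + 1
    cur$bases <- cur$bases + bases
    cur$left_starts <- c(cur$left_starts, start_pos)
    cur$right_ends <- c(cur$right_ends, end_pos)
    chains[[key]] <- cur
  }
  by_q <- split(seq_along(frag_ids)[usable], frag_qnames[usable])
  for (q in names(by_q)) {
    idx <- by_q[[q]]
    parts <- list()
    ok <- TRUE
    for (fi in idx) {
      bl <- blocks[blocks$id == frag_ids[fi], c("start", "end"), drop = FALSE]
      bl <- bl[order(bl$start), , drop = FALSE]
      bl <- .snap_blocks(bl, jmap, frag_strands[fi])
      b <- bin_of_fragment(bl, ranges, junction_keys)
      if (is.null(b)) { ok <- FALSE; break }
      b$start_pos <- bl$start[1L]; b$end_pos <- bl$end[nrow(bl)]
      b$gaps <- if (nrow(bl) > 1L)
        paste0(bl$end[-nrow(bl)], ":", bl$start[-1L]) else character(0)
      parts[[length(parts) + 1L]] <- b
    }
    if (!ok) { rejected <- rejected + length(idx); next }
    # sequenced junction crossings, counted at the mate level: a merged
    # pair whose unsequenced insert gap spans a junction must not count
    for (p in parts) for (gk in p$gaps)
      jx[[gk]] <- (jx[[gk]] %||% 0) + 1
    if (length(parts) == 1L) {
      add_bin(parts[[1L]]$chain, .bases_on(parts[[1L]], ranges),
              parts[[1L]]$start_pos, parts[[1L]]$end_pos)
      assigned <- assigned + 1L
    } else if (length(parts) == 2L) {
      cm <- combine_mates(parts[[1L]]$chain, parts[[2L]]$chain)
      if (cm$kind == "reject") { rejected <- rejected + 2L; next }
      bases <- .bases_on(parts[[1L]], ranges) + .bases_on(parts[[2L]], ranges)
      if (cm$kind == "bin") {
        add_bin(cm$chain, bases,
                min(parts[[1L]]$start_pos, parts[[2L]]$start_pos),
                max(parts[[1L]]$end_pos, parts[[2L]]$end_pos))
      } else {
        lkey <- paste(chain_key(cm$left), chain_key(cm$right), sep = "|")
        cur <- links[[lkey]]
        if (is.null(cur)) cur <- list(left = cm$left, right = cm$right, count = 0)
        cur$count <- cur$count + 1
        links[[lkey]] <- cur
        # bases of unmerged mates still inform the bins they'd map to
        # (combine_mates may have reordered the mates along the genome)
        pl <- if (identical(parts[[1L]]$chain, cm$left)) parts[[1L]]
              else parts[[2L]]
        pr <- if (identical(parts[[1L]]$chain, cm$left)) parts[[2L]]
              else parts[[1L]]
        add_bin(cm$left, .bases_on(pl, ranges), pl$start_pos, pl$end_pos)
        add_bin(cm$right, .bases_on(pr, ranges), pr$start_pos, pr$end_pos)
      }
      assigned <- assigned + 2L
    }
  }
  bin_list <- lapply(sort(names(chains)), function(k) {
    b <- chains[[k]]
    b$left_starts <- table(b$left_starts)
    b$right_ends <- table(b$right_ends)
    b
  })
  link_list <- lapply(sort(names(links)), function(k) links[[k]])
  jx_list <- as.list(jx)
  list(bins = bin_list, links = link_list, rejected = rejected,
       assigned = assigned, junction_reads = jx_list)
}

# scatter a fragment's per-chain-exon bases onto the full range index space
.bases_on <- function(part, ranges) {
  v <- numeric(max(ranges$index))
  v[part$chain] <- part$bases
  v
}
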