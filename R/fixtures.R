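#' Synthetic loci: transcript structures and paired-end read simulation
#'
#' The generator builds loci as exon layouts plus isoform chains, samples
#' paired-end fragments uniformly along each isoform (optionally with a 5'-3'
#' coverage trend, junction jitter, and fragment dropout), and emits a
#' coordinate-sorted SAM plus a truth GTF.  Alignments are generated directly
#' (no base-level sequence simulation; SEQ is an N-run), since the assembler
#' consumes alignments, not bases.
#'
#' @param chrom chromosome name
#' @param exon_starts,exon_lengths integer vectors (0-based starts), genomic
#'   order, non-overlapping, separated by introns
#' @param isoforms list of strictly increasing integer vectors (exon indices)
#' @param abundances numeric target per-base read depth per isoform
#' @param strand "+" or "-"
#' @param read_length,frag_mean,frag_sd read and fragment-length model (bp)
#' @return object of class `sim_locus`
#' @export
make_locus <- function(chrom, exon_starts, exon_lengths, isoforms, abundances,
                       strand = "+", read_length = 100, frag_mean = 280,
                       frag_sd = 25) {
  stopifnot(length(exon_starts) == length(exon_lengths),
            all(exon_lengths > 0),
            length(isoforms) == length(abundances),
            all(abundances > 0))
  ends <- exon_starts + exon_lengths
  if (is.unsorted(exon_starts, strictly = TRUE) ||
      any(utils::head(ends, -1L) > utils::tail(exon_starts, -1L)))
    stop("exons must be sorted and non-overlapping")
  for (ch in isoforms) {
    if (!is_strictly_increasing(ch)) stop("isoform chains must be increasing")
    tlen <- sum(exon_lengths[ch])
    if (tlen < 2L * read_length)
      stop("isoform shorter than a paired fragment; rejected locus spec")
  }
  structure(list(chrom = chrom, strand = strand,
                 exon_starts = as.integer(exon_starts),
                 exon_ends = as.integer(ends),
                 isoforms = lapply(isoforms, as.integer),
                 abundances = abundances,
                 read_length = as.integer(read_length),
                 frag_mean = frag_mean, frag_sd = frag_sd),
            class = "sim_locus")
}

#' Worked-example locus with an ambiguous exon between three isoforms
#'
#' Eight exons A..H.  Isoform 1 = (A,C,D,E,F,G), isoform 2 = (B,D,E,F,G),
#' isoform 3 = (A,C,D,H).  E and F are shorter than a read and
#' |E|+|F| < read length, so multi-splice bins such as (D,E,F,G) arise and pin
#' the shared suffix into a single edge; D is longer than a read and sits at
#' the crossing point of all three isoforms, so it is the locus's only
#' ambiguous exon and must become a graph node, resolved by mate pairs.
#' @param abundances per-isoform depths (default distinct)
#' @export
fig_locus <- function(abundances = c(12, 8, 20)) {
  lens <- c(A = 150L, B = 120L, C = 60L, D = 150L,
            E = 40L, F = 50L, G = 200L, H = 180L)
  gaps <- c(90L, 80L, 70L, 100L, 60L, 90L, 120L)  # introns between neighbours
  starts <- integer(8)
  starts[1] <- 1000L
  for (i in 2:8) starts[i] <- starts[i - 1L] + lens[i - 1L] + gaps[i - 1L]
  make_locus("chrF", starts, lens,
             isoforms = list(c(1L, 3L, 4L, 5L, 6L, 7L),
                             c(2L, 4L, 5L, 6L, 7L),
                             c(1L, 3L, 4L, 8L)),
             abundances = abundances)
}

# Identifiability screen: every maximal contiguous run of exons shared by two
# isoforms that diverge on both sides must be bridgeable by a fragment, i.e.
# its genomic transcript length must not exceed the mean outer fragment span.
.locus_identifiable <- function(lens, isoforms, frag_mean, read_length = 100) {
  k <- length(isoforms)
  if (k < 2L) return(TRUE)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    a <- isoforms[[i]]; b <- isoforms[[j]]
    common <- intersect(a, b)
    if (!length(common)) next
    # runs contiguous in both chains
    pa <- match(common, a); pb <- match(common, b)
    o <- order(common)
    common <- common[o]; pa <- pa[o]; pb <- pb[o]
    run_break <- c(TRUE, diff(pa) != 1L | diff(pb) != 1L)
    run_id <- cumsum(run_break)
    for (r in unique(run_id)) {
      run <- common[run_id == r]
      first <- run[1L]; last <- run[length(run)]
      div_before <- match(first, a) > 1L && match(first, b) > 1L &&
        a[match(first, a) - 1L] != b[match(first, b) - 1L]
      div_after <- match(last, a) < length(a) && match(last, b) < length(b) &&
        a[match(last, a) + 1L] != b[match(last, b) + 1L]
      if (div_before && div_after && sum(lens[run]) > frag_mean - 2)
        return(FALSE)
    }
  }
  TRUE
}

#' Random identifiable locus
#'
#' Exon layouts and isoform chains are drawn so that the truth is recoverable
#' from noiseless reads: all isoforms span the locus end to end (no internal
#' start/end sites), splice chains are pairwise distinct, and shared interior
#' stretches between divergence points are short enough for mate pairs to
#' bridge.  Uses the current RNG stream; seed at the caller.
#'
#' @param chrom,offset placement of the locus
#' @param n_isoforms number of isoforms (1-8)
#' @param depth target per-base depth shared by all isoforms
#' @param distinct_abundances if TRUE, geometrically spaced depths instead of
#'   equal ones
#' @export
random_locus <- function(chrom = "chrS", offset = 1000L, n_isoforms = 2L,
                         depth = 20, distinct_abundances = FALSE,
                         read_length = 100, frag_mean = 280, frag_sd = 25) {
  n_isoforms <- as.integer(n_isoforms)
  for (attempt in seq_len(200L)) {
    n_min <- if (n_isoforms > 1L) ceiling(log2(n_isoforms)) + 2L else 1L
    n_exons <- max(sample(2:8, 1L), n_min, if (n_isoforms > 2L) 4L else 2L)
    if (n_isoforms == 1L && stats::runif(1) < 0.15) n_exons <- 1L
    lens <- as.integer(sample(50:200, n_exons, replace = TRUE))
    lens[1L] <- max(lens[1L], 170L)
    lens[n_exons] <- max(lens[n_exons], 170L)
    if (n_exons == 1L) lens <- max(lens, 2L * read_length + 40L)
    gaps <- as.integer(sample(80:300, max(n_exons - 1L, 0L), replace = TRUE))
    starts <- offset + c(0L, cumsum(lens[-n_exons] + gaps))
    if (n_exons == 1L) starts <- offset
    if (n_isoforms == 1L) {
      isoforms <- list(seq_len(n_exons))
      if (sum(lens) < 2L * read_length + 20L) next
    } else {
      interior <- if (n_exons > 2L) 2:(n_exons - 1L) else integer(0)
      seen <- character(0); isoforms <- list()
      guard <- 0L
      while (length(isoforms) < n_isoforms && guard < 500L) {
        guard <- guard + 1L
        keep <- interior[stats::runif(length(interior)) < 0.6]
        ch <- c(1L, keep, n_exons)
        key <- chain_key(ch)
        if (!key %in% seen && sum(lens[ch]) >= 2L * read_length + 20L) {
          seen <- c(seen, key); isoforms <- c(isoforms, list(ch))
        }
      }
      if (length(isoforms) < n_isoforms) next
    }
    if (!all(seq_len(n_exons) %in% unlist(isoforms))) next
    if (!.locus_identifiable(lens, isoforms, frag_mean, read_length)) next
    ab <- if (distinct_abundances)
      depth * 1.7^(seq_len(n_isoforms) - 1L)[sample(n_isoforms)]
    else rep(depth, n_isoforms)
    loc <- try(make_locus(chrom, starts, lens, isoforms, ab,
                          read_length = read_length, frag_mean = frag_mean,
                          frag_sd = frag_sd), silent = TRUE)
    if (!inherits(loc, "try-error")) return(loc)
  }
  stop("could not generate an identifiable locus")
}

# transcript-coordinate interval [s, e) -> genomic blocks along a chain
.tx_to_blocks <- function(locus, chain, s, e) {
  lens <- locus$exon_ends[chain] - locus$exon_starts[chain]
  offs <- c(0L, cumsum(lens))
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(chain)) {
    lo <- max(s, offs[i]); hi <- min(e, offs[i + 1L])
    if (hi > lo) {
      g0 <- locus$exon_starts[chain[i]] + (lo - offs[i])
      out_s <- c(out_s, g0); out_e <- c(out_e, g0 + (hi - lo))
    }
  }
  # merge blocks contiguous on the genome (can only happen with zero gaps)
  if (length(out_s) > 1L) {
    keep <- c(TRUE, out_s[-1L] != out_e[-length(out_e)])
    grp <- cumsum(keep)
    out_s <- tapply(out_s, grp, min); out_e <- tapply(out_e, grp, max)
  }
  cbind(start = as.integer(out_s), end = as.integer(out_e))
}

.blocks_to_cigar <- function(bl) {
  n <- nrow(bl)
  parts <- character(0)
  for (i in seq_len(n)) {
    parts <- c(parts, paste0(bl[i, "end"] - bl[i, "start"], "M"))
    if (i < n) parts <- c(parts, paste0(bl[i + 1L, "start"] - bl[i, "end"], "N"))
  }
  paste(parts, collapse = "")
}

#' Sample paired-end fragments from a locus
#'
#' Fragment counts per isoform are `abundance * transcript_length / (2 *
#' read_length)` so that realized depth matches the requested abundance.
#' Fragment starts are uniform along the transcript unless `trend` is set, in
#' which case sampling density changes by `2^trend` from 5' to 3'.
#'
#' @param locus a `sim_locus`
#' @param seed optional integer; if given, sampling is reproducible
#' @param trend log2 fold-change of sampling density along the transcript
#' @param jitter_rate,jitter_bp fraction of spliced reads whose junction is
#'   shifted by up to `jitter_bp` bases (alignment-noise emulation)
#' @param drop_rate fraction of fragments discarded
#' @param qname_prefix prefix for read names
#' @return data.frame of SAM-ready records (one row per mate)
#' @export
sample_reads <- function(locus, seed = NULL, trend = 0, jitter_rate = 0,
                         jitter_bp = 0, drop_rate = 0, qname_prefix = "frag") {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  r <- locus$read_length
  rec <- list(); ri <- 0L
  minov <- 30L  # minimum aligned bases for a clipped mate to be emitted
  for (k in seq_along(locus$isoforms)) {
    chain <- locus$isoforms[[k]]
    tlen <- sum(locus$exon_ends[chain] - locus$exon_starts[chain])
    # fragment starts are drawn over an extended window so that coverage is
    # uniform across the whole transcript (the noiseless study condition:
    # equal coverage everywhere); mates overhanging the transcript ends are
    # clipped, emulating reads from the flanks of the captured segment
    width <- tlen + locus$frag_mean - 2L * minov
    nfrag <- max(1L, round(locus$abundances[k] * width / (2 * r)))
    flen <- pmax(r, round(stats::rnorm(nfrag, locus$frag_mean,
                                       locus$frag_sd)))
    lo <- -flen + minov
    hi <- tlen - minov
    u <- stats::runif(nfrag)
    fs <- integer(nfrag)
    for (i in seq_len(nfrag)) {
      w <- hi - lo[i]
      if (trend == 0) {
        fs[i] <- lo[i] + floor(u[i] * (w + 1L))
      } else {
        # inverse-CDF sample of density 2^(trend * x / w)
        a <- trend * log(2) / w
        fs[i] <- lo[i] + floor(log(1 + u[i] * (exp(a * w) - 1)) / a)
      }
    }
    keep <- if (drop_rate > 0) stats::runif(nfrag) >= drop_rate
            else rep(TRUE, nfrag)
    for (i in which(keep)) {
      s1 <- max(0L, fs[i]); e1 <- min(tlen, fs[i] + r)
      s2 <- max(0L, fs[i] + flen[i] - r); e2 <- min(tlen, fs[i] + flen[i])
      has1 <- e1 - s1 >= minov; has2 <- e2 - s2 >= minov
      if (!has1 && !has2) next
      m1 <- if (has1) .tx_to_blocks(locus, chain, s1, e1) else NULL
      m2 <- if (has2) .tx_to_blocks(locus, chain, s2, e2) else NULL
      if (jitter_rate > 0 && jitter_bp > 0) {
        if (has1) m1 <- .jitter_blocks(m1, jitter_rate, jitter_bp)
        if (has2) m2 <- .jitter_blocks(m2, jitter_rate, jitter_bp)
      }
      ri <- ri + 1L
      qn <- sprintf("%s_%s_%d", qname_prefix, k, ri)
      if (has1 && has2) {
        rec[[length(rec) + 1L]] <- data.frame(
          qname = qn, chrom = locus$chrom,
          pos = c(m1[1L, "start"], m2[1L, "start"]),
          cigar = c(.blocks_to_cigar(m1), .blocks_to_cigar(m2)),
          flag = c(99L, 147L),
          mpos = c(m2[1L, "start"], m1[1L, "start"]),
          tlen = c(m2[nrow(m2), "end"] - m1[1L, "start"],
                   -(m2[nrow(m2), "end"] - m1[1L, "start"])),
          seqlen = c(sum(m1[, "end"] - m1[, "start"]),
                     sum(m2[, "end"] - m2[, "start"])),
          xs = ifelse(c(nrow(m1) > 1L, nrow(m2) > 1L), locus$strand,
                      NA_character_),
          stringsAsFactors = FALSE)
      } else {
        m <- if (has1) m1 else m2
        rec[[length(rec) + 1L]] <- data.frame(
          qname = qn, chrom = locus$chrom, pos = m[1L, "start"],
          cigar = .blocks_to_cigar(m),
          flag = if (has1) 0L else 16L,
          mpos = m[1L, "start"], tlen = 0L,
          seqlen = sum(m[, "end"] - m[, "start"]),
          xs = if (nrow(m) > 1L) locus$strand else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rec))
    return(data.frame(qname = character(0), chrom = character(0),
                      pos = integer(0), cigar = character(0), flag = integer(0),
                      mpos = integer(0), tlen = integer(0), seqlen = integer(0),
                      xs = character(0)))
  do.call(rbind, rec)
}

.jitter_blocks <- function(bl, rate, bp) {
  if (nrow(bl) < 2L || stats::runif(1) >= rate) return(bl)
  j <- sample(nrow(bl) - 1L, 1L)
  shift <- sample(c(-bp:-1, 1:bp), 1L)
  # shift the intron: donor (end of block j) and acceptor (start of j+1)
  if (bl[j, "end"] - bl[j, "start"] > abs(shift) &&
      bl[j + 1L, "end"] - bl[j + 1L, "start"] > abs(shift)) {
    bl[j, "end"] <- bl[j, "end"] + shift
    bl[j + 1L, "start"] <- bl[j + 1L, "start"] + shift
  }
  bl
}

#' Write simulated records as a coordinate-sorted SAM file
#' @param records data.frame from [sample_reads()] (rows from several loci may
#'   be concatenated)
#' @param seqlengths named integer vector of chromosome lengths; inferred with
#'   a margin when NULL
#' @param path output path
#' @export
emit_sam <- function(records, path, seqlengths = NULL) {
  if (is.null(seqlengths)) {
    if (nrow(records)) {
      ends <- records$pos + vapply(records$cigar, function(cg) {
        sum(.cigar_ref_lengths(cg))
      }, numeric(1))
      seqlengths <- tapply(ends, records$chrom, function(x) max(x) + 1000L)
    } else seqlengths <- c(chrU = 10000L)
  }
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  lines <- character(0)
  if (nrow(records)) {
    o <- order(match(records$chrom, names(seqlengths)), records$pos,
               records$qname, records$flag)
    records <- records[o, , drop = FALSE]
    opt <- ifelse(is.na(records$xs), "", sprintf("\tXS:A:%s", records$xs))
    lines <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*%s",
                     records$qname, records$flag, records$chrom,
                     records$pos + 1L, records$cigar, records$mpos + 1L,
                     records$tlen, strrep("N", records$seqlen), opt)
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

.cigar_ref_lengths <- function(cigar) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  n[op %in% c("M", "D", "N", "=", "X")]
}

#' Write the truth annotation of one or more loci as GTF
#' @param loci list of `sim_locus` objects (or a single one)
#' @param path output path
#' @export
emit_truth_gtf <- function(loci, path) {
  if (inherits(loci, "sim_locus")) loci <- list(loci)
  txs <- list()
  for (li in seq_along(loci)) {
    loc <- loci[[li]]
    for (k in seq_along(loc$isoforms)) {
      ch <- loc$isoforms[[k]]
      txs[[length(txs) + 1L]] <- list(
        chrom = loc$chrom, strand = loc$strand,
        exons = data.frame(start = loc$exon_starts[ch],
                           end = loc$exon_ends[ch]),
        abundance = loc$abundances[k], fpkm = NA_real_,
        gene_id = sprintf("truth_gene_%d", li),
        transcript_id = sprintf("truth_%d_%d", li, k),
        guided = FALSE)
    }
  }
  write_gtf(txs, path)
}

#' A multi-locus synthetic dataset
#'
#' Places `n_loci` random identifiable loci along one synthetic chromosome with
#' wide intergenic gaps, samples reads for each, and returns loci plus the
#' combined record table.
#'
#' @param n_loci number of loci
#' @param seed RNG seed controlling both structure and read sampling
#' @param isoform_range range to draw per-locus isoform counts from
#' @inheritParams random_locus
#' @inheritParams sample_reads
#' @export
synthetic_genome <- function(n_loci = 10L, seed = 1L, isoform_range = 1:4,
                             depth = 20, distinct_abundances = FALSE,
                             trend = 0, jitter_rate = 0, jitter_bp = 0,
                             drop_rate = 0) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  offset <- 1000L
  loci <- list(); recs <- list()
  for (i in seq_len(n_loci)) {
    k <- sample(isoform_range, 1L)
    loc <- random_locus(chrom = "chrS", offset = offset, n_isoforms = k,
                        depth = depth,
                        distinct_abundances = distinct_abundances)
    loci[[i]] <- loc
    recs[[i]] <- sample_reads(loc, trend = trend, jitter_rate = jitter_rate,
                              jitter_bp = jitter_bp, drop_rate = drop_rate,
                              qname_prefix = sprintf("L%d", i))
    offset <- max(loc$exon_ends) + 3000L
  }
  list(loci = loci, records = do.call(rbind, recs),
       seqlengths = c(chrS = offset + 1000L))
}
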