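#' Sparse per-base coverage as signed gain/loss events
#'
#' Read alignments are stored as combined coverage gains (+1 at each aligned
#' block start) and losses (-1 at each block end) per base and chromosome.
#' Prefix sums of the deltas give the exact read depth at any base, so the
#' structure supports mean/boundary/max depth queries over arbitrary intervals
#' while staying sparse.
#'
#' @param blocks data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open aligned blocks, one row per block).
#' @return object of class `coverage_deltas`: per chromosome a list with
#'   sorted unique `pos` and aggregated `delta`, with
#'   `sum(delta) == 0` and all prefix sums non-negative.
#' @export
coverage_deltas <- function(blocks) {
  out <- list()
  if (nrow(blocks)) {
    for (chr in unique(blocks$chrom)) {
      b <- blocks[blocks$chrom == chr, , drop = FALSE]
      ev <- c(b$start, b$end)
      dl <- c(rep(1, nrow(b)), rep(-1, nrow(b)))
      agg <- rowsum(dl, ev)
      pos <- as.integer(rownames(agg))
      o <- order(pos)
      keep <- agg[o, 1L] != 0
      out[[chr]] <- list(pos = pos[o][keep], delta = agg[o, 1L][keep])
    }
  }
  structure(out, class = "coverage_deltas")
}

# step function of depth for one chromosome: depth on [pos[i], pos[i+1]) is
# cum[i]; depth is 0 before pos[1]
.depth_steps <- function(d) {
  if (is.null(d) || length(d$pos) == 0L)
    return(list(pos = integer(0), cum = numeric(0)))
  list(pos = d$pos, cum = cumsum(d$delta))
}

#' Read depth at a single base
#' @param deltas a `coverage_deltas` object
#' @param chrom chromosome name
#' @param at 0-based base position
#' @export
depth_at <- function(deltas, chrom, at) {
  st <- .depth_steps(deltas[[chrom]])
  i <- findInterval(at, st$pos)
  ifelse(i == 0L, 0, st$cum[pmax(i, 1L)])
}

#' Maximal intervals of non-zero coverage on one chromosome
#' @return data.frame(start, end), 0-based half-open, sorted and disjoint
#' @export
covered_intervals <- function(deltas, chrom) {
  st <- .depth_steps(deltas[[chrom]])
  if (length(st$pos) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  covered <- st$cum > 1e-9
  runs <- rle(covered)
  idx <- cumsum(runs$lengths)
  starts <- integer(0); ends <- integer(0)
  from <- c(1L, head(idx, -1L) + 1L)
  for (k in seq_along(runs$values)) {
    if (runs$values[k]) {
      starts <- c(starts, st$pos[from[k]])
      ends <- c(ends, st$pos[idx[k] + 1L])  # first position where depth drops
    }
  }
  data.frame(start = starts, end = ends)
}

# depth run-lengths restricted to [start, end): data.frame(start, end, depth)
region_depth_runs <- function(deltas, chrom, start, end) {
  stopifnot(end > start)
  st <- .depth_steps(deltas[[chrom]])
  if (length(st$pos) == 0L)
    return(data.frame(start = start, end = end, depth = 0))
  brk <- c(start, st$pos[st$pos > start & st$pos < end], end)
  i <- findInterval(brk[-length(brk)], st$pos)
  dep <- ifelse(i == 0L, 0, st$cum[pmax(i, 1L)])
  data.frame(start = brk[-length(brk)], end = brk[-1L], depth = dep)
}

# windowed depth statistics: mean over the first and last `w` bases and the
# maximum of a `w`-wide moving average.  The plain per-base maximum is biased
# upward by counting noise at any realistic depth, which would leak into the
# coverage overheads as phantom corrections.
region_stats_smoothed <- function(deltas, chrom, start, end, w = 25L) {
  len <- end - start
  w <- min(w, len)
  r <- region_depth_runs(deltas, chrom, start, end)
  wd <- r$end - r$start
  left <- {
    take <- pmax(0, pmin(r$end, start + w) - r$start)
    sum(r$depth * take) / w
  }
  right <- {
    take <- pmax(0, r$end - pmax(r$start, end - w))
    sum(r$depth * take) / w
  }
  # moving-average maximum: the integral of depth is piecewise linear, so the
  # windowed mean attains its maximum at a run boundary
  brk <- unique(c(r$start, r$end))
  brk <- brk[brk <= end - w]
  integ <- function(x) {
    take <- pmax(0, pmin(r$end, x) - r$start)
    sum(r$depth * take)
  }
  mx <- if (!length(brk)) sum(r$depth * wd) / len else
    max(vapply(brk, function(x) (integ(x + w) - integ(x)) / w, numeric(1)))
  list(left = left, right = right, max = mx)
}

#' Depth statistics over a genomic interval
#'
#' Mean, boundary (first and last base), maximum and median per-base depth over
#' a 0-based half-open interval, from the sparse delta store.
#' @inheritParams depth_at
#' @param start,end interval bounds, `end > start`
#' @export
region_stats <- function(deltas, chrom, start, end) {
  if (end <= start) stop("zero-length coverage query")
  r <- region_depth_runs(deltas, chrom, start, end)
  w <- r$end - r$start
  med <- {
    o <- order(r$depth)
    cw <- cumsum(w[o])
    r$depth[o][which(cw >= sum(w) / 2)[1L]]
  }
  list(mean = sum(r$depth * w) / sum(w),
       left = r$depth[1L],
       right = r$depth[nrow(r)],
       max = max(r$depth),
       median = med)
}
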