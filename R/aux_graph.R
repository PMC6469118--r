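#' Build the auxiliary overlap/containment graph over bins
#'
#' Nodes are the deduplicated read bins.  A directed `overlap` edge v -> w is
#' added when a proper suffix of v's exon chain equals a proper prefix of w's
#' (the longest such overlap is recorded); a `contained` edge v -> w when v's
#' chain is a contiguous infix of w's.  Containment is taken as contiguous
#' infix because bins encode co-linear splice chains: a non-contiguous subset
#' would assert a contradictory splice structure.
#'
#' @param bins list of bins (each: chain, count, bases, ...) sorted by genomic
#'   position of the first exon
#' @return object of class `aux_graph`: list(bins, overlap, contained) with
#'   edge data.frames (from, to, olap)
#' @export
build_aux_edges <- function(bins) {
  n <- length(bins)
  of <- integer(0); ot <- integer(0); ol <- integer(0)
  cf <- integer(0); ct <- integer(0)
  if (n > 1L) {
    firsts <- vapply(bins, function(b) b$chain[1L], integer(1))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      a <- bins[[i]]$chain; b <- bins[[j]]$chain
      k <- chain_overlap_len(a, b)
      if (k > 0L) { of <- c(of, i); ot <- c(ot, j); ol <- c(ol, k) }
      if (length(a) < length(b) && chain_is_infix(a, b)) {
        cf <- c(cf, i); ct <- c(ct, j)
      }
    }
  }
  structure(list(bins = bins,
                 overlap = data.frame(from = of, to = ot, olap = ol),
                 contained = data.frame(from = cf, to = ct)),
            class = "aux_graph")
}

# DAG transitive reduction of an edge list over n nodes: drop (a, c) whenever
# c stays reachable from a through a path of length >= 2
.transitive_reduce <- function(edges, n) {
  if (!nrow(edges)) return(edges)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges)))
    adj[[edges$from[k]]] <- c(adj[[edges$from[k]]], edges$to[k])
  redundant <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; c_ <- edges$to[k]
    # BFS from a's other successors
    seen <- logical(n)
    queue <- setdiff(adj[[a]], c_)
    while (length(queue)) {
      x <- queue[[1L]]; queue <- queue[-1L]
      if (seen[x]) next
      seen[x] <- TRUE
      if (x == c_) break
      queue <- c(queue, adj[[x]])
    }
    if (seen[c_]) redundant[k] <- TRUE
  }
  edges[!redundant, , drop = FALSE]
}

#' Strip forbidden edges and transitively reduce the auxiliary graph
#'
#' Contained bins are not allowed to own overlap edges: all overlap edges
#' incident to a contained node are removed.  Transitive overlap and
#' transitive containment edges are then removed (string-graph style
#' reduction; implemented as exact DAG transitive reduction).
#'
#' @param g an `aux_graph`
#' @export
strip_and_reduce <- function(g) {
  n <- length(g$bins)
  contained_nodes <- unique(g$contained$from)
  ov <- g$overlap
  keep <- !(ov$from %in% contained_nodes | ov$to %in% contained_nodes)
  ov <- ov[keep, , drop = FALSE]
  g$overlap <- .transitive_reduce(ov, n)
  g$contained <- .transitive_reduce(g$contained, n)
  g
}

#' Merge uniquely chained bins and absorb single-container bins
#'
#' Pairs of non-contained bins connected by an overlap edge that is the
#' source's only out-overlap and the target's only in-overlap are merged into
#' a single longer bin (chains concatenated through the overlap, counts and
#' bases combined).  After merging, every remaining overlap edge marks genuine
#' ambiguity.  Contained bins are then classified against the merged maximal
#' bins: a bin contained in exactly one maximal bin is absorbed into it
#' (count and bases added); a bin contained in two or more stays as a
#' `multi_contained` bin driving path joining during graph construction.
#'
#' @param g a stripped and reduced `aux_graph`
#' @return list(maximal, overlap, multi_contained, containers) where
#'   `maximal` is the list of merged bins, `overlap` their remaining overlap
#'   edges (indices into `maximal`), `multi_contained` the retained contained
#'   bins and `containers` the per-bin list of containing maximal bins
#' @export
merge_unique_chains <- function(g) {
  contained_nodes <- unique(g$contained$from)
  live <- setdiff(seq_along(g$bins), contained_nodes)
  bins <- g$bins
  ov <- g$overlap
  alias <- seq_along(bins)          # node -> surviving merged node
  repeat {
    # drop parallel duplicates created by earlier merges (keep longest overlap)
    if (nrow(ov) > 1L) {
      o <- order(ov$from, ov$to, -ov$olap)
      ov <- ov[o, , drop = FALSE]
      dup <- duplicated(ov[c("from", "to")])
      ov <- ov[!dup, , drop = FALSE]
    }
    cand <- which(vapply(seq_len(nrow(ov)), function(k) {
      v <- ov$from[k]; w <- ov$to[k]
      sum(ov$from == v) == 1L && sum(ov$to == w) == 1L
    }, logical(1)))
    if (!length(cand)) break
    k <- cand[1L]
    v <- ov$from[k]; w <- ov$to[k]; olap <- ov$olap[k]
    bv <- bins[[v]]; bw <- bins[[w]]
    merged <- bv
    merged$chain <- c(bv$chain, bw$chain[-seq_len(olap)])
    merged$count <- bv$count + bw$count
    merged$bases <- bv$bases + bw$bases
    bins[[v]] <- merged
    alias[w] <- v
    ov <- ov[-k, , drop = FALSE]
    ov$from[ov$from == w] <- v
    ov$to[ov$to == w] <- v
    live <- setdiff(live, w)
  }
  maximal_idx <- live
  maximal <- bins[maximal_idx]
  # remap overlap edges to positions in `maximal`
  pos <- match(seq_along(bins), maximal_idx)
  ov2 <- data.frame(from = pos[ov$from], to = pos[ov$to], olap = ov$olap)
  # classify contained bins against merged maximal chains; bins inside two or
  # more maximal bins stay pending -- whether they force a path join or fall
  # into an already-shared region is decided during graph construction
  multi <- list(); containers <- list()
  for (ci in contained_nodes) {
    ch <- g$bins[[ci]]$chain
    inside <- which(vapply(maximal, function(m)
      chain_is_infix(ch, m$chain), logical(1)))
    if (length(inside) == 1L) {
      m <- maximal[[inside]]
      m$count <- m$count + g$bins[[ci]]$count
      m$bases <- m$bases + g$bins[[ci]]$bases
      maximal[[inside]] <- m
    } else if (length(inside) >= 2L) {
      multi[[length(multi) + 1L]] <- g$bins[[ci]]
      containers[[length(containers) + 1L]] <- inside
    }
    # length 0 cannot occur: every contained bin sits inside some maximal one
  }
  # longer pending bins first: a bin nested in another pending bin's span must
  # be classified after its host has (possibly) joined the containers
  if (length(multi)) {
    o <- order(-vapply(multi, function(b) length(b$chain), integer(1)),
               vapply(multi, function(b) b$chain[1L], integer(1)))
    multi <- multi[o]; containers <- containers[o]
  }
  list(maximal = maximal, overlap = ov2, multi_contained = multi,
       containers = containers)
}

#' Export an auxiliary graph as DOT for debugging
#' @param g an `aux_graph`
#' @param path output file
#' @export
aux_graph_dot <- function(g, path) {
  lab <- vapply(g$bins, function(b) chain_key(b$chain), character(1))
  lines <- c("digraph aux {",
             sprintf("  n%d [label=\"%s\"];", seq_along(lab), lab),
             sprintf("  n%d -> n%d [label=\"o%d\"];",
                     g$overlap$from, g$overlap$to, g$overlap$olap),
             sprintf("  n%d -> n%d [style=dashed];",
                     g$contained$from, g$contained$to),
             "}")
  writeLines(lines, path)
  invisible(path)
}
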