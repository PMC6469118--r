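#' @name bin_graph
#' @title Generalized exon-bin splice graph
#'
#' @description
#' The bin graph is a DAG whose nodes are a minimal subset of exon ranges
#' (labels injective) plus source `s` and sink `t`, and whose edges carry
#' maximal ordered exon chains.  It satisfies four conditions: (i) every s-t
#' path spells a well-formed, unique transcript; (ii) every retained bin maps
#' to a unique path whose terminal node labels are the bin's first and last
#' exons; (iii) the number of nodes is minimal among graphs with (i)+(ii);
#' (iv) edge chains are maximal.  Nodes therefore appear exactly where bins
#' genuinely conflict; everything unambiguous stays inside long edges.
#'
#' Internally the graph is a mutable environment.  Bins hold their current
#' path as a vector of shared edge ids, so splitting an edge updates every
#' owning bin at once (the shared-interval-marker idea).
NULL

.bg_new <- function() {
  bg <- new.env(parent = emptyenv())
  bg$edges <- list()        # name -> list(from, to, chain, owners)
  bg$paths <- list()        # bin id (character) -> vector of edge names
  bg$nodes <- integer(0)    # exon labels present as nodes
  bg$next_id <- 1L
  bg$dropped <- 0L
  bg
}

.bg_add_node <- function(bg, label) {
  if (!label %in% bg$nodes) bg$nodes <- c(bg$nodes, label)
}

.bg_add_edge <- function(bg, from, to, chain, owners) {
  # reuse an identical parallel edge (keeps path spellings unique)
  for (nm in names(bg$edges)) {
    e <- bg$edges[[nm]]
    if (e$from == from && e$to == to && length(e$chain) == length(chain) &&
        all(e$chain == chain)) {
      bg$edges[[nm]]$owners <- union(e$owners, owners)
      return(nm)
    }
  }
  nm <- sprintf("e%d", bg$next_id)
  bg$next_id <- bg$next_id + 1L
  bg$edges[[nm]] <- list(from = from, to = to, chain = chain,
                         owners = owners)
  nm
}

# split edge `nm` at interior exon `at`; propagates to every owning bin's path
.bg_split_edge <- function(bg, nm, at) {
  e <- bg$edges[[nm]]
  pos <- match(at, e$chain)
  stopifnot(!is.na(pos), pos > 1L, pos < length(e$chain))
  .bg_add_node(bg, at)
  n1 <- sprintf("e%d", bg$next_id); bg$next_id <- bg$next_id + 1L
  n2 <- sprintf("e%d", bg$next_id); bg$next_id <- bg$next_id + 1L
  bg$edges[[n1]] <- list(from = e$from, to = at,
                         chain = e$chain[seq_len(pos)], owners = e$owners)
  bg$edges[[n2]] <- list(from = at, to = e$to,
                         chain = e$chain[pos:length(e$chain)],
                         owners = e$owners)
  bg$edges[[nm]] <- NULL
  for (b in names(bg$paths)) {
    p <- bg$paths[[b]]
    i <- match(nm, p)
    if (!is.na(i)) bg$paths[[b]] <- append(p[-i], c(n1, n2), after = i - 1L)
  }
  c(n1, n2)
}

# ensure a node exists at exon `at` on bin `bid`'s path (splitting if interior)
.bg_split_path_at <- function(bg, bid, at) {
  for (nm in bg$paths[[bid]]) {
    e <- bg$edges[[nm]]
    if (at == e$chain[1L] || at == e$chain[length(e$chain)]) return(invisible())
    if (at %in% e$chain) { .bg_split_edge(bg, nm, at); return(invisible()) }
  }
  stop(sprintf("exon %d not on path of bin %s", at, bid))
}

# merge edges with identical (from, to, chain) into the first one
.bg_merge_parallel <- function(bg, nms) {
  keep <- nms[1L]
  for (nm in nms[-1L]) {
    bg$edges[[keep]]$owners <- union(bg$edges[[keep]]$owners,
                                     bg$edges[[nm]]$owners)
    for (b in names(bg$paths))
      bg$paths[[b]][bg$paths[[b]] == nm] <- keep
    bg$edges[[nm]] <- NULL
  }
  keep
}

# walk/join existing structure from node `cur` along chain R, restricted to
# edges owned by bins in `allowed`; returns list(edges, cur, R)
.bg_join_walk <- function(bg, cur, R, allowed, owner) {
  walked <- character(0)
  repeat {
    if (length(R) <= 1L) break
    cands <- character(0)
    for (nm in names(bg$edges)) {
      e <- bg$edges[[nm]]
      if (e$from == cur && length(intersect(e$owners, allowed))) {
        m <- length(e$chain)
        if (m > length(R) || !all(e$chain == R[seq_len(m)]))
          stop("bin incompatible with established splits")
        cands <- c(cands, nm)
      }
    }
    if (!length(cands)) break
    L <- min(vapply(cands, function(nm) length(bg$edges[[nm]]$chain),
                    integer(1)))
    target <- R[L]
    for (nm in cands) {
      if (length(bg$edges[[nm]]$chain) > L) .bg_split_edge(bg, nm, target)
    }
    # re-collect the now-parallel prefix edges and merge them
    pref <- character(0)
    for (nm in names(bg$edges)) {
      e <- bg$edges[[nm]]
      if (e$from == cur && e$to == target && length(e$chain) == L &&
          all(e$chain == R[seq_len(L)]) &&
          length(intersect(e$owners, allowed)))
        pref <- c(pref, nm)
    }
    kept <- .bg_merge_parallel(bg, pref)
    bg$edges[[kept]]$owners <- union(bg$edges[[kept]]$owners, owner)
    walked <- c(walked, kept)
    cur <- target
    R <- R[L:length(R)]
  }
  list(edges = walked, cur = cur, R = R)
}

#' Build the bin graph from the merged auxiliary graph
#'
#' Step (a): maximal bins are processed in genomic order (ties: longer chain
#' first).  Each bin gets nodes for its first and last exon; a bin without
#' incoming overlaps becomes a single maximal edge, otherwise the paths of its
#' overlap predecessors are split at the bin's first exon, joined along the
#' shared chain up to the rightmost pre-existing node, and the residual chain
#' is added as a new edge.  Step (b): each multi-contained bin joins all its
#' containers' paths along its own chain.
#'
#' @param am result of [merge_unique_chains()]
#' @return a bin-graph environment; see [bin_graph_edges()] for inspection
#' @export
build_bin_graph <- function(am) {
  bg <- .bg_new()
  M <- length(am$maximal)
  bg$bins <- c(am$maximal, am$multi_contained)
  ord <- order(vapply(am$maximal, function(b) b$chain[1L], integer(1)),
               -vapply(am$maximal, function(b) length(b$chain), integer(1)),
               vapply(am$maximal, function(b) chain_key(b$chain), character(1)))
  preds_of <- function(i) am$overlap$from[am$overlap$to == i]
  for (i in ord) {
    b <- am$maximal[[i]]
    ch <- b$chain
    f <- ch[1L]; l <- ch[length(ch)]
    bid <- as.character(i)
    .bg_add_node(bg, f); .bg_add_node(bg, l)
    if (length(ch) == 1L) { bg$paths[[bid]] <- character(0); next }
    preds <- preds_of(i)
    if (!length(preds)) {
      nm <- .bg_add_edge(bg, f, l, ch, i)
      bg$paths[[bid]] <- nm
      next
    }
    ok <- TRUE
    for (p in preds) {
      res <- try(.bg_split_path_at(bg, as.character(p), f), silent = TRUE)
      if (inherits(res, "try-error")) { ok <- FALSE; break }
    }
    if (!ok) { bg$dropped <- bg$dropped + 1L
               warning("bin incompatible with established splits; dropped")
               next }
    w <- try(.bg_join_walk(bg, f, ch, preds, i), silent = TRUE)
    if (inherits(w, "try-error")) { bg$dropped <- bg$dropped + 1L
                                    warning("bin incompatible; dropped")
                                    next }
    nm <- .bg_add_edge(bg, w$cur, l, w$R, i)
    bg$paths[[bid]] <- c(w$edges, nm)
  }
  # step (b): multi-contained bins.  A bin whose containers already share one
  # path over its span adds no structure and is absorbed; otherwise the
  # containers' paths are joined along the bin's chain.  `am$multi_contained`
  # comes ordered longest-first so nested bins see their hosts' joins.
  bg$retained_multi <- logical(length(am$multi_contained))
  for (k in seq_along(am$multi_contained)) {
    m <- am$multi_contained[[k]]
    ch <- m$chain
    f <- ch[1L]; l <- ch[length(ch)]
    mid <- as.character(M + k)
    cont <- as.character(am$containers[[k]])
    cont <- cont[cont %in% names(bg$paths)]
    if (length(cont) < 1L) next
    spans <- lapply(cont, function(cc) .bg_span_signature(bg, cc, ch))
    if (any(vapply(spans, is.null, logical(1)))) next  # noise survivor
    if (length(unique(vapply(spans, paste, character(1),
                             collapse = ","))) == 1L) {
      # already shared: absorb count and bases into the first container --
      # unless the span is a plain node, where the exon's own coverage
      # already accounts for these reads and crediting any container's
      # edges would double them into one path
      if (!startsWith(spans[[1L]][1L], "@")) {
        ci <- as.integer(cont[1L])
        bg$bins[[ci]]$count <- bg$bins[[ci]]$count + m$count
        bg$bins[[ci]]$bases <- bg$bins[[ci]]$bases + m$bases
      }
      next
    }
    bg$retained_multi[k] <- TRUE
    if (length(ch) == 1L) {
      # single-exon bin shared ambiguously: force the node on all containers
      for (cc in cont) .bg_split_path_at(bg, cc, f)
      bg$paths[[mid]] <- character(0)
      next
    }
    for (cc in cont) {
      .bg_split_path_at(bg, cc, f)
      .bg_split_path_at(bg, cc, l)
    }
    w <- .bg_join_walk(bg, f, ch, as.integer(cont), M + k)
    stopifnot(length(w$R) == 1L, w$cur == l)
    bg$paths[[mid]] <- w$edges
  }
  bg$n_maximal <- M
  bg
}

# signature of the minimal edge run covering `chain` on a bin's path: the
# edge names, or "@<label>" when a single-exon chain sits exactly on a node
.bg_span_signature <- function(bg, bid, chain) {
  p <- bg$paths[[bid]]
  f <- chain[1L]; l <- chain[length(chain)]
  if (length(chain) == 1L) {
    for (nm in p) {
      e <- bg$edges[[nm]]
      if (f == e$chain[1L]) return(sprintf("@%d", f))
      if (f == e$chain[length(e$chain)]) return(sprintf("@%d", f))
      if (f %in% e$chain) return(nm)
    }
    return(NULL)
  }
  first <- NA_integer_; last <- NA_integer_
  for (i in seq_along(p)) {
    e <- bg$edges[[p[i]]]
    if (is.na(first) && f %in% e$chain &&
        f != e$chain[length(e$chain)]) first <- i
    if (!is.na(first) && l %in% e$chain) { last <- i; break }
  }
  if (is.na(first) || is.na(last)) return(NULL)
  p[first:last]
}

#' Chains subject to condition (ii) after construction
#'
#' The merged maximal bins plus every multi-contained bin that genuinely
#' joined distinct container paths (bins falling into already-shared regions
#' were absorbed and are excluded).
#' @param am result of [merge_unique_chains()]
#' @param bg the graph built from it
#' @export
retained_chains <- function(am, bg) {
  ch <- lapply(am$maximal, `[[`, "chain")
  if (length(am$multi_contained))
    ch <- c(ch, lapply(am$multi_contained[bg$retained_multi], `[[`, "chain"))
  ch
}

#' Edge table of a bin graph
#' @param bg a bin-graph environment
#' @return data.frame(name, from, to, chain, n_owners); `from` 0 encodes the
#'   source `s`, `to` -1 the sink `t`
#' @export
bin_graph_edges <- function(bg) {
  nms <- names(bg$edges)
  if (is.null(nms)) nms <- character(0)
  data.frame(name = nms,
             from = vapply(nms, function(n) bg$edges[[n]]$from, integer(1)),
             to = vapply(nms, function(n) bg$edges[[n]]$to, integer(1)),
             chain = vapply(nms, function(n) chain_key(bg$edges[[n]]$chain),
                            character(1)),
             n_owners = vapply(nms, function(n)
               length(bg$edges[[n]]$owners), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Node labels of a bin graph (exon indices; excludes s and t)
#' @param bg a bin-graph environment
#' @export
bin_graph_nodes <- function(bg) sort(bg$nodes)

# wire source and sink: s (label 0) feeds every node without predecessors,
# t (label -1) drains every node without successors
.bg_finalize_st <- function(bg) {
  froms <- vapply(bg$edges, function(e) e$from, integer(1))
  tos <- vapply(bg$edges, function(e) e$to, integer(1))
  for (v in sort(bg$nodes)) {
    if (!v %in% tos) .bg_add_edge(bg, 0L, v, integer(0), integer(0))
    if (!v %in% froms) .bg_add_edge(bg, v, -1L, integer(0), integer(0))
  }
  invisible(bg)
}

# spelled exon chain of an edge sequence (plus path node labels, which covers
# edge-less singleton paths)
.bg_spell <- function(bg, edge_names, extra_nodes = integer(0)) {
  ex <- unlist(lapply(edge_names, function(nm) bg$edges[[nm]]$chain))
  sort(unique(c(ex, extra_nodes)))
}

# enumerate all s-t paths as lists of edge names (cap guards pathological
# cases; loci are small)
.bg_all_paths <- function(bg, cap = 20000L) {
  out <- list()
  edges_from <- split(names(bg$edges),
                      vapply(bg$edges, function(e) e$from, integer(1)))
  recurse <- function(v, acc) {
    if (length(out) >= cap) return()
    for (nm in edges_from[[as.character(v)]] %||% character(0)) {
      e <- bg$edges[[nm]]
      if (e$to == -1L) out[[length(out) + 1L]] <<- c(acc, nm)
      else recurse(e$to, c(acc, nm))
    }
  }
  recurse(0L, character(0))
  out
}

#' Verify the four bin-graph conditions
#'
#' (i) every s-t path spells a strictly increasing exon chain and no two
#' paths spell the same chain; (ii) every retained bin has exactly one path
#' between its terminal nodes spelling its chain; (iii) the exon-node count
#' equals the exhaustive-search minimum (checked when the locus has at most
#' `oracle_max_exons` exons); acyclicity and label injectivity hold by
#' construction and are re-checked.
#'
#' @param bg a bin-graph environment (s/t wired)
#' @param retained_chains list of integer chains subject to condition (ii)
#' @param oracle_max_exons exhaustive minimality search cutoff
#' @return list of violation messages (empty when all conditions hold)
#' @export
check_conditions <- function(bg, retained_chains, oracle_max_exons = 8L) {
  viol <- character(0)
  if (anyDuplicated(bg$nodes)) viol <- c(viol, "node labels not injective")
  if (!.bg_is_acyclic(bg)) viol <- c(viol, "graph contains a cycle")
  paths <- .bg_all_paths(bg)
  spells <- vapply(paths, function(p) chain_key(.bg_spell(bg, p)),
                   character(1))
  for (p in seq_along(paths)) {
    ch <- .bg_spell(bg, paths[[p]])
    if (!is_strictly_increasing(ch))
      viol <- c(viol, sprintf("path %d spells a malformed chain", p))
  }
  if (anyDuplicated(spells))
    viol <- c(viol, "two distinct s-t paths spell the same transcript")
  for (ch in retained_chains) {
    if (length(ch) == 1L) {
      if (!ch %in% bg$nodes)
        viol <- c(viol, sprintf("bin %s lost its node", chain_key(ch)))
      next
    }
    n <- .bg_count_spelling_paths(bg, ch)
    if (n != 1L)
      viol <- c(viol, sprintf("bin %s maps to %d paths", chain_key(ch), n))
  }
  exons <- sort(unique(unlist(retained_chains)))
  if (length(exons) <= oracle_max_exons && length(retained_chains)) {
    opt <- minimal_node_count(retained_chains)
    if (length(bg$nodes) != opt)
      viol <- c(viol, sprintf("node count %d, exhaustive minimum %d",
                              length(bg$nodes), opt))
  }
  viol
}

.bg_is_acyclic <- function(bg) {
  vs <- c(0L, -1L, bg$nodes)
  adj <- lapply(vs, function(v) {
    unique(vapply(bg$edges, function(e) if (e$from == v) e$to else NA_integer_,
                  integer(1)))
  })
  names(adj) <- as.character(vs)
  state <- setNames(integer(length(vs)), as.character(vs))
  ok <- TRUE
  visit <- function(v) {
    key <- as.character(v)
    if (state[[key]] == 1L) { ok <<- FALSE; return() }
    if (state[[key]] == 2L) return()
    state[[key]] <<- 1L
    for (w in adj[[key]]) if (!is.na(w)) visit(w)
    state[[key]] <<- 2L
  }
  for (v in vs) visit(v)
  ok
}

.bg_count_spelling_paths <- function(bg, ch) {
  f <- ch[1L]; l <- ch[length(ch)]
  count <- 0L
  recurse <- function(v, got) {
    if (v == l && length(got) == length(ch) && all(got == ch)) {
      count <<- count + 1L
      return()
    }
    for (nm in names(bg$edges)) {
      e <- bg$edges[[nm]]
      if (e$from == v && length(e$chain)) {
        new <- merge_chains_at(got, e$chain)
        m <- length(new)
        if (m <= length(ch) && all(new == ch[seq_len(m)]))
          recurse(e$to, new)
      }
    }
  }
  recurse(f, f)
  count
}

#' Exhaustive minimal node count for a retained-bin set
#'
#' Independent oracle for condition (iii): searches node subsets (always
#' including every bin's terminal exons) in increasing size, accepting the
#' first subset for which the uniformly split graph satisfies conditions (i)
#' and (ii).  Intended for loci with few exons.
#'
#' @param chains list of integer exon chains of the retained bins
#' @return minimal number of exon nodes
#' @export
minimal_node_count <- function(chains) {
  endpoints <- sort(unique(unlist(lapply(chains, function(ch)
    c(ch[1L], ch[length(ch)])))))
  interior <- setdiff(sort(unique(unlist(chains))), endpoints)
  for (k in 0:length(interior)) {
    combs <- if (k == 0L) list(integer(0))
             else utils::combn(interior, k, simplify = FALSE)
    for (extra in combs) {
      S <- sort(c(endpoints, extra))
      if (.forced_graph_valid(chains, S)) return(length(S))
    }
  }
  length(endpoints) + length(interior)
}

# uniformly split graph over node set S; validity = conditions (i) and (ii)
.forced_graph_valid <- function(chains, S) {
  edges <- list()
  add <- function(from, to, seg) {
    key <- paste(from, to, chain_key(seg), sep = "|")
    edges[[key]] <<- list(from = from, to = to, chain = seg)
  }
  for (ch in chains) {
    if (length(ch) == 1L) next
    cuts <- which(ch %in% S)
    if (!1L %in% cuts || !length(ch) %in% cuts) return(FALSE)
    for (i in seq_len(length(cuts) - 1L))
      add(ch[cuts[i]], ch[cuts[i + 1L]], ch[cuts[i]:cuts[i + 1L]])
  }
  # (ii): unique spelling path per chain
  for (ch in chains) {
    if (length(ch) == 1L) next
    n <- 0L
    recurse <- function(v, got) {
      if (v == ch[length(ch)] && length(got) == length(ch) &&
          all(got == ch)) { n <<- n + 1L; return() }
      for (e in edges) {
        if (e$from == v) {
          new <- merge_chains_at(got, e$chain)
          m <- length(new)
          if (m <= length(ch) && all(new == ch[seq_len(m)])) recurse(e$to, new)
        }
      }
    }
    recurse(ch[1L], ch[1L])
    if (n != 1L) return(FALSE)
  }
  # (i): s-t path spellings distinct and well-formed
  froms <- vapply(edges, function(e) e$from, integer(1))
  tos <- vapply(edges, function(e) e$to, integer(1))
  sources <- setdiff(froms, tos)
  spells <- character(0); bad <- FALSE
  recurse2 <- function(v, got) {
    if (bad) return()
    nxt <- which(froms == v)
    if (!length(nxt)) { spells <<- c(spells, chain_key(got)); return() }
    for (i in nxt) {
      e <- edges[[i]]
      new <- sort(unique(c(got, e$chain)))
      if (!is_strictly_increasing(new)) { bad <<- TRUE; return() }
      recurse2(e$to, new)
    }
  }
  for (v in unique(sources)) recurse2(v, integer(0))
  if (bad || anyDuplicated(spells)) return(FALSE)
  TRUE
}

#' Export a bin graph as DOT
#' @param bg a bin-graph environment
#' @param path output file
#' @export
bin_graph_dot <- function(bg, path) {
  ed <- bin_graph_edges(bg)
  nm <- function(v) ifelse(v == 0L, "s", ifelse(v == -1L, "t",
                                                paste0("x", v)))
  lines <- c("digraph bin_graph {",
             sprintf("  %s -> %s [label=\"%s\"];", nm(ed$from), nm(ed$to),
                     ed$chain),
             "}")
  writeLines(lines, path)
  invisible(path)
}
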