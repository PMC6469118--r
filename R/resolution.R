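#' @name resolution
#' @title Graph simplification, phasing resolution and transcript extraction
#'
#' @description
#' After the flow is solved, conservation lets the graph be contracted until
#' every internal node has at least two in- and two out-edges; those nodes are
#' the genuinely unresolved points of the assembly.  Phasing evidence (long
#' bins spanning a node, mate pairs bridging it) selects in/out edge pairings
#' through a two-step linear program; leftover flow is decomposed into the
#' longest possible transcripts.
NULL

.sg_new <- function() {
  sg <- new.env(parent = emptyenv())
  sg$edges <- list()   # name -> list(from, to, chain, fl, cov, evid)
  sg$next_id <- 1L
  sg
}

.sg_add <- function(sg, from, to, chain, fl, cov = fl, evid = FALSE) {
  nm <- sprintf("r%d", sg$next_id)
  sg$next_id <- sg$next_id + 1L
  sg$edges[[nm]] <- list(from = from, to = to, chain = chain, fl = fl,
                         cov = cov, evid = evid)
  nm
}

.sg_nodes <- function(sg) {
  v <- unlist(lapply(sg$edges, function(e) c(e$from, e$to)))
  sort(setdiff(unique(v), c(0L, -1L)))
}

.sg_in <- function(sg, v) names(sg$edges)[vapply(sg$edges, function(e)
  e$to == v, logical(1))]
.sg_out <- function(sg, v) names(sg$edges)[vapply(sg$edges, function(e)
  e$from == v, logical(1))]

#' Simplify a flow-annotated bin graph
#'
#' Drops zero-flow edges, then contracts tree nodes (in- or out-degree 1) and
#' composite-path nodes, concatenating edge chains and carrying flows through
#' unchanged.  Flow conservation is asserted at every contracted node.
#' The remaining internal nodes all have in- and out-degree at least two and
#' are reported as the likely points of assembly mismatches.
#'
#' @param bg bin-graph environment (s/t wired)
#' @param edge_flow named numeric flow per bin-graph edge
#' @param edge_cov named numeric observed coverage per edge
#' @param min_flow edges below this flow are dropped up front
#' @return simplified-graph environment
#' @export
simplify_graph <- function(bg, edge_flow, edge_cov, min_flow = 0.5) {
  sg <- .sg_new()
  for (nm in names(bg$edges)) {
    e <- bg$edges[[nm]]
    fl <- edge_flow[[nm]] %||% 0
    if (fl >= min_flow)
      .sg_add(sg, e$from, e$to, e$chain, fl,
              cov = if (length(e$chain)) edge_cov[[nm]] %||% fl else Inf,
              evid = length(e$owners) > 0L)  # read bins map onto this edge
  }
  .sg_contract(sg, strict = TRUE)  # UTEC output must conserve flow exactly
  sg
}

.sg_contract <- function(sg, strict = FALSE) {
  repeat {
    changed <- FALSE
    for (v in .sg_nodes(sg)) {
      ins <- .sg_in(sg, v); outs <- .sg_out(sg, v)
      if (!length(ins) || !length(outs)) {
        # dangling after removals: drop incident edges
        for (nm in c(ins, outs)) sg$edges[[nm]] <- NULL
        changed <- TRUE
        break
      }
      if (length(ins) == 1L || length(outs) == 1L) {
        fin <- sum(vapply(ins, function(n) sg$edges[[n]]$fl, numeric(1)))
        fout <- sum(vapply(outs, function(n) sg$edges[[n]]$fl, numeric(1)))
        if (strict && abs(fin - fout) > 1e-6 * max(1, fin))
          stop(sprintf("flow conservation violated at node %d", v))
        # after residual pruning the sides may disagree; never fabricate
        # flow beyond what the constraining side provides
        # contracting a node between two chain-less (source/sink) edges must
        # keep the node's own exon label in the merged edge
        chain2 <- function(ei, eo) {
          if (!length(ei$chain) && !length(eo$chain)) return(v)
          merge_chains_at(ei$chain, eo$chain)
        }
        # a path is evidenced only if every exon-bearing segment is;
        # source/sink segments are neutral
        evid2 <- function(ei, eo) {
          if (!length(ei$chain)) return(eo$evid || !length(eo$chain))
          if (!length(eo$chain)) return(ei$evid)
          ei$evid && eo$evid
        }
        if (length(ins) == 1L) {
          ei <- sg$edges[[ins]]
          fac <- if (fout > fin) fin / fout else 1
          for (nm in outs) {
            eo <- sg$edges[[nm]]
            .sg_add(sg, ei$from, eo$to, chain2(ei, eo),
                    eo$fl * fac, cov = min(ei$cov, eo$cov),
                    evid = evid2(ei, eo))
          }
        } else {
          eo <- sg$edges[[outs]]
          fac <- if (fin > fout) fout / fin else 1
          for (nm in ins) {
            ei <- sg$edges[[nm]]
            .sg_add(sg, ei$from, eo$to, chain2(ei, eo),
                    ei$fl * fac, cov = min(ei$cov, eo$cov),
                    evid = evid2(ei, eo))
          }
        }
        for (nm in c(ins, outs)) sg$edges[[nm]] <- NULL
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  invisible(sg)
}

#' Unresolved nodes of a simplified graph (diagnostic output)
#' @param sg simplified graph
#' @param ranges exon-range table (for coordinates); optional
#' @return data.frame(node, n_in, n_out, start, end)
#' @export
unresolved_nodes <- function(sg, ranges = NULL) {
  vs <- .sg_nodes(sg)
  df <- data.frame(node = vs,
                   n_in = vapply(vs, function(v) length(.sg_in(sg, v)),
                                 integer(1)),
                   n_out = vapply(vs, function(v) length(.sg_out(sg, v)),
                                  integer(1)))
  if (!is.null(ranges) && nrow(df)) {
    df$start <- ranges$start[match(df$node, ranges$index)]
    df$end <- ranges$end[match(df$node, ranges$index)]
  }
  df
}

# does bin chain `c` support in-edge `ce` (chain ending at v)?  Returns the
# number of matched exons before v, 0 if incompatible.
.match_in <- function(c, v, ce) {
  pv <- match(v, c); pe <- match(v, ce)
  if (is.na(pv) || is.na(pe) || pv < 2L) return(0L)
  m <- min(pv, pe) - 1L
  if (m < 1L) return(0L)
  if (all(c[(pv - m):(pv - 1L)] == ce[(pe - m):(pe - 1L)])) m else 0L
}

# match one mate of a paired link against an edge chain on one side of the
# node.  Returns 2 (strong: the mate lies inside the edge), 1 (weak: the mate
# could lie on a path continuing beyond the edge's other endpoint), or 0
# (incompatible).  `terminal` says the edge's far endpoint is the source or
# sink, where no continuation exists.
.match_link_side <- function(mate, ce, terminal, before) {
  if (!length(ce)) return(0L)
  if (chain_is_infix(mate, ce)) return(2L)
  n <- length(mate); m <- length(ce)
  if (before) {
    # mate lies upstream of the node: beyond the edge's start?
    if (mate[n] < ce[1L]) return(if (terminal) 0L else 1L)
    # tail of the mate may align with the head of the edge chain
    if (!terminal) for (k in seq_len(min(n - 1L, m))) {
      if (all(mate[(n - k + 1L):n] == ce[seq_len(k)])) return(1L)
    }
  } else {
    if (mate[1L] > ce[m]) return(if (terminal) 0L else 1L)
    if (!terminal) for (k in seq_len(min(n - 1L, m))) {
      if (all(mate[seq_len(k)] == ce[(m - k + 1L):m])) return(1L)
    }
  }
  0L
}

# do both mate chains occur, in order, as infixes of one edge chain?
.pair_fits_chain <- function(left, right, ce) {
  nl <- length(left); nc <- length(ce)
  if (nl + length(right) > nc) return(FALSE)
  for (h in which(ce == left[1L])) {
    if (h + nl - 1L > nc || !all(ce[h:(h + nl - 1L)] == left)) next
    rest <- ce[(h + nl):nc]
    if (length(rest) >= length(right) && chain_is_infix(right, rest))
      return(TRUE)
  }
  FALSE
}

.match_out <- function(c, v, ce) {
  pv <- match(v, c); pe <- match(v, ce)
  if (is.na(pv) || is.na(pe) || pv >= length(c)) return(0L)
  m <- min(length(c) - pv, length(ce) - pe)
  if (m < 1L) return(0L)
  if (all(c[(pv + 1L):(pv + m)] == ce[(pe + 1L):(pe + m)])) m else 0L
}

#' Collect phasing evidence at the unresolved nodes
#'
#' Long bins spanning a node and paired links bridging it induce connections
#' between specific in- and out-edges.  Bins that are sub-chains of another
#' spanning bin are dropped (they add no information); evidence matching a
#' unique in/out pair is `specific`, ambiguous evidence is admitted only for
#' edge pairs no specific connection covers, with its count split over the
#' admitted pairs.
#'
#' @param sg simplified graph
#' @param bins list of read bins (chain, count)
#' @param links list of paired links (left, right, count)
#' @return list per unresolved node: list(`specific` = data.frame(e, ep, n,
#'   rank), `ambiguous` = list of candidate pair sets with their counts)
#' @export
collect_evidence <- function(sg, bins, links) {
  out <- list()
  for (v in .sg_nodes(sg)) {
    S <- .sg_in(sg, v); T_ <- .sg_out(sg, v)
    S <- S[vapply(S, function(n) length(sg$edges[[n]]$chain) > 0, logical(1))]
    T_ <- T_[vapply(T_, function(n) length(sg$edges[[n]]$chain) > 0,
                    logical(1))]
    if (!length(S) || !length(T_)) next
    all_chains <- lapply(sg$edges, `[[`, "chain")
    spanning <- Filter(function(b) {
      p <- match(v, b$chain)
      !is.na(p) && p > 1L && p < length(b$chain) &&
        # a bin that fits inside one edge is explained without this node
        !any(vapply(all_chains, function(ce)
          chain_is_infix(b$chain, ce), logical(1)))
    }, bins)
    if (length(spanning) > 1L) {
      drop <- vapply(seq_along(spanning), function(i) {
        any(vapply(seq_along(spanning), function(j) {
          i != j && length(spanning[[i]]$chain) < length(spanning[[j]]$chain) &&
            chain_is_infix(spanning[[i]]$chain, spanning[[j]]$chain)
        }, logical(1)))
      }, logical(1))
      spanning <- spanning[!drop]
    }
    con <- new.env(parent = emptyenv())
    add_con <- function(e, ep, n, rank) {
      key <- paste(e, ep, sep = "|")
      cur <- con[[key]] %||% list(e = e, ep = ep, n = 0, rank = 0L)
      cur$n <- cur$n + n
      cur$rank <- max(cur$rank, rank)
      con[[key]] <- cur
    }
    ambiguous <- list()
    for (b in spanning) {
      mi <- vapply(S, function(nm) .match_in(b$chain, v, sg$edges[[nm]]$chain),
                   integer(1))
      mo <- vapply(T_, function(nm) .match_out(b$chain, v,
                                               sg$edges[[nm]]$chain),
                   integer(1))
      ei <- S[mi > 0L]; eo <- T_[mo > 0L]
      if (length(ei) == 1L && length(eo) == 1L) {
        add_con(ei, eo, b$count, max(mi) + max(mo))
      } else if (length(ei) >= 1L && length(eo) >= 1L) {
        ambiguous[[length(ambiguous) + 1L]] <-
          list(pairs = expand.grid(e = ei, ep = eo,
                                   stringsAsFactors = FALSE),
               n = b$count, rank = 1L)
      }
    }
    for (lk in links) {
      # a pair that fits together inside one edge is explained by a path
      # bypassing this node; counting it here would fabricate a connection
      if (any(vapply(all_chains, function(ce)
        .pair_fits_chain(lk$left, lk$right, ce), logical(1)))) next
      mi <- vapply(S, function(nm) {
        e <- sg$edges[[nm]]
        if (v %in% lk$left && match(v, lk$left) > 1L)
          (if (.match_in(lk$left, v, e$chain) > 0L) 2L else 0L)
        else .match_link_side(lk$left, e$chain, e$from == 0L, before = TRUE)
      }, integer(1))
      mo <- vapply(T_, function(nm) {
        e <- sg$edges[[nm]]
        if (v %in% lk$right && match(v, lk$right) < length(lk$right))
          (if (.match_out(lk$right, v, e$chain) > 0L) 2L else 0L)
        else .match_link_side(lk$right, e$chain, e$to == -1L,
                              before = FALSE)
      }, integer(1))
      ei <- S[mi == 2L]; eo <- T_[mo == 2L]
      ei_any <- S[mi > 0L]; eo_any <- T_[mo > 0L]
      if (!length(ei_any) || !length(eo_any)) next
      if (length(ei) == 1L && length(eo) == 1L &&
          length(ei_any) == 1L && length(eo_any) == 1L)
        add_con(ei, eo, lk$count, 2L)
      else ambiguous[[length(ambiguous) + 1L]] <-
        list(pairs = expand.grid(e = ei_any, ep = eo_any,
                                 stringsAsFactors = FALSE),
             n = lk$count, rank = 1L)
    }
    keys <- sort(ls(con))
    if (!length(keys) && !length(ambiguous)) next
    specific <- if (length(keys)) do.call(rbind, lapply(keys, function(k) {
      cc <- con[[k]]
      data.frame(e = cc$e, ep = cc$ep, n = cc$n, rank = cc$rank,
                 stringsAsFactors = FALSE)
    })) else data.frame(e = character(0), ep = character(0), n = numeric(0),
                        rank = integer(0), stringsAsFactors = FALSE)
    out[[as.character(v)]] <- list(specific = specific, ambiguous = ambiguous)
  }
  out
}

#' Resolve one ambiguous node with the two-step phasing LP
#'
#' Step 1 finds connection flows x minimizing the total absolute deviation
#' from the evidence counts n, subject to never exceeding the edge flows.
#' Step 2 fixes the step-1 optima as lower bounds and maximizes the used flow
#' by minimizing the unexplained residuals y on both edge sides.
#'
#' @param fl named numeric: flow of every in- and out-edge at the node
#' @param ev data.frame(e, ep, n) of connections
#' @return list(x = data.frame(e, ep, x), y = named residuals,
#'   obj1, obj2); NULL when the LP fails
#' @export
resolve_node <- function(fl, ev) {
  m <- nrow(ev)
  edges <- unique(c(ev$e, ev$ep))
  ne <- length(edges)
  inc <- matrix(0, nrow = ne, ncol = m,
                dimnames = list(edges, NULL))
  for (i in seq_len(m)) {
    inc[ev$e[i], i] <- 1
    inc[ev$ep[i], i] <- 1
  }
  flv <- vapply(edges, function(e) fl[[e]], numeric(1))
  # step 1: min sum u,  u >= |n - x|, per-edge sum(x) <= fl
  cc1 <- c(rep(0, m), rep(1, m))
  A1 <- rbind(cbind(-diag(m), -diag(m)),
              cbind(diag(m), -diag(m)),
              cbind(inc, matrix(0, ne, m)))
  b1 <- c(-ev$n, ev$n, flv)
  s1 <- tryCatch(pracma::linprog(cc1, A = A1, b = b1, maxiter = 200L),
                 error = function(e) NULL)
  if (is.null(s1) || is.null(s1$x) || !all(is.finite(s1$x))) return(NULL)
  x1 <- pmax(0, s1$x[seq_len(m)])
  obj1 <- sum(abs(ev$n - x1))
  # step 2: min sum y,  y_e >= fl_e - sum(x at e), x >= x1, sum(x at e) <= fl
  cc2 <- c(rep(0, m), rep(1, ne))
  A2 <- rbind(cbind(-inc, -diag(ne)),
              cbind(inc, matrix(0, ne, ne)))
  b2 <- c(-flv, flv)
  lb2 <- c(x1 - 1e-9, rep(0, ne))
  s2 <- tryCatch(pracma::linprog(cc2, A = A2, b = b2, lb = lb2,
                                 maxiter = 200L),
                 error = function(e) NULL)
  if (is.null(s2) || is.null(s2$x) || !all(is.finite(s2$x))) return(NULL)
  x2 <- pmax(0, s2$x[seq_len(m)])
  obj2v <- sum(s2$x[m + seq_len(ne)])
  # the used-flow optimum is typically degenerate; among its solutions pick
  # the one closest (L1) to an evidence-proportional allocation x ~ alpha n,
  # with the scale alpha free -- linear because alpha is a scalar
  # variables: x (m), y (ne), alpha, u (m)
  cc3 <- c(rep(0, m + ne + 1L), rep(1, m))
  A3 <- rbind(
    cbind(-inc, -diag(ne), matrix(0, ne, 1L + m)),       # y >= fl - sum x
    cbind(inc, matrix(0, ne, ne + 1L + m)),              # sum x <= fl
    c(rep(0, m), rep(1, ne), 0, rep(0, m)),              # sum y <= optimum
    cbind(diag(m), matrix(0, m, ne), -ev$n, -diag(m)),   # u >= x - n alpha
    cbind(-diag(m), matrix(0, m, ne), ev$n, -diag(m)))   # u >= n alpha - x
  b3 <- c(-flv, flv, obj2v + 1e-6, rep(0, m), rep(0, m))
  lb3 <- c(x1 - 1e-9, rep(0, ne), 0, rep(0, m))
  s3 <- tryCatch(pracma::linprog(cc3, A = A3, b = b3, lb = lb3,
                                 maxiter = 400L),
                 error = function(e) NULL)
  if (!is.null(s3) && !is.null(s3$x) && all(is.finite(s3$x)))
    x2 <- pmax(0, s3$x[seq_len(m)])
  # integral rounding, kept feasible per edge
  x <- round(x2)
  for (e in edges) {
    idx <- which(ev$e == e | ev$ep == e)
    over <- sum(x[idx]) - flv[[e]]
    while (over > 1e-9) {
      j <- idx[which.max(x[idx])]
      dec <- min(x[j], ceiling(over))
      x[j] <- x[j] - dec
      over <- over - dec
    }
  }
  y <- flv - as.numeric(inc %*% x)
  names(y) <- edges
  obj2 <- sum(pmax(0, flv - as.numeric(inc %*% x2)))
  list(x = data.frame(e = ev$e, ep = ev$ep, x = x, stringsAsFactors = FALSE),
       y = y, x1 = x1, obj1 = obj1, obj2 = obj2)
}

# replace node v by its resolved connections.  Edges no connection touches
# keep their full flow as residual stubs (incomplete evidence must leave
# significant flow intact for later decomposition); on edges the evidence
# does cover, unexplained leftover flow is coverage-estimation noise and is
# dropped.
.sg_apply_resolution <- function(sg, v, res) {
  ins <- .sg_in(sg, v); outs <- .sg_out(sg, v)
  covered <- unique(c(res$x$e, res$x$ep))
  for (i in seq_len(nrow(res$x))) {
    if (res$x$x[i] < 0.5) next
    ei <- sg$edges[[res$x$e[i]]]; eo <- sg$edges[[res$x$ep[i]]]
    .sg_add(sg, ei$from, eo$to, merge_chains_at(ei$chain, eo$chain),
            res$x$x[i], cov = min(ei$cov, eo$cov), evid = TRUE)
  }
  for (nm in c(ins, outs)) {
    if (nm %in% covered) { sg$edges[[nm]] <- NULL; next }
    sg$edges[[nm]]$evid <- FALSE  # residual stub: unexplained by evidence
  }
  .sg_contract(sg)
  invisible(sg)
}

#' Resolve all evidenced nodes of a simplified graph
#'
#' Nodes are processed in the order of evidence quality (best specificity
#' rank, then minimal square-root error per flow from a trial step-1 LP);
#' evidence is re-collected after each resolution since edges change.
#'
#' @param sg simplified graph
#' @param bins,links read bins and paired links of the locus
#' @return sg, modified in place (also returned)
#' @export
resolve_graph <- function(sg, bins, links) {
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 50L) break
    evs <- collect_evidence(sg, bins, links)
    if (!length(evs)) break
    score <- lapply(names(evs), function(vn) {
      v <- as.integer(vn)
      fl <- .sg_flows_at(sg, v)
      r <- .resolve_node_staged(fl, evs[[vn]])
      if (is.null(r)) return(NULL)
      rank <- if (nrow(evs[[vn]]$specific)) max(evs[[vn]]$specific$rank)
              else 1L
      # evidence quality: nodes with fewer alternative pairings are better
      # determined, and resolving them first lengthens the chains seen by
      # the harder nodes
      list(v = v, res = r, size = length(fl), rank = rank,
           err = sqrt(sum((r$ev$n - r$x$x)^2)) / max(1, sum(unlist(fl))))
    })
    score <- Filter(Negate(is.null), score)
    if (!length(score)) break
    o <- order(vapply(score, `[[`, numeric(1), "size"),
               -vapply(score, `[[`, numeric(1), "rank"),
               vapply(score, `[[`, numeric(1), "err"),
               vapply(score, `[[`, numeric(1), "v"))
    best <- score[[o[1L]]]
    .sg_apply_resolution(sg, best$v, best$res)
  }
  sg
}

# two-stage resolution of one node: specific evidence first; ambiguous
# candidate pairs are admitted only for edges whose flow the specific
# connections cannot sufficiently explain (residual above one flow unit),
# with each read's count split over its admitted pairs
.resolve_node_staged <- function(fl, ev) {
  E1 <- ev$specific
  res <- if (nrow(E1)) resolve_node(fl, E1) else NULL
  # residual flow per edge: full flow for edges no specific connection
  # touches, the LP residual for the others
  resid <- stats::setNames(unlist(fl), names(fl))
  if (!is.null(res)) resid[names(res$y)] <- res$y
  if (length(ev$ambiguous)) {
    extra <- list()
    covered_keys <- if (nrow(E1)) paste(E1$e, E1$ep, sep = "|") else
      character(0)
    x1map <- if (!is.null(res))
      stats::setNames(res$x$x, paste(res$x$e, res$x$ep, sep = "|"))
    else numeric(0)
    for (am in ev$ambiguous) {
      keys <- paste(am$pairs$e, am$pairs$ep, sep = "|")
      open <- !(keys %in% covered_keys)
      # specific siblings sufficiently explain the observation when their
      # allocated flow can account for its read count
      cap <- sum(x1map[keys[!open]], na.rm = TRUE)
      if (am$n <= cap + 2 * sqrt(max(cap, 1))) next
      # residual must exceed the counting-noise scale (two Poisson standard
      # deviations of the edge flow) on both sides to count as unexplained
      sig <- function(nm) {
        nm %in% names(resid) &&
          resid[[nm]] > 2 * sqrt(max(1, fl[[nm]] %||% 1))
      }
      touch <- vapply(seq_len(nrow(am$pairs)), function(i)
        sig(am$pairs$e[i]) && sig(am$pairs$ep[i]), logical(1))
      adm <- which(open & touch)
      for (i in adm)
        extra[[length(extra) + 1L]] <- data.frame(
          e = am$pairs$e[i], ep = am$pairs$ep[i],
          n = am$n / length(adm), rank = am$rank,
          stringsAsFactors = FALSE)
    }
    if (length(extra)) {
      E2 <- rbind(E1, do.call(rbind, extra))
      # merge duplicate pairs
      key <- paste(E2$e, E2$ep, sep = "|")
      E2 <- do.call(rbind, lapply(split(E2, key), function(d)
        data.frame(e = d$e[1L], ep = d$ep[1L], n = sum(d$n),
                   rank = max(d$rank), stringsAsFactors = FALSE)))
      E2 <- E2[order(E2$e, E2$ep), , drop = FALSE]
      res2 <- resolve_node(fl, E2)
      if (!is.null(res2)) return(c(res2, list(ev = E2)))
    }
  }
  if (is.null(res)) return(NULL)
  c(res, list(ev = E1))
}

.sg_flows_at <- function(sg, v) {
  nms <- c(.sg_in(sg, v), .sg_out(sg, v))
  fl <- lapply(nms, function(nm) sg$edges[[nm]]$fl)
  names(fl) <- nms
  fl
}

#' Remove weak unevidenced edges
#'
#' An edge without phasing evidence is removed when its flow is below
#' `frac_evidenced` (default 30%) of any other edge incident to a shared
#' vertex, or below `frac_unevidenced` (default 75%) when that vertex has no
#' evidence at all.  A removal that would leave a vertex without in- or
#' out-edges is rolled back.  Idempotent.
#'
#' @param sg simplified graph
#' @param evs evidence per node (from [collect_evidence()])
#' @param frac_evidenced,frac_unevidenced thresholds in [0, 1]
#' @return number of edges removed
#' @export
filter_edges <- function(sg, evs, frac_evidenced = 0.30,
                         frac_unevidenced = 0.75) {
  edge_evid <- function(nm) {
    isTRUE(sg$edges[[nm]]$evid) ||
      any(vapply(evs, function(ev)
        nm %in% c(ev$specific$e, ev$specific$ep), logical(1)))
  }
  removed <- 0L
  repeat {
    victim <- NULL
    for (nm in names(sg$edges)) {
      e <- sg$edges[[nm]]
      if (edge_evid(nm)) next
      for (v in c(e$from, e$to)) {
        frac <- if (!is.null(evs[[as.character(v)]])) frac_evidenced
                else frac_unevidenced
        others <- setdiff(c(.sg_in(sg, v), .sg_out(sg, v)), nm)
        # compare only against real transcript edges, not source/sink stubs
        # whose flow aggregates several paths
        others <- others[vapply(others, function(n2)
          length(sg$edges[[n2]]$chain) > 0, logical(1))]
        if (!length(others)) next
        mx <- max(vapply(others, function(n2) sg$edges[[n2]]$fl, numeric(1)))
        if (e$fl < frac * mx) { victim <- nm; break }
      }
      if (!is.null(victim)) break
    }
    if (is.null(victim)) break
    saved <- sg$edges[[victim]]
    sg$edges[[victim]] <- NULL
    dangling <- any(vapply(.sg_nodes(sg), function(v)
      !length(.sg_in(sg, v)) || !length(.sg_out(sg, v)), logical(1)))
    if (dangling) {
      sg$edges[[victim]] <- saved  # critical edge: roll back
      break
    }
    removed <- removed + 1L
  }
  removed
}

#' Remove retained introns without coverage support
#'
#' An edge whose chain runs contiguously (genomically adjacent exon ranges)
#' across the intron of another edge's splice is an intron-retention
#' candidate; it is removed unless the median per-base depth over the
#' intronic span reaches `ir_frac` of the weaker flanking exon's mean depth.
#'
#' @param sg simplified graph
#' @param ranges exon-range table
#' @param deltas coverage store
#' @param chrom chromosome
#' @param ir_frac significance threshold (default 0.35)
#' @return number of edges removed
#' @export
filter_intron_retention <- function(sg, ranges, deltas, chrom,
                                    ir_frac = 0.35) {
  # splice gaps used by any edge
  gaps <- list()
  for (nm in names(sg$edges)) {
    ch <- sg$edges[[nm]]$chain
    if (length(ch) < 2L) next
    for (i in seq_len(length(ch) - 1L)) {
      d <- ranges$end[ranges$index == ch[i]]
      a <- ranges$start[ranges$index == ch[i + 1L]]
      if (a > d) gaps[[length(gaps) + 1L]] <- c(d, a)
    }
  }
  if (!length(gaps)) return(0L)
  removed <- 0L
  for (nm in names(sg$edges)) {
    e <- sg$edges[[nm]]
    ch <- e$chain
    if (length(ch) < 2L || is.null(sg$edges[[nm]])) next
    st <- ranges$start[match(ch, ranges$index)]
    en <- ranges$end[match(ch, ranges$index)]
    for (g in gaps) {
      # does this chain cover [g1, g2) contiguously?
      inside <- which(st >= g[1] & en <= g[2])
      if (!length(inside)) next
      covers <- sum(en[inside] - st[inside]) == g[2] - g[1]
      contiguous <- all(diff(inside) == 1L) &&
        (length(inside) < 2L ||
           all(en[inside[-length(inside)]] == st[inside[-1L]]))
      flank_l <- any(en == g[1]); flank_r <- any(st == g[2])
      if (covers && contiguous && flank_l && flank_r) {
        intron_med <- region_stats(deltas, chrom, g[1], g[2])$median
        fl_l <- exon_cov(deltas, chrom,
                         st[which(en == g[1])[1L]], g[1])
        fl_r <- exon_cov(deltas, chrom, g[2],
                         en[which(st == g[2])[1L]])
        if (intron_med < ir_frac * min(fl_l, fl_r)) {
          saved <- sg$edges[[nm]]
          sg$edges[[nm]] <- NULL
          dangling <- any(vapply(.sg_nodes(sg), function(v)
            !length(.sg_in(sg, v)) || !length(.sg_out(sg, v)), logical(1)))
          if (dangling) sg$edges[[nm]] <- saved
          else removed <- removed + 1L
          break
        }
      }
    }
  }
  removed
}

#' Decompose residual flow into transcripts
#'
#' Iteratively selects the s-t path with the most exons (ties: larger
#' bottleneck flow, then lexicographically earlier chain), emits it with its
#' bottleneck flow, subtracts that flow, and repeats until no path with at
#' least one flow unit remains.
#'
#' @param sg simplified graph
#' @param guided_chains optional exon chains extracted first (guide mode)
#' @return list of list(chain, flow, guided)
#' @export
extract_transcripts <- function(sg, guided_chains = NULL) {
  out <- list()
  for (g in guided_chains %||% list()) {
    p <- .sg_find_spelling_path(sg, g)
    if (is.null(p)) next
    w <- min(vapply(p, function(nm) sg$edges[[nm]]$fl, numeric(1)))
    if (w < 1) next
    out[[length(out) + 1L]] <- list(chain = g, flow = w, guided = TRUE)
    for (nm in p) sg$edges[[nm]]$fl <- sg$edges[[nm]]$fl - w
  }
  repeat {
    best <- .sg_longest_path(sg)
    if (is.null(best) || best$bottleneck < 1) break
    ch <- best$chain
    if (!length(ch)) {
      # edge-less singleton path s -> v -> t
      vlab <- setdiff(unique(unlist(lapply(best$edges, function(nm)
        c(sg$edges[[nm]]$from, sg$edges[[nm]]$to)))), c(0L, -1L))
      ch <- sort(vlab)
    }
    if (!length(ch)) break
    out[[length(out) + 1L]] <- list(chain = ch, flow = best$bottleneck,
                                    guided = FALSE)
    for (nm in best$edges)
      sg$edges[[nm]]$fl <- sg$edges[[nm]]$fl - best$bottleneck
  }
  out
}

.sg_find_spelling_path <- function(sg, chain) {
  found <- NULL
  recurse <- function(v, got, acc) {
    if (!is.null(found)) return()
    if (v == -1L) {
      if (length(got) == length(chain) && all(got == chain)) found <<- acc
      return()
    }
    for (nm in names(sg$edges)) {
      e <- sg$edges[[nm]]
      if (e$from != v || e$fl < 1) next
      new <- if (length(e$chain)) merge_chains_at(got, e$chain) else got
      m <- length(new)
      if (m <= length(chain) && (m == 0L || all(new == chain[seq_len(m)])))
        recurse(e$to, new, c(acc, nm))
    }
  }
  recurse(0L, integer(0), character(0))
  found
}

# best s-t path by (number of exons, bottleneck, lexicographic chain) over
# edges with >= 1 unit of flow
.sg_longest_path <- function(sg) {
  act <- names(sg$edges)[vapply(sg$edges, function(e) e$fl >= 1, logical(1))]
  if (!length(act)) return(NULL)
  vs <- unique(c(0L, unlist(lapply(act, function(nm)
    c(sg$edges[[nm]]$from, sg$edges[[nm]]$to))), -1L))
  # topological order on the active subgraph
  indeg <- vapply(vs, function(v) sum(vapply(act, function(nm)
    sg$edges[[nm]]$to == v, logical(1))), integer(1))
  names(indeg) <- as.character(vs)
  order_ <- integer(0); ready <- sort(vs[indeg == 0L])
  while (length(ready)) {
    v <- ready[1L]; ready <- ready[-1L]
    order_ <- c(order_, v)
    for (nm in act) {
      if (sg$edges[[nm]]$from == v) {
        w <- sg$edges[[nm]]$to
        indeg[[as.character(w)]] <- indeg[[as.character(w)]] - 1L
        if (indeg[[as.character(w)]] == 0L)
          ready <- sort(c(ready, w))
      }
    }
  }
  best <- list()
  best[["0"]] <- list(nex = 0L, bneck = Inf, chain = integer(0),
                      edges = character(0))
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$nex != b$nex) return(a$nex > b$nex)
    if (a$bneck != b$bneck) return(a$bneck > b$bneck)
    chain_compare(a$chain, b$chain) < 0
  }
  for (v in order_) {
    cur <- best[[as.character(v)]]
    if (is.null(cur)) next
    for (nm in act) {
      e <- sg$edges[[nm]]
      if (e$from != v) next
      newch <- if (length(e$chain)) {
        if (length(cur$chain) &&
            cur$chain[length(cur$chain)] == e$chain[1L])
          merge_chains_at(cur$chain, e$chain)
        else c(cur$chain, e$chain)
      } else cur$chain
      cand <- list(nex = length(newch),
                   bneck = min(cur$bneck, e$fl),
                   chain = newch,
                   edges = c(cur$edges, nm))
      key <- as.character(e$to)
      if (better(cand, best[[key]])) best[[key]] <- cand
    }
  }
  res <- best[["-1"]]
  if (is.null(res)) return(NULL)
  list(chain = res$chain, bottleneck = res$bneck, edges = res$edges)
}

#' Trust-dependent abundance filter for guided loci
#'
#' In guided loci, unannotated transcripts below a trust-dependent fraction
#' of the locus's maximum abundance are dropped; guided transcripts always
#' pass.  The fraction is `0.05 * (trust/100) * (trust/20)`, capped at 1, so
#' trust 0 disables the filter and trust 100 requires 25% of the maximum.
#'
#' @param transcripts list from [extract_transcripts()]
#' @param trust trust level in [0, 100]
#' @export
guided_abundance_filter <- function(transcripts, trust) {
  if (!length(transcripts) || trust <= 0) return(transcripts)
  frac <- min(1, 0.05 * (trust / 100) * (trust / 20))
  mx <- max(vapply(transcripts, `[[`, numeric(1), "flow"))
  Filter(function(tx) tx$guided || tx$flow >= frac * mx, transcripts)
}

#' Rebalance flow after edge removals
#'
#' Rebuilds a flow network from the reduced graph (observed values = current
#' coverage labels) and re-runs the UTEC solve, updating edge flows.
#' @param sg simplified graph
#' @param node_cov named numeric exon-node coverage (by label)
#' @export
rebalance_flow <- function(sg, node_cov) {
  if (!length(sg$edges)) return(invisible(sg))
  arcs <- list()
  for (v in .sg_nodes(sg))
    arcs[[length(arcs) + 1L]] <- data.frame(
      id = sprintf("n%d", v), tail = sprintf("%d.in", v),
      head = sprintf("%d.out", v),
      cov = node_cov[[as.character(v)]] %||%
        sum(vapply(.sg_in(sg, v), function(nm) sg$edges[[nm]]$cov,
                   numeric(1))),
      w = 1, free = FALSE, stringsAsFactors = FALSE)
  for (nm in names(sg$edges)) {
    e <- sg$edges[[nm]]
    tail <- if (e$from == 0L) "s" else sprintf("%d.out", e$from)
    head <- if (e$to == -1L) "t" else sprintf("%d.in", e$to)
    free <- length(e$chain) == 0L && (e$from == 0L || e$to == -1L)
    arcs[[length(arcs) + 1L]] <- data.frame(
      id = nm, tail = tail, head = head, cov = if (free) 0 else e$cov,
      w = if (free) 0 else max(1L, length(e$chain) - 1L), free = free,
      stringsAsFactors = FALSE)
  }
  net <- structure(list(arcs = do.call(rbind, arcs)), class = "flow_net")
  sol <- solve_utec(net)
  for (nm in names(sg$edges))
    sg$edges[[nm]]$fl <- sol$flow[[nm]]
  # drop edges the rebalance zeroed out
  for (nm in names(sg$edges))
    if (sg$edges[[nm]]$fl < 0.5) sg$edges[[nm]] <- NULL
  .sg_contract(sg)
  invisible(sg)
}
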