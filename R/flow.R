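#' @name flow
#' @title Convex-cost flow denoising of the bin graph
#'
#' @description
#' Every graph node v is expanded into an arc v.in -> v.out carrying the
#' node's observed exon coverage, and every edge into an arc carrying the
#' bin coverage; source/sink arcs are free.  A flow f on this network is
#' scored by the deviation costs c_v(x) = x^2 / cov(v) on node arcs and
#' c_vu(x) = x^2 (|l(uv)|-1) / cov(uv) on edge arcs, x = |cov - f|; the
#' minimum-cost conserving flow is the denoised expression cover whose path
#' decomposition explains the observed coverage with minimal squared error
#' (the unannotated transcript expression cover).
NULL

#' Forward and reverse coverage overheads of the graph nodes
#'
#' b+ is the difference between a node's maximal base depth and the depth at
#' its rightmost base; b- the same for the leftmost base.  Ragged coverage at
#' exon boundaries (alignment noise at splice sites) shows up as positive
#' overheads and drives the pre-correction.
#'
#' @param nodes integer exon labels
#' @param ranges exon-range table of the locus
#' @param deltas coverage store
#' @param chrom chromosome
#' @return list per node label: list(bp, bm)
#' @export
#' @param read_span typical aligned read length, used to discount the
#'   counting-noise bias of the windowed maximum
node_overheads <- function(nodes, ranges, deltas, chrom, read_span = 100) {
  out <- list()
  w <- 25
  for (v in nodes) {
    r <- ranges[ranges$index == v, ]
    s <- region_stats_smoothed(deltas, chrom, r$start, r$end, w = w)
    # a windowed mean of depth c has standard error ~ sqrt(c r / (w + r));
    # the max over windows sits about two of those above the truth, so
    # overheads below that are indistinguishable from noise
    noise <- 2 * sqrt(max(s$max, 1) * read_span / (w + read_span))
    out[[as.character(v)]] <- list(bp = max(0, s$max - s$right - noise),
                                   bm = max(0, s$max - s$left - noise))
  }
  out
}

#' Pre-correct coverage for non-uniformity
#'
#' Forward pass in topological order: each node receives the overhead-adjusted
#' coverage of its predecessors, apportioned by relative edge coverage, minus
#' its own left overhead (floored at zero); edges forward their node's
#' correction proportionally.  The reverse pass is symmetric in reverse
#' topological order.  Final coverage is cov(x) + max(cov_f(x), cov_r(x)),
#' so perfectly uniform coverage (all overheads zero) is left unchanged and
#' no coverage ever decreases.
#'
#' @param bg bin-graph environment (s/t wired)
#' @param node_cov named numeric (by node label)
#' @param edge_cov named numeric (by edge name)
#' @param overheads from [node_overheads()]
#' @return list(node_cov, edge_cov) corrected
#' @export
precorrect_coverage <- function(bg, node_cov, edge_cov, overheads) {
  vs <- .bg_topo_nodes(bg)
  ed <- bin_graph_edges(bg)
  bp <- function(v) if (v %in% c(0L, -1L)) 0 else overheads[[as.character(v)]]$bp
  bm <- function(v) if (v %in% c(0L, -1L)) 0 else overheads[[as.character(v)]]$bm
  ecov <- function(nm) edge_cov[[nm]] %||% 0
  covf_n <- stats::setNames(numeric(length(vs)), as.character(vs))
  covf_e <- stats::setNames(numeric(nrow(ed)), ed$name)
  for (v in vs) {
    if (v == 0L) next
    inn <- ed$name[ed$to == v]
    den <- sum(vapply(inn, ecov, numeric(1)))
    acc <- 0
    if (den > 0) for (nm in inn) {
      u <- ed$from[ed$name == nm]
      acc <- acc + (covf_n[[as.character(u)]] + bp(u)) * ecov(nm) / den
    }
    covf_n[[as.character(v)]] <- max(0, acc - bm(v))
    outn <- ed$name[ed$from == v]
    deno <- sum(vapply(outn, ecov, numeric(1)))
    if (deno > 0) for (nm in outn)
      covf_e[[nm]] <- covf_n[[as.character(v)]] * ecov(nm) / deno
  }
  covr_n <- stats::setNames(numeric(length(vs)), as.character(vs))
  covr_e <- stats::setNames(numeric(nrow(ed)), ed$name)
  for (v in rev(vs)) {
    if (v == -1L) next
    outn <- ed$name[ed$from == v]
    den <- sum(vapply(outn, ecov, numeric(1)))
    acc <- 0
    if (den > 0) for (nm in outn) {
      u <- ed$to[ed$name == nm]
      acc <- acc + (covr_n[[as.character(u)]] + bm(u)) * ecov(nm) / den
    }
    covr_n[[as.character(v)]] <- max(0, acc - bp(v))
    inn <- ed$name[ed$to == v]
    deno <- sum(vapply(inn, ecov, numeric(1)))
    if (deno > 0) for (nm in inn)
      covr_e[[nm]] <- covr_n[[as.character(v)]] * ecov(nm) / deno
  }
  for (v in names(node_cov)) {
    if (!v %in% names(covf_n)) next  # coverage entry for a non-graph exon
    node_cov[[v]] <- node_cov[[v]] + max(covf_n[[v]], covr_n[[v]])
  }
  for (nm in names(edge_cov))
    edge_cov[[nm]] <- edge_cov[[nm]] + max(covf_e[[nm]] %||% 0,
                                           covr_e[[nm]] %||% 0)
  list(node_cov = node_cov, edge_cov = edge_cov)
}

.bg_topo_nodes <- function(bg) {
  ed <- bin_graph_edges(bg)
  vs <- unique(c(0L, ed$from, ed$to, -1L))
  indeg <- vapply(vs, function(v) sum(ed$to == v), integer(1))
  names(indeg) <- as.character(vs)
  out <- integer(0)
  ready <- vs[indeg == 0L]
  while (length(ready)) {
    ready <- sort(ready)
    v <- ready[1L]; ready <- ready[-1L]
    out <- c(out, v)
    for (w in ed$to[ed$from == v]) {
      key <- as.character(w)
      indeg[[key]] <- indeg[[key]] - 1L
      if (indeg[[key]] == 0L) ready <- c(ready, w)
    }
  }
  stopifnot(length(out) == length(vs))
  out
}

#' Guide-based coverage correction
#'
#' Each guide transcript is mapped to an s-t path of the graph (incompatible
#' guides are dropped).  Per exon node a bias factor b_v = sum(out edge cov) /
#' sum(in edge cov) captures local non-uniformity; each guide gets the largest
#' base coverage that, propagated along its path while multiplying the bias
#' factors, exceeds no observed node or edge coverage.  Guide coverages are
#' summed per feature; if the explained fraction F of total coverage reaches
#' `trust_threshold` the coverage is replaced by the guide sum, otherwise it
#' is moved toward the guide sum proportionally to F.
#'
#' @param bg bin-graph environment (s/t wired)
#' @param node_cov,edge_cov observed coverage
#' @param guides list of integer exon chains
#' @param trust_threshold fraction in [0, 1]
#' @return list(node_cov, edge_cov, F, n_used, n_dropped)
#' @export
guided_correct <- function(bg, node_cov, edge_cov, guides, trust_threshold) {
  paths <- .bg_all_paths(bg)
  spells <- vapply(paths, function(p) chain_key(.bg_spell(bg, p)),
                   character(1))
  ed <- bin_graph_edges(bg)
  bias <- stats::setNames(rep(1, length(bg$nodes)), as.character(bg$nodes))
  for (v in bg$nodes) {
    den <- sum(unlist(edge_cov[ed$name[ed$to == v]]), 0)
    num <- sum(unlist(edge_cov[ed$name[ed$from == v]]), 0)
    if (den > 0 && num > 0) bias[[as.character(v)]] <- num / den
  }
  gn <- stats::setNames(numeric(length(node_cov)), names(node_cov))
  ge <- stats::setNames(numeric(length(edge_cov)), names(edge_cov))
  n_used <- 0L; n_dropped <- 0L
  for (g in guides) {
    hit <- which(spells == chain_key(g))
    if (!length(hit)) { n_dropped <- n_dropped + 1L; next }
    p <- paths[[hit[1L]]]
    # factor at each feature along the path: product of biases at nodes passed
    fac <- 1
    caps <- numeric(0); feats <- list()
    for (nm in p) {
      e <- bg$edges[[nm]]
      if (e$from > 0L) {
        fac <- fac * bias[[as.character(e$from)]]
        caps <- c(caps, node_cov[[as.character(e$from)]] / fac)
        feats[[length(feats) + 1L]] <- list(kind = "node",
                                            id = as.character(e$from),
                                            fac = fac)
      }
      if (length(e$chain)) {
        caps <- c(caps, edge_cov[[nm]] / fac)
        feats[[length(feats) + 1L]] <- list(kind = "edge", id = nm, fac = fac)
      }
    }
    if (!length(caps)) { n_dropped <- n_dropped + 1L; next }
    gamma <- max(0, min(caps))
    for (ft in feats) {
      if (ft$kind == "node") gn[[ft$id]] <- gn[[ft$id]] + gamma * ft$fac
      else ge[[ft$id]] <- ge[[ft$id]] + gamma * ft$fac
    }
    n_used <- n_used + 1L
  }
  tot <- sum(unlist(node_cov)) + sum(unlist(edge_cov))
  expl <- sum(pmin(gn, unlist(node_cov))) + sum(pmin(ge, unlist(edge_cov)))
  F <- if (tot > 0) expl / tot else 0
  if (n_used > 0) {
    if (F >= trust_threshold && trust_threshold > 0) {
      for (v in names(node_cov)) node_cov[[v]] <- gn[[v]]
      for (nm in names(edge_cov)) edge_cov[[nm]] <- ge[[nm]]
    } else {
      for (v in names(node_cov))
        node_cov[[v]] <- node_cov[[v]] + F * max(0, gn[[v]] - node_cov[[v]])
      for (nm in names(edge_cov))
        edge_cov[[nm]] <- edge_cov[[nm]] + F * max(0, ge[[nm]] - edge_cov[[nm]])
    }
  }
  list(node_cov = node_cov, edge_cov = edge_cov, F = F, n_used = n_used,
       n_dropped = n_dropped)
}

#' Build the node-split flow network from a bin graph
#'
#' @param bg bin-graph environment (s/t wired)
#' @param node_cov,edge_cov (corrected) coverage
#' @return a `flow_net`: list(arcs = data.frame(id, tail, head, cov, w, free))
#' @export
build_flow_network <- function(bg, node_cov, edge_cov) {
  arcs <- list()
  for (v in sort(bg$nodes))
    arcs[[length(arcs) + 1L]] <- data.frame(
      id = sprintf("n%d", v), tail = sprintf("%d.in", v),
      head = sprintf("%d.out", v), cov = node_cov[[as.character(v)]],
      w = 1, free = FALSE, stringsAsFactors = FALSE)
  for (nm in names(bg$edges)) {
    e <- bg$edges[[nm]]
    tail <- if (e$from == 0L) "s" else sprintf("%d.out", e$from)
    head <- if (e$to == -1L) "t" else sprintf("%d.in", e$to)
    if (length(e$chain) == 0L)
      arcs[[length(arcs) + 1L]] <- data.frame(
        id = nm, tail = tail, head = head, cov = 0, w = 0, free = TRUE,
        stringsAsFactors = FALSE)
    else
      arcs[[length(arcs) + 1L]] <- data.frame(
        id = nm, tail = tail, head = head, cov = edge_cov[[nm]],
        w = max(1L, length(e$chain) - 1L), free = FALSE,
        stringsAsFactors = FALSE)
  }
  structure(list(arcs = do.call(rbind, arcs)), class = "flow_net")
}

# per-unit deviation cost of the zero-coverage arcs: locus median of the
# first marginal cost of covered arcs
.zero_cov_unit <- function(arcs) {
  co <- pmax(1, round(arcs$cov))
  unit <- arcs$w / co
  unit <- unit[!arcs$free & arcs$cov > 0]
  if (!length(unit)) return(1)
  stats::median(unit)
}

#' Exact UTEC cost of a flow assignment
#' @param net a `flow_net`
#' @param flow named numeric (by arc id)
#' @export
utec_cost <- function(net, flow) {
  a <- net$arcs
  z <- .zero_cov_unit(a)
  tot <- 0
  for (k in seq_len(nrow(a))) {
    if (a$free[k]) next
    co <- if (a$cov[k] > 0) max(1, round(a$cov[k])) else 0
    d <- abs(flow[[a$id[k]]] - co)
    tot <- tot + if (co == 0) z * d else a$w[k] * d^2 / co
  }
  tot
}

#' Solve the convex-cost minimum-cost flow (UTEC)
#'
#' Observed coverages are rounded to integers (at least 1 on covered arcs).
#' The convex deviation costs are linearized with unit breakpoints and solved
#' as a min-cost b-flow on the offset (deviation) network by successive
#' shortest paths, which yields an integral optimal flow.  The deviation range
#' starts small and doubles whenever an artificial bound is hit, so the
#' solution is exact for the final range (at most 4x the observed value,
#' the point beyond which a deviation always costs more than rebuilding the
#' locus from zero).
#'
#' @param net a `flow_net`
#' @return list(flow = named numeric per arc id, objective)
#' @export
solve_utec <- function(net) {
  a <- net$arcs
  co <- ifelse(a$free, 0, ifelse(a$cov > 0, pmax(1, round(a$cov)), 0))
  z <- .zero_cov_unit(a)
  cap_nat <- pmax(4L * co, 48L)
  K <- 16L
  repeat {
    res <- .ssp_offset(a, co, z, pmin(K, cap_nat), pmin(K, co))
    # artificial saturation: a deviation at exactly the imposed bound that is
    # below the natural bound
    sat_f <- any(res$dev_f >= pmin(K, cap_nat) - 1e-9 & K < cap_nat)
    sat_r <- any(res$dev_r >= pmin(K, co) - 1e-9 & K < co)
    if ((!sat_f && !sat_r) || K >= max(cap_nat)) break
    K <- K * 2L
  }
  flow <- stats::setNames(co + res$dev_f - res$dev_r, a$id)
  list(flow = flow, objective = utec_cost(net, flow))
}

# successive-shortest-path min-cost b-flow on the deviation network
.ssp_offset <- function(a, co, z, cap_f, cap_r) {
  verts <- unique(c(a$tail, a$head, "s", "t"))
  # circulation arc t -> s (free, both directions)
  tails <- character(0); heads <- character(0)
  caps <- numeric(0); costs <- numeric(0); of <- integer(0); dir <- integer(0)
  nA <- nrow(a)
  for (k in seq_len(nA)) {
    if (a$free[k]) {
      tails <- c(tails, a$tail[k]); heads <- c(heads, a$head[k])
      caps <- c(caps, Inf); costs <- c(costs, 0); of <- c(of, k)
      dir <- c(dir, 1L)
      next
    }
    cK <- co[k]
    # forward deviations (flow above observed), unit breakpoints
    Df <- cap_f[k]
    if (Df > 0) {
      ks <- seq_len(Df)
      mc <- if (cK == 0) rep(z, Df) else a$w[k] * (2 * ks - 1) / cK
      tails <- c(tails, rep(a$tail[k], Df))
      heads <- c(heads, rep(a$head[k], Df))
      caps <- c(caps, rep(1, Df)); costs <- c(costs, mc)
      of <- c(of, rep(k, Df)); dir <- c(dir, rep(1L, Df))
    }
    # reverse deviations (flow below observed)
    Dr <- cap_r[k]
    if (Dr > 0) {
      ks <- seq_len(Dr)
      mc <- a$w[k] * (2 * ks - 1) / cK
      tails <- c(tails, rep(a$head[k], Dr))
      heads <- c(heads, rep(a$tail[k], Dr))
      caps <- c(caps, rep(1, Dr)); costs <- c(costs, mc)
      of <- c(of, rep(k, Dr)); dir <- c(dir, rep(-1L, Dr))
    }
  }
  # t -> s circulation
  tails <- c(tails, "t", "s"); heads <- c(heads, "s", "t")
  caps <- c(caps, Inf, Inf); costs <- c(costs, 0, 0)
  of <- c(of, NA, NA); dir <- c(dir, 0L, 0L)
  # vertex imbalances: net deviation inflow required at x
  b <- stats::setNames(numeric(length(verts)), verts)
  for (k in seq_len(nA)) {
    b[[a$tail[k]]] <- b[[a$tail[k]]] + co[k]
    b[[a$head[k]]] <- b[[a$head[k]]] - co[k]
  }
  SS <- "..SS"; TT <- "..TT"
  for (v in verts) {
    if (b[[v]] > 0) {
      # vertex needs net deviation inflow: drain it to TT so the inflow is
      # forced through deviation arcs
      tails <- c(tails, v); heads <- c(heads, TT)
      caps <- c(caps, b[[v]]); costs <- c(costs, 0)
      of <- c(of, NA); dir <- c(dir, 0L)
    } else if (b[[v]] < 0) {
      tails <- c(tails, SS); heads <- c(heads, v)
      caps <- c(caps, -b[[v]]); costs <- c(costs, 0)
      of <- c(of, NA); dir <- c(dir, 0L)
    }
  }
  res <- .mcmf(c(verts, SS, TT), tails, heads, caps, costs, SS, TT)
  dev_f <- numeric(nA); dev_r <- numeric(nA)
  fl <- res$flow
  for (i in seq_along(fl)) {
    if (!is.na(of[i]) && fl[i] > 0) {
      if (dir[i] == 1L) dev_f[of[i]] <- dev_f[of[i]] + fl[i]
      else if (dir[i] == -1L) dev_r[of[i]] <- dev_r[of[i]] + fl[i]
    }
  }
  list(dev_f = dev_f, dev_r = dev_r)
}

# generic min-cost max-flow, successive shortest paths with Bellman-Ford
# (residual arcs may have negative cost)
.mcmf <- function(verts, tails, heads, caps, costs, S, T_) {
  vid <- stats::setNames(seq_along(verts), verts)
  m <- length(tails)
  # residual arc arrays: forward arcs 1..m, backward arcs m+1..2m
  rt <- c(vid[tails], vid[heads])
  rh <- c(vid[heads], vid[tails])
  rcap <- c(caps, numeric(m))
  rcost <- c(costs, -costs)
  partner <- c(m + seq_len(m), seq_len(m))
  nV <- length(verts)
  s <- vid[[S]]; t <- vid[[T_]]
  flow <- numeric(m)
  repeat {
    # Bellman-Ford, vectorized over arcs
    dist <- rep(Inf, nV); dist[s] <- 0
    pre <- rep(NA_integer_, nV)
    act <- which(rcap > 1e-9)
    for (it in seq_len(nV)) {
      nd <- dist[rt[act]] + rcost[act]
      improve <- nd < dist[rh[act]] - 1e-9
      if (!any(improve)) break
      ii <- act[improve]
      # resolve multiple updates to one head: keep the best per head
      o <- order(rh[ii], nd[improve])
      ii <- ii[o]; ndo <- nd[improve][o]
      first <- !duplicated(rh[ii])
      upd <- ii[first]
      better <- ndo[first] < dist[rh[upd]] - 1e-9
      upd <- upd[better]
      if (!length(upd)) break
      dist[rh[upd]] <- (dist[rt[upd]] + rcost[upd])
      pre[rh[upd]] <- upd
    }
    if (!is.finite(dist[t])) break
    # reconstruct path, find bottleneck
    path <- integer(0); v <- t
    while (v != s) {
      e <- pre[v]
      path <- c(e, path)
      v <- rt[e]
    }
    push <- min(rcap[path])
    rcap[path] <- rcap[path] - push
    rcap[partner[path]] <- rcap[partner[path]] + push
    fwd <- path[path <= m]
    bwd <- path[path > m] - m
    flow[fwd] <- flow[fwd] + push
    flow[bwd] <- flow[bwd] - push
  }
  list(flow = flow)
}

#' Brute-force UTEC optimum by path-flow enumeration
#'
#' Independent oracle: enumerates every integral conserving s-t flow as a
#' combination of simple-path flows and evaluates the exact convex cost.
#' Only feasible for tiny networks.
#'
#' @param net a `flow_net`
#' @param max_flow cap on each path flow (default: twice the largest rounded
#'   coverage)
#' @return list(objective, flow)
#' @export
utec_brute_objective <- function(net, max_flow = NULL) {
  a <- net$arcs
  co <- ifelse(a$free, 0, ifelse(a$cov > 0, pmax(1, round(a$cov)), 0))
  if (is.null(max_flow)) max_flow <- 2L * max(co, 1L)
  # all simple s-t paths over arcs
  paths <- list()
  recurse <- function(v, used) {
    if (v == "t") { paths[[length(paths) + 1L]] <<- used; return() }
    for (k in which(a$tail == v)) recurse(a$head[k], c(used, k))
  }
  recurse("s", integer(0))
  np <- length(paths)
  stopifnot(np >= 1L, (max_flow + 1)^np <= 2e6)
  grid <- as.matrix(do.call(expand.grid, rep(list(0:max_flow), np)))
  inc <- matrix(0, nrow = np, ncol = nrow(a))
  for (p in seq_len(np)) inc[p, paths[[p]]] <- 1
  flows <- grid %*% inc
  z <- .zero_cov_unit(a)
  cost <- numeric(nrow(flows))
  for (k in seq_len(nrow(a))) {
    if (a$free[k]) next
    d <- abs(flows[, k] - co[k])
    cost <- cost + if (co[k] == 0) z * d else a$w[k] * d^2 / co[k]
  }
  r <- which.min(cost)
  list(objective = cost[r], flow = stats::setNames(flows[r, ], a$id))
}
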