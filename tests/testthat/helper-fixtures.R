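# Shared helpers: in-memory fixture builders and independent oracles.

# minimal flow-net constructor
mknet <- function(arcs) structure(list(arcs = arcs), class = "flow_net")

# random small flow network (<= 6 costed arcs) in one of three shapes
rand_flow_net <- function() {
  topo <- sample(3, 1)
  if (topo == 1) {          # chain s -> a -> b -> t
    cov <- sample(1:20, 3, replace = TRUE)
    arcs <- data.frame(
      id = c("na", "nb", "eab", "es", "et"),
      tail = c("a.in", "b.in", "a.out", "s", "b.out"),
      head = c("a.out", "b.out", "b.in", "a.in", "t"),
      cov = c(cov, 0, 0), w = c(1, 1, sample(1:3, 1), 0, 0),
      free = c(FALSE, FALSE, FALSE, TRUE, TRUE), stringsAsFactors = FALSE)
  } else if (topo == 2) {   # split a -> {b, c}
    cov <- sample(1:20, 5, replace = TRUE)
    arcs <- data.frame(
      id = c("na", "nb", "nc", "eab", "eac", "es", "ebt", "ect"),
      tail = c("a.in", "b.in", "c.in", "a.out", "a.out", "s", "b.out",
               "c.out"),
      head = c("a.out", "b.out", "c.out", "b.in", "c.in", "a.in", "t", "t"),
      cov = c(cov, 0, 0, 0), w = c(1, 1, 1, 1, 1, 0, 0, 0),
      free = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE)
  } else {                  # merge {a, b} -> c
    cov <- sample(1:20, 5, replace = TRUE)
    arcs <- data.frame(
      id = c("na", "nb", "nc", "eac", "ebc", "esa", "esb", "ect"),
      tail = c("a.in", "b.in", "c.in", "a.out", "b.out", "s", "s", "c.out"),
      head = c("a.out", "b.out", "c.out", "c.in", "c.in", "a.in", "b.in",
               "t"),
      cov = c(cov, 0, 0, 0), w = c(1, 1, 1, 1, 1, 0, 0, 0),
      free = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE)
  }
  mknet(arcs)
}

# build a bin object directly (bases synthesized from the count); bases
# vectors share one generous length so bins from one locus always combine
mkbin <- function(chain, count = 1, n_exons = max(chain)) {
  bases <- numeric(max(n_exons, 12L))
  bases[chain] <- count * 80
  list(chain = as.integer(chain), count = count, bases = bases,
       left_starts = table(integer(0)), right_ends = table(integer(0)))
}

# random locus expressed directly as read bins: isoform chains over
# n_exons exons plus read-like windows of each chain
random_bin_locus <- function(n_exons = NULL, n_iso = NULL) {
  if (is.null(n_exons)) n_exons <- sample(3:8, 1)
  if (is.null(n_iso)) n_iso <- sample(1:4, 1)
  interior <- if (n_exons > 2L) 2:(n_exons - 1L) else integer(0)
  seen <- character(0); chains <- list()
  guard <- 0L
  while (length(chains) < n_iso && guard < 100L) {
    guard <- guard + 1L
    ch <- c(1L, interior[runif(length(interior)) < 0.6], n_exons)
    key <- paste(ch, collapse = ",")
    if (!key %in% seen) { seen <- c(seen, key); chains <- c(chains, list(ch)) }
  }
  binkeys <- new.env(parent = emptyenv())
  for (ch in chains) {
    n <- length(ch)
    for (w in 1:min(3, n)) for (s in seq_len(n - w + 1L)) {
      k <- paste(ch[s:(s + w - 1L)], collapse = ",")
      binkeys[[k]] <- TRUE
    }
    binkeys[[paste(ch, collapse = ",")]] <- TRUE
  }
  bins <- lapply(sort(ls(binkeys)), function(k)
    mkbin(as.integer(strsplit(k, ",")[[1]]), count = sample(3:10, 1),
          n_exons = n_exons))
  list(chains = chains, bins = bins, n_exons = n_exons)
}

# graph construction pipeline from a bin list
graph_of_bins <- function(bins) {
  am <- merge_unique_chains(strip_and_reduce(build_aux_edges(bins)))
  bg <- build_bin_graph(am)
  binflow:::.bg_finalize_st(bg)
  list(am = am, bg = bg)
}

# brute-force transitive reduction oracle (O(N^3) reachability)
brute_transitive_reduction <- function(edges, n) {
  if (!nrow(edges)) return(edges)
  reach <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(edges))) reach[edges$from[k], edges$to[k]] <- TRUE
  path2 <- matrix(FALSE, n, n)  # reachability via paths of length >= 2
  cur <- reach
  for (step in seq_len(n)) {
    cur <- (cur %*% reach) > 0
    path2 <- path2 | cur
  }
  keep <- !path2[cbind(edges$from, edges$to)]
  edges[keep, , drop = FALSE]
}

# brute-force two-step phasing objectives on an integer grid
brute_resolve <- function(fl, ev, lb = NULL, max_x = 12L) {
  m <- nrow(ev); flv <- unlist(fl)
  grids <- as.matrix(do.call(expand.grid, rep(list(0:max_x), m)))
  ok <- rep(TRUE, nrow(grids))
  edges <- unique(c(ev$e, ev$ep))
  for (e in edges) {
    idx <- which(ev$e == e | ev$ep == e)
    ok <- ok & rowSums(grids[, idx, drop = FALSE]) <= flv[[e]]
  }
  if (!is.null(lb))
    for (j in seq_len(m)) ok <- ok & grids[, j] >= lb[j]
  g <- grids[ok, , drop = FALSE]
  if (!nrow(g)) return(NULL)
  obj1 <- min(rowSums(abs(sweep(g, 2, ev$n))))
  ytot <- numeric(nrow(g))
  for (e in edges) {
    idx <- which(ev$e == e | ev$ep == e)
    ytot <- ytot + pmax(0, flv[[e]] - rowSums(g[, idx, drop = FALSE]))
  }
  list(obj1 = obj1, obj2 = min(ytot))
}

# build a simplified-graph environment directly from an edge table
mksg <- function(edges) {
  sg <- binflow:::.sg_new()
  for (e in edges)
    binflow:::.sg_add(sg, e$from, e$to, e$chain, e$fl,
                      cov = e$cov %||% e$fl, evid = isTRUE(e$evid))
  sg
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# assemble one sim_locus end to end; returns transcripts near the locus
assemble_locus_fixture <- function(loc, seed = 1, ...) {
  recs <- sample_reads(loc, seed = seed, ...)
  sam <- tempfile(fileext = ".sam")
  emit_sam(recs, sam)
  run_pipeline(assembly_config(sam))
}
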