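#' Assembly configuration
#'
#' @param bam input SAM/BAM path (coordinate sorted)
#' @param out output GTF path (NULL: no file written)
#' @param guide optional guide annotation (GTF)
#' @param trust guide trust level in [0, 100]
#' @param strandedness "auto" uses the XS strand tag of spliced reads
#' @param min_edge_frac flow fraction below which unevidenced edges at
#'   evidenced nodes are removed (default 0.30)
#' @param no_evidence_frac the same threshold at nodes without any evidence
#'   (default 0.75)
#' @param ir_frac intron-retention coverage significance threshold
#' @param bandwidth splice-site clustering bandwidth (bp)
#' @param min_intron minimum intron length (bp)
#' @param min_tx_cov minimum transcript abundance; 0 disables the filter
#'   (the default: edge filtering already handles weak noise)
#' @param single_exon report single-exon transcripts (default TRUE)
#' @param seed RNG seed recorded in the run (the pipeline itself is
#'   deterministic; the seed namespaces derived randomness)
#' @param verbose emit per-locus progress to stderr
#' @export
assembly_config <- function(bam, out = NULL, guide = NULL, trust = 50,
                            strandedness = c("auto", "fr", "rf", "none"),
                            min_edge_frac = 0.30, no_evidence_frac = 0.75,
                            ir_frac = 0.35, bandwidth = 3L, min_intron = 30L,
                            min_tx_cov = 0, single_exon = TRUE, seed = 1L,
                            verbose = FALSE) {
  strandedness <- match.arg(strandedness)
  stopifnot(min_edge_frac >= 0, min_edge_frac <= 1,
            no_evidence_frac >= 0, no_evidence_frac <= 1,
            ir_frac >= 0, ir_frac <= 1,
            trust >= 0, trust <= 100,
            bandwidth >= 0, min_intron >= 1)
  structure(list(bam = bam, out = out, guide = guide, trust = trust,
                 strandedness = strandedness, min_edge_frac = min_edge_frac,
                 no_evidence_frac = no_evidence_frac, ir_frac = ir_frac,
                 bandwidth = as.integer(bandwidth),
                 min_intron = as.integer(min_intron),
                 min_tx_cov = min_tx_cov, single_exon = single_exon,
                 seed = as.integer(seed), verbose = verbose),
            class = "assembly_config")
}

#' Run the full assembly pipeline
#'
#' Per locus and strand: exon binning, auxiliary graph, bin graph, coverage
#' pre-correction (and guide correction when an annotation is given), UTEC
#' flow solve, simplification, evidence-based LP resolution, noise filters,
#' and longest-path flow decomposition.  Output is deterministic for a fixed
#' input and configuration.
#'
#' @param config an [assembly_config()]
#' @return list with `transcripts` (list of assembled transcript objects),
#'   `log` (per-locus data.frame), `n_templates`, and `gtf` (output path or
#'   NULL)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "assembly_config"))
  # pin the RNG: the LP solver may consult it on degenerate vertices, and the
  # output contract is byte-identical results for a fixed input + seed
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  say <- function(...) if (config$verbose) message(sprintf(...))
  st <- stream_fragments(config$bam, min_intron = config$min_intron)
  cl <- cluster_splice_sites(st$junctions, bandwidth = config$bandwidth)
  loci <- partition_loci(st$deltas, cl$junctions)
  guides <- if (!is.null(config$guide)) read_gtf_transcripts(config$guide)
            else list()
  transcripts <- list()
  log <- list()
  for (li in seq_len(nrow(loci))) {
    chrom <- loci$chrom[li]; lstart <- loci$start[li]; lend <- loci$end[li]
    jloc <- cl$junctions[cl$junctions$chrom == chrom &
                           cl$junctions$acceptor > lstart &
                           cl$junctions$donor < lend, , drop = FALSE]
    strands <- sort(unique(jloc$strand[jloc$strand %in% c("+", "-")]))
    if (!length(strands)) strands <- "."
    # fragments whose blocks touch the locus
    hit_ids <- unique(st$blocks$id[st$blocks$chrom == chrom &
                                     st$blocks$end > lstart &
                                     st$blocks$start < lend])
    for (sd in strands) {
      res <- .assemble_locus(st, cl, hit_ids, chrom, lstart, lend, sd,
                             guides, config, say)
      if (!is.null(res)) {
        for (tx in res$transcripts) {
          tx$gene_id <- sprintf("BINFLOW.%d", li)
          tx$transcript_id <- sprintf("BINFLOW.%d.%d%s", li,
                                      length(transcripts) + 1L,
                                      if (sd == "-") "m" else "")
          tx$fpkm <- tx$abundance * 1e9 /
            (sum(tx$exons$end - tx$exons$start) * max(1L, st$n_templates))
          transcripts[[length(transcripts) + 1L]] <- tx
        }
        log[[length(log) + 1L]] <-
          cbind(data.frame(chrom = chrom, start = lstart, end = lend,
                           strand = sd), res$stats)
      }
    }
  }
  if (!config$single_exon)
    transcripts <- Filter(function(tx) nrow(tx$exons) > 1L, transcripts)
  if (config$min_tx_cov > 0)
    transcripts <- Filter(function(tx) tx$abundance >= config$min_tx_cov,
                          transcripts)
  if (!is.null(config$out)) write_gtf(transcripts, config$out)
  list(transcripts = transcripts,
       log = if (length(log)) do.call(rbind, log) else NULL,
       n_templates = st$n_templates, gtf = config$out)
}

# per-base coverage of every bin-graph edge.  The edge's depth is estimated
# from the features that belong to it alone, all on the same local-depth
# scale: the crossing-read count of each junction unique to the edge (the
# standard depth estimator at a splice site; a naive bases/length average
# would halve it, since coverage around a junction from crossing reads alone
# is triangular) and the mean depth of each interior exon unique to the
# edge.  When no unique feature exists the aligned bases of the owning bins
# averaged over the chain serve as fallback.
.edge_coverage <- function(bg, ranges, junction_reads = NULL, deltas = NULL,
                           chrom = NULL) {
  glen <- function(ch) sum(ranges$end[match(ch, ranges$index)] -
                             ranges$start[match(ch, ranges$index)])
  gap_after <- function(a, b)
    ranges$start[match(b, ranges$index)] > ranges$end[match(a, ranges$index)]
  # sequenced crossing count of the junction between exons a and b
  jcount_of <- function(a, b) {
    key <- paste0(ranges$end[match(a, ranges$index)], ":",
                  ranges$start[match(b, ranges$index)])
    junction_reads[[key]] %||% 0
  }
  # how many edges contain each junction / each interior exon
  jedges <- new.env(parent = emptyenv())
  xedges <- new.env(parent = emptyenv())
  for (nm in names(bg$edges)) {
    ch <- bg$edges[[nm]]$chain
    if (length(ch) < 2L) next
    for (i in seq_len(length(ch) - 1L)) {
      if (gap_after(ch[i], ch[i + 1L])) {
        key <- paste0(ch[i], "-", ch[i + 1L])
        jedges[[key]] <- c(jedges[[key]], nm)
      }
    }
    for (x in ch[-c(1L, length(ch))]) {
      key <- as.character(x)
      xedges[[key]] <- c(xedges[[key]], nm)
    }
  }
  out <- list()
  for (nm in names(bg$edges)) {
    e <- bg$edges[[nm]]
    ch <- e$chain
    if (!length(ch)) { out[[nm]] <- 0; next }
    ests <- numeric(0)
    if (length(ch) > 1L) {
      for (i in seq_len(length(ch) - 1L)) {
        if (gap_after(ch[i], ch[i + 1L])) {
          key <- paste0(ch[i], "-", ch[i + 1L])
          if (length(jedges[[key]]) == 1L)
            ests <- c(ests, jcount_of(ch[i], ch[i + 1L]))
        }
      }
      if (!is.null(deltas)) {
        for (x in ch[-c(1L, length(ch))]) {
          if (x %in% bg$nodes) next
          if (length(xedges[[as.character(x)]]) > 1L) next
          r <- ranges[ranges$index == x, ]
          ests <- c(ests, exon_cov(deltas, chrom, r$start, r$end))
        }
      }
    }
    if (length(ests)) { out[[nm]] <- mean(ests); next }
    tot <- 0
    for (o in e$owners) {
      b <- bg$bins[[o]]
      tot <- tot + sum(b$bases[e$chain])
    }
    out[[nm]] <- tot / glen(ch)
  }
  out
}

.assemble_locus <- function(st, cl, hit_ids, chrom, lstart, lend, sd, guides,
                            config, say) {
  fr <- st$fragments[st$fragments$id %in% hit_ids, , drop = FALSE]
  if (!nrow(fr)) return(NULL)
  usable <- !fr$spliced | fr$strand == sd | fr$strand == "*" | sd == "."
  fr <- fr[usable, , drop = FALSE]
  if (!nrow(fr)) return(NULL)
  bl <- st$blocks[st$blocks$id %in% fr$id, , drop = FALSE]
  deltas <- coverage_deltas(bl)
  jn <- cl$junctions[cl$junctions$chrom == chrom &
                       cl$junctions$acceptor > lstart &
                       cl$junctions$donor < lend &
                       (cl$junctions$strand == sd |
                          cl$junctions$strand == "*" | sd == "."), ,
                     drop = FALSE]
  er <- withCallingHandlers(
    build_exon_ranges(jn, deltas, chrom, lstart, lend),
    warning = function(w) { say("locus %s:%d-%d: %s", chrom, lstart, lend,
                                conditionMessage(w))
                            invokeRestart("muffleWarning") })
  if (!nrow(er$ranges)) return(NULL)
  bb <- build_locus_bins(fr$id, fr$qname, fr$strand, fr$spliced, bl,
                         er$ranges, er$junctions, cl$map, sd)
  if (!length(bb$bins)) return(NULL)
  aux <- build_aux_edges(bb$bins)
  am <- merge_unique_chains(strip_and_reduce(aux))
  bg <- withCallingHandlers(
    build_bin_graph(am),
    warning = function(w) { say("locus %s:%d-%d: %s", chrom, lstart, lend,
                                conditionMessage(w))
                            invokeRestart("muffleWarning") })
  .bg_finalize_st(bg)
  node_cov <- list()
  for (v in sort(bg$nodes)) {
    r <- er$ranges[er$ranges$index == v, ]
    node_cov[[as.character(v)]] <- exon_cov(deltas, chrom, r$start, r$end)
  }
  edge_cov <- .edge_coverage(bg, er$ranges, bb$junction_reads, deltas, chrom)
  oh <- node_overheads(sort(bg$nodes), er$ranges, deltas, chrom)
  cc <- precorrect_coverage(bg, node_cov, edge_cov, oh)
  guided_chains <- list()
  if (length(guides)) {
    for (g in guides) {
      if (g$chrom != chrom || (sd != "." && g$strand != sd)) next
      if (min(g$exons$start) >= lend || max(g$exons$end) <= lstart) next
      ch <- .guide_chain(g, er$ranges)
      if (!is.null(ch)) guided_chains[[length(guided_chains) + 1L]] <- ch
      else say("locus %s:%d-%d: guide %s incompatible; dropped",
               chrom, lstart, lend, g$transcript_id)
    }
    if (length(guided_chains)) {
      gc <- guided_correct(bg, cc$node_cov, cc$edge_cov, guided_chains,
                           config$trust / 100)
      cc$node_cov <- gc$node_cov; cc$edge_cov <- gc$edge_cov
    }
  }
  net <- build_flow_network(bg, cc$node_cov, cc$edge_cov)
  sol <- solve_utec(net)
  sg <- simplify_graph(bg, sol$flow, unlist(cc$edge_cov))
  node_cov_v <- unlist(cc$node_cov)
  evs <- collect_evidence(sg, bb$bins, bb$links)
  n_rm <- filter_edges(sg, evs, config$min_edge_frac, config$no_evidence_frac)
  if (n_rm > 0) rebalance_flow(sg, node_cov_v)
  n_ir <- filter_intron_retention(sg, er$ranges, deltas, chrom,
                                  config$ir_frac)
  if (n_ir > 0) rebalance_flow(sg, node_cov_v)
  unres <- unresolved_nodes(sg, er$ranges)
  resolve_graph(sg, bb$bins, bb$links)
  evs2 <- collect_evidence(sg, bb$bins, bb$links)
  filter_edges(sg, evs2, config$min_edge_frac, config$no_evidence_frac)
  txs <- extract_transcripts(sg, guided_chains = guided_chains)
  if (length(guided_chains)) txs <- guided_abundance_filter(txs, config$trust)
  out <- list()
  for (tx in txs) {
    ex <- .chain_to_exons(tx$chain, er$ranges)
    out[[length(out) + 1L]] <- list(chrom = chrom, strand = sd, exons = ex,
                                    abundance = tx$flow,
                                    guided = isTRUE(tx$guided))
  }
  say("locus %s:%d-%d[%s]: %d bins, %d nodes, %d unresolved, %d transcripts",
      chrom, lstart, lend, sd, length(bb$bins), length(bg$nodes),
      nrow(unres), length(out))
  list(transcripts = out,
       stats = data.frame(n_bins = length(bb$bins),
                          n_links = length(bb$links),
                          n_rejected = bb$rejected,
                          n_nodes = length(bg$nodes),
                          n_exons = nrow(er$ranges),
                          n_unresolved = nrow(unres),
                          n_transcripts = length(out)))
}

# chain of exon-range indices -> genomic exons (adjacent ranges merged)
.chain_to_exons <- function(chain, ranges) {
  st <- ranges$start[match(chain, ranges$index)]
  en <- ranges$end[match(chain, ranges$index)]
  keep <- c(TRUE, st[-1L] != en[-length(en)])
  grp <- cumsum(keep)
  data.frame(start = as.integer(tapply(st, grp, min)),
             end = as.integer(tapply(en, grp, max)),
             row.names = NULL)
}

#' Parse command-line arguments for the assembler script
#'
#' Thin optparse wrapper used by `inst/scripts/assemble.R`; exposed so the
#' interface is testable.
#' @param args character vector of command-line arguments
#' @return an [assembly_config()]
#' @export
parse_assemble_args <- function(args) {
  if (!requireNamespace("optparse", quietly = TRUE))
    stop("the command line interface needs the optparse package")
  spec <- list(
    optparse::make_option("--bam", type = "character"),
    optparse::make_option("--guide", type = "character", default = NULL),
    optparse::make_option("--trust", type = "double", default = 50),
    optparse::make_option("--strandedness", type = "character",
                          default = "auto"),
    optparse::make_option("--min-edge-frac", type = "double", default = 0.30,
                          dest = "min_edge_frac"),
    optparse::make_option("--no-evidence-frac", type = "double",
                          default = 0.75, dest = "no_evidence_frac"),
    optparse::make_option("--ir-frac", type = "double", default = 0.35,
                          dest = "ir_frac"),
    optparse::make_option("--bandwidth", type = "integer", default = 3L),
    optparse::make_option("--min-intron", type = "integer", default = 30L,
                          dest = "min_intron"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option(c("-o", "--out"), type = "character"),
    optparse::make_option("--verbose", action = "store_true",
                          default = FALSE))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                              args = args)
  if (is.null(opt$bam) || is.null(opt$out))
    stop("--bam and -o/--out are required")
  assembly_config(bam = opt$bam, out = opt$out, guide = opt$guide,
                  trust = opt$trust, strandedness = opt$strandedness,
                  min_edge_frac = opt$min_edge_frac,
                  no_evidence_frac = opt$no_evidence_frac,
                  ir_frac = opt$ir_frac, bandwidth = opt$bandwidth,
                  min_intron = opt$min_intron, seed = opt$seed,
                  verbose = opt$verbose)
}
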