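#' Write transcripts as GTF2.2
#'
#' One `transcript` feature plus one `exon` feature per exon, 1-based closed
#' coordinates, attributes `gene_id`, `transcript_id`, `FPKM` and `cov`, in
#' deterministic order (chromosome, start, transcript id).  An empty
#' transcript set produces a header-only file.
#'
#' @param transcripts list; each element has chrom, strand, exons
#'   (data.frame start/end, 0-based half-open), abundance, fpkm, gene_id,
#'   transcript_id, guided
#' @param path output file
#' @export
write_gtf <- function(transcripts, path) {
  hdr <- c("##format: gtf", "##source: binflow")
  if (!length(transcripts)) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  starts <- vapply(transcripts, function(tx) min(tx$exons$start), numeric(1))
  chroms <- vapply(transcripts, function(tx) tx$chrom, character(1))
  tids <- vapply(transcripts, function(tx) tx$transcript_id, character(1))
  o <- order(chroms, starts, tids)
  lines <- character(0)
  for (tx in transcripts[o]) {
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    fpkm <- if (is.null(tx$fpkm) || is.na(tx$fpkm)) "" else
      sprintf(" FPKM \"%.4f\";", tx$fpkm)
    attr0 <- sprintf("gene_id \"%s\"; transcript_id \"%s\";%s cov \"%.4f\";%s",
                     tx$gene_id, tx$transcript_id, fpkm, tx$abundance,
                     if (isTRUE(tx$guided)) " reference_id \"guided\";" else "")
    lines <- c(lines, sprintf("%s\tbinflow\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              tx$chrom, min(ex$start) + 1L, max(ex$end),
                              tx$strand, attr0))
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf(
        "%s\tbinflow\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
        tx$chrom, ex$start[i] + 1L, ex$end[i], tx$strand, attr0, i))
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read transcripts from a GTF/GFF annotation (e.g. assembly guides)
#'
#' @param path GTF file
#' @return list per transcript: chrom, strand, exons (0-based half-open),
#'   transcript_id, gene_id
#' @export
read_gtf_transcripts <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) return(list())
  tid <- as.character(gr$transcript_id)
  out <- list()
  for (id in unique(tid)) {
    sub <- gr[tid == id]
    sub <- sub[order(GenomicRanges::start(sub))]
    out[[length(out) + 1L]] <- list(
      chrom = as.character(GenomicRanges::seqnames(sub))[1L],
      strand = as.character(GenomicRanges::strand(sub))[1L],
      exons = data.frame(start = GenomicRanges::start(sub) - 1L,
                         end = GenomicRanges::end(sub)),
      transcript_id = id,
      gene_id = if (!is.null(sub$gene_id)) as.character(sub$gene_id)[1L]
                else NA_character_)
  }
  out
}

# match a guide transcript's exons onto the locus exon ranges; NULL when the
# guide's boundaries or splices disagree with the graph's ranges
.guide_chain <- function(guide, ranges) {
  chain <- integer(0)
  n_ex <- nrow(guide$exons)
  for (i in seq_len(n_ex)) {
    gs <- guide$exons$start[i]; ge <- guide$exons$end[i]
    rs <- which(ranges$start >= gs & ranges$end <= ge)
    if (!length(rs)) return(NULL)
    rs <- rs[order(ranges$start[rs])]
    if (ranges$start[rs[1L]] != gs || ranges$end[rs[length(rs)]] != ge)
      return(NULL)
    if (length(rs) > 1L &&
        !all(ranges$end[rs[-length(rs)]] == ranges$start[rs[-1L]]))
      return(NULL)
    chain <- c(chain, ranges$index[rs])
  }
  if (!is_strictly_increasing(chain)) return(NULL)
  chain
}
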