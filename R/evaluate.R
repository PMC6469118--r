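#' Compare assembled transcripts against a truth set
#'
#' A multi-exon transcript is correct when its full splice chain (all
#' intron coordinates) and strand match a truth transcript on the same
#' chromosome; terminal exon ends are ignored, as read evidence cannot pin
#' them.  Single-exon transcripts match by genomic overlap on the same
#' chromosome.
#'
#' @param transcripts list of assembled transcripts (chrom, strand, exons,
#'   abundance)
#' @param truth list of `sim_locus` objects, or a list of transcript objects
#'   of the same shape as `transcripts`
#' @return list with recall, precision, counts, and a data.frame `matched`
#'   of (truth_abundance, est_abundance) pairs for rank comparisons
#' @export
evaluate_assembly <- function(transcripts, truth) {
  truth_tx <- list()
  for (item in truth) {
    if (inherits(item, "sim_locus")) {
      for (k in seq_along(item$isoforms)) {
        ch <- item$isoforms[[k]]
        truth_tx[[length(truth_tx) + 1L]] <- list(
          chrom = item$chrom, strand = item$strand,
          exons = data.frame(start = item$exon_starts[ch],
                             end = item$exon_ends[ch]),
          abundance = item$abundances[k])
      }
    } else truth_tx[[length(truth_tx) + 1L]] <- item
  }
  key <- function(tx) {
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    n <- nrow(ex)
    if (n == 1L) return(NA_character_)
    introns <- paste(ex$end[-n], ex$start[-1L], sep = "-", collapse = ";")
    paste(tx$chrom, tx$strand, introns, sep = "|")
  }
  tkeys <- vapply(truth_tx, key, character(1))
  akeys <- vapply(transcripts, key, character(1))
  matched_t <- logical(length(truth_tx))
  matched_a <- logical(length(transcripts))
  pairs <- list()
  for (i in seq_along(transcripts)) {
    if (is.na(akeys[i])) next
    j <- which(!matched_t & tkeys == akeys[i])
    if (length(j)) {
      j <- j[1L]
      matched_t[j] <- TRUE; matched_a[i] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        truth_abundance = truth_tx[[j]]$abundance,
        est_abundance = transcripts[[i]]$abundance)
    }
  }
  # single-exon transcripts: overlap matching (strand-agnostic when the
  # assembly could not orient the locus)
  for (i in seq_along(transcripts)) {
    if (!is.na(akeys[i]) || matched_a[i]) next
    ax <- transcripts[[i]]
    for (j in seq_along(truth_tx)) {
      if (matched_t[j] || !is.na(tkeys[j])) next
      tx <- truth_tx[[j]]
      if (ax$chrom == tx$chrom &&
          min(ax$exons$end) > min(tx$exons$start) &&
          max(ax$exons$start) < max(tx$exons$end)) {
        matched_t[j] <- TRUE; matched_a[i] <- TRUE
        pairs[[length(pairs) + 1L]] <- data.frame(
          truth_abundance = tx$abundance,
          est_abundance = ax$abundance)
        break
      }
    }
  }
  list(recall = if (length(truth_tx)) mean(matched_t) else NA_real_,
       precision = if (length(transcripts)) mean(matched_a) else NA_real_,
       n_truth = length(truth_tx), n_assembled = length(transcripts),
       n_matched = sum(matched_a),
       matched = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(truth_abundance = numeric(0),
                    est_abundance = numeric(0)))
}
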