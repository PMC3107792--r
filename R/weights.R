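#' Compute read-isoform compatibility weights
#'
#' For every read r and isoform j, the weight `w_rj = sum_a Q_a F_a O_a`
#' over the read's alignments `a` compatible with j, where Q is the base
#' quality term, F the fragment-length term and O the orientation term.
#' Compatibilities are found by a coordinate-sorted line sweep over
#' alignment and isoform genome intervals; reads with no positive-weight
#' isoform are dropped and counted.
#'
#' @param alns an `alignment_set` from [read_alignments()] or
#'   [reads_to_alignments()].
#' @param txome a [transcriptome()].
#' @param dist a [frag_dist_normal()] fragment-length distribution.
#' @param directional TRUE for strand-preserving library protocols.
#' @return list with `weights` (data.frame `read`, `tx`, `w`, sorted by
#'   read then isoform), `n_reads` and `n_dropped`.
#' @export
compute_weights <- function(alns, txome, dist, directional = FALSE) {
  aln <- alns$aln
  sp_s <- txome$seg_start[txome$seg_off[-length(txome$seg_off)] + 1L]
  sp_e <- txome$seg_end[txome$seg_off[-1L]]
  L <- total_length(txome)
  strand_i <- ifelse(txome$tx$strand == "+", 1L, -1L)
  out <- list()
  for (ch in unique(aln$chrom)) {
    ai <- which(aln$chrom == ch)
    ai <- ai[order(aln$start[ai])]
    ti <- which(txome$tx$chrom == ch)
    if (!length(ti)) next
    ti <- ti[order(sp_s[ti])]
    g <- .csr_gather(alns$blk_off, ai)
    res <- cpp_sweep_weights(
      aln$read[ai], aln$qa[ai], aln$start[ai], aln$end[ai],
      aln$strand[ai], aln$strand2[ai], aln$paired[ai],
      alns$blk_start[g$pos], alns$blk_end[g$pos], alns$blk_mate[g$pos],
      c(0L, cumsum(g$lens)),
      ti, sp_s[ti], sp_e[ti], strand_i[ti], L[ti],
      txome$seg_start, txome$seg_end, txome$seg_cum, txome$seg_off,
      dist$k[1L], dist$pmf, dist$cdf, directional)
    out[[length(out) + 1L]] <- data.frame(read = res$read, tx = res$tx,
                                          w = res$w)
  }
  w <- if (length(out)) do.call(rbind, out)
    else data.frame(read = integer(0), tx = integer(0), w = numeric(0))
  w <- w[order(w$read, w$tx), , drop = FALSE]
  rownames(w) <- NULL
  n_reads <- length(alns$read_id)
  list(weights = w, n_reads = n_reads,
       n_dropped = n_reads - length(unique(w$read)))
}
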