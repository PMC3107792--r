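#' Quantify isoform and gene expression from alignments
#'
#' End-to-end pipeline: read-isoform weights (line sweep), optional hexamer
#' bias and repeat-masking corrections, read-class collapsing via the
#' online union-find, per-component EM with insert-size-aware effective
#' lengths, global assembly and gene-level aggregation.
#'
#' @param alignments an `alignment_set` (from [read_alignments()] or
#'   [reads_to_alignments()]) or a SAM/BAM path.
#' @param txome a [transcriptome()] or a GTF path.
#' @param dist fragment-length distribution, see [frag_dist_normal()].
#' @param directional TRUE for strand-preserving protocols.
#' @param polya poly(A) tail length to append to all transcripts (0 = off).
#' @param repeats optional repeat annotation (GRanges, BED path or
#'   data.frame); reads overlapping repeats are discarded and effective
#'   lengths use repeat-adjusted transcript lengths.
#' @param read_len read length (required when `repeats` is given).
#' @param hexamer_reads optional character vector of read sequences,
#'   parallel to the alignment set's reads, enabling the hexamer-priming
#'   bias correction.
#' @param collapse collapse equivalent reads into read classes (default
#'   TRUE; FALSE is a debugging mode and must give identical results).
#' @param init,seed,tol,max_iter EM controls, see [run_component_em()].
#' @param fast_lengths approximate the effective length by `l - mu + 1`
#'   for transcripts with `l >= mu + 100`.
#' @param keep_trace keep per-component log-likelihood traces.
#' @return object of class `"txem_fit"` with elements `isoforms` (tx_id,
#'   gene_id, frequency, expected_count, effective_length, fpkm), `genes`
#'   (gene_id, frequency) and `stats`.
#' @export
quantify <- function(alignments, txome, dist = frag_dist_normal(250, 25),
                     directional = FALSE, polya = 0L, repeats = NULL,
                     read_len = NULL, hexamer_reads = NULL, collapse = TRUE,
                     init = "uniform", seed = NULL, tol = 1e-8,
                     max_iter = 10000L, fast_lengths = FALSE,
                     keep_trace = FALSE) {
  if (is.character(txome)) txome <- read_transcriptome(txome)
  if (polya > 0L) txome <- extend_poly_a(txome, polya)
  if (is.character(alignments))
    alignments <- read_alignments(alignments, txome)
  adj <- NULL
  if (!is.null(repeats)) {
    if (is.null(read_len)) stop("read_len is required with repeat masking")
    rm_ <- repeat_mask(txome, repeats, read_len)
    txome <- rm_$txome
    adj <- txome$tx$adj_length
    alignments <- .drop_repeat_reads(alignments, repeats)
  }
  wts <- compute_weights(alignments, txome, dist, directional)
  w <- wts$weights
  # per-read multiplicities (hexamer bias correction folds in here)
  m_r <- rep(1, length(alignments$read_id))
  if (!is.null(hexamer_reads)) {
    prof <- hexamer_distributions(hexamer_reads)
    if (!is.null(prof)) {
      b <- hexamer_weight_table(prof)
      m_r <- hexamer_read_weights(hexamer_reads, b)
    }
  }
  forest <- class_forest(collapse = collapse)
  comps <- list()
  if (nrow(w) > 0L) {
    reads_present <- unique(w$read)  # sorted: w is ordered by read
    cnt <- tabulate(match(w$read, reads_present))
    forest_add_reads(forest, w$tx, w$w, c(0L, cumsum(cnt)),
                     m_r[reads_present])
    comps <- forest_collect(forest)
  }
  Lvec <- if (!is.null(adj)) adj else total_length(txome)
  lt <- effective_length(dist, Lvec)
  if (fast_lengths) {
    fl <- Lvec >= dist$mu + 100
    lt[fl] <- approx_effective_length(Lvec[fl], dist$mu)
  }
  results <- vector("list", length(comps))
  traces <- if (keep_trace) vector("list", length(comps)) else NULL
  for (i in seq_along(comps)) {
    cp <- comps[[i]]
    results[[i]] <- run_component_em(cp$W, cp$m, lt[cp$iso], init = init,
                                     seed = seed, tol = tol,
                                     max_iter = max_iter,
                                     trace = keep_trace)
    if (keep_trace) traces[[i]] <- results[[i]]$ll_trace
  }
  glob <- combine_components(results, lapply(comps, `[[`, "iso"),
                             nrow(txome$tx), lt)
  total_m <- sum(glob$n)
  fpkm <- if (total_m > 0) glob$n * 1e9 / (lt * total_m) else glob$n
  iso_tab <- data.frame(tx_id = txome$tx$tx_id, gene_id = txome$tx$gene_id,
                        frequency = glob$f, expected_count = glob$n,
                        effective_length = lt, fpkm = fpkm,
                        stringsAsFactors = FALSE)
  gf <- gene_expression(glob$f, txome$tx$gene_id)
  gene_tab <- data.frame(gene_id = names(gf), frequency = as.numeric(gf),
                         stringsAsFactors = FALSE)
  st <- forest_stats(forest)
  fit <- list(isoforms = iso_tab, genes = gene_tab,
              stats = list(n_reads = wts$n_reads,
                           n_dropped = wts$n_dropped,
                           n_components = length(comps),
                           n_classes = st$n_classes,
                           total_multiplicity = st$total_m,
                           iterations = sum(vapply(results, `[[`,
                             integer(1), "iterations")),
                           converged = all(vapply(results, `[[`,
                             logical(1), "converged"))),
              components = lapply(comps, `[[`, "iso"),
              component_results = results,
              ll_traces = traces)
  class(fit) <- "txem_fit"
  fit
}

.drop_repeat_reads <- function(alns, repeats) {
  rep_gr <- .as_repeat_granges(repeats)
  aln <- alns$aln
  blk_aln <- rep.int(seq_len(nrow(aln)), diff(alns$blk_off))
  gr <- GenomicRanges::GRanges(aln$chrom[blk_aln],
          IRanges::IRanges(alns$blk_start + 1L, alns$blk_end))
  hit_aln <- unique(blk_aln[suppressWarnings(
    GenomicRanges::countOverlaps(gr, rep_gr)) > 0L])
  bad_reads <- unique(aln$read[hit_aln])
  if (!length(bad_reads)) return(alns)
  keep <- !(aln$read %in% bad_reads)
  g <- .csr_gather(alns$blk_off, which(keep))
  .alignment_set(alns$read_id, aln[keep, c("read", "chrom", "strand",
                   "strand2", "paired", "qa")],
                 c(0L, cumsum(g$lens)), alns$blk_start[g$pos],
                 alns$blk_end[g$pos], alns$blk_mate[g$pos],
                 alns$n_unmapped, alns$n_rejected)
}

#' @export
print.txem_fit <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("txem_fit: %d isoforms, %d genes\n",
                     "  reads %d (dropped %d), classes %d, components %d\n",
                     "  EM iterations %d, converged: %s\n"),
              nrow(x$isoforms), nrow(x$genes), s$n_reads, s$n_dropped,
              s$n_classes, s$n_components, s$iterations, s$converged))
  invisible(x)
}

#' Write estimates to TSV files
#'
#' Emits `<prefix>.isoforms.tsv`, `<prefix>.genes.tsv` and a small
#' `<prefix>.log` run summary.  Numeric columns use full precision so reruns
#' with identical inputs are byte-identical.
#'
#' @param fit a [quantify()] result.
#' @param prefix output path prefix.
#' @export
write_estimates <- function(fit, prefix) {
  iso <- fit$isoforms
  for (cl in c("frequency", "expected_count", "effective_length", "fpkm"))
    iso[[cl]] <- sprintf("%.10g", iso[[cl]])
  write.table(iso, paste0(prefix, ".isoforms.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gen <- fit$genes
  gen$frequency <- sprintf("%.10g", gen$frequency)
  write.table(gen, paste0(prefix, ".genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  s <- fit$stats
  writeLines(sprintf("%s\t%s", names(s), vapply(s, format, character(1))),
             paste0(prefix, ".log"))
  invisible(prefix)
}
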