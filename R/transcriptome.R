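#' Construct a transcriptome from exon coordinates
#'
#' Builds the in-memory representation of a known-isoform library used by all
#' other functions in the package.  All coordinates are 0-based, half-open
#' genome intervals; exons are sorted and overlapping/adjacent exons are
#' merged per transcript.
#'
#' @param tx_id character vector of transcript identifiers (unique).
#' @param gene_id character vector of gene identifiers, one per transcript.
#'   Transcripts sharing a `gene_id` form one gene cluster.
#' @param chrom character vector of chromosome names.
#' @param strand character vector, `"+"` or `"-"`.
#' @param exons list of two-column integer matrices, one per transcript:
#'   columns are genome start and end (0-based, half-open).
#' @param polya integer, poly(A) tail length appended to every transcript
#'   (see [extend_poly_a()]).
#' @return An object of class `"transcriptome"`.
#' @seealso [read_transcriptome()] to load from GTF.
#' @export
transcriptome <- function(tx_id, gene_id, chrom, strand, exons, polya = 0L) {
  n <- length(tx_id)
  stopifnot(n >= 1, length(gene_id) == n, length(chrom) == n,
            length(strand) == n, length(exons) == n,
            all(strand %in% c("+", "-")), !anyDuplicated(tx_id))
  exons <- lapply(exons, function(m) {
    m <- matrix(as.integer(m), ncol = 2)
    if (nrow(m) == 0L) stop("transcript with zero exons")
    m <- m[order(m[, 1L]), , drop = FALSE]
    if (any(m[, 2L] <= m[, 1L])) stop("empty or inverted exon interval")
    # merge overlapping / book-ended exons
    ir <- IRanges::reduce(IRanges::IRanges(m[, 1L] + 1L, m[, 2L]))
    cbind(IRanges::start(ir) - 1L, IRanges::end(ir))
  })
  len <- vapply(exons, function(m) sum(m[, 2L] - m[, 1L]), integer(1))
  obj <- list(
    tx = data.frame(tx_id = as.character(tx_id),
                    gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    strand = as.character(strand),
                    length = len,
                    polya = as.integer(polya),
                    adj_length = NA_real_,
                    stringsAsFactors = FALSE),
    ex_start = unlist(lapply(exons, function(m) m[, 1L]), use.names = FALSE),
    ex_end = unlist(lapply(exons, function(m) m[, 2L]), use.names = FALSE),
    ex_off = c(0L, cumsum(vapply(exons, nrow, integer(1))))
  )
  class(obj) <- "transcriptome"
  .build_segments(obj)
}

# Segment table: annotated exons in ascending genome order plus (optionally)
# a virtual poly(A) segment on the genomic 3' side of the transcript.
# Zero-gap neighbours are merged so that a segment boundary always implies a
# real intron gap; seg_cum holds the number of transcript bases preceding
# each segment in ascending genome order.
.build_segments <- function(txome) {
  n <- nrow(txome$tx)
  starts <- vector("list", n); ends <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- (txome$ex_off[i] + 1L):txome$ex_off[i + 1L]
    s <- txome$ex_start[idx]; e <- txome$ex_end[idx]
    tail_len <- txome$tx$polya[i]
    if (tail_len > 0L) {
      if (txome$tx$strand[i] == "+") {
        s <- c(s, e[length(e)]); e <- c(e, e[length(e)] + tail_len)
      } else {
        s <- c(s[1L] - tail_len, s); e <- c(s[2L], e)
      }
      # merge zero-gap neighbours (tail abuts the terminal exon)
      keep <- c(TRUE, s[-1L] != e[-length(e)])
      grp <- cumsum(keep)
      s <- tapply(s, grp, min); e <- tapply(e, grp, max)
    }
    starts[[i]] <- as.integer(s); ends[[i]] <- as.integer(e)
  }
  txome$seg_start <- unlist(starts, use.names = FALSE)
  txome$seg_end <- unlist(ends, use.names = FALSE)
  txome$seg_off <- c(0L, cumsum(lengths(starts)))
  w <- txome$seg_end - txome$seg_start
  cum <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- (txome$seg_off[i] + 1L):txome$seg_off[i + 1L]
    cum[[i]] <- cumsum(c(0, w[idx]))[seq_along(idx)]
  }
  txome$seg_cum <- unlist(cum, use.names = FALSE)
  txome
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("transcriptome: %d isoforms, %d genes, %d chromosome(s)\n",
              nrow(x$tx), length(unique(x$tx$gene_id)),
              length(unique(x$tx$chrom))))
  cat(sprintf("  annotated lengths %d-%d, poly(A) tail %d\n",
              min(x$tx$length), max(x$tx$length), max(x$tx$polya)))
  invisible(x)
}

# resolve transcript id or index to index
tx_index <- function(txome, tx) {
  if (is.character(tx)) {
    i <- match(tx, txome$tx$tx_id)
    if (anyNA(i)) stop("unknown transcript id: ", tx[is.na(i)][1L])
    i
  } else as.integer(tx)
}

#' Total transcript length including any poly(A) tail
#' @param txome a transcriptome.
#' @return numeric vector of lengths, one per isoform.
#' @export
total_length <- function(txome) txome$tx$length + txome$tx$polya

# exon matrix (annotated, ascending genome order) for one transcript
tx_exons <- function(txome, tx) {
  i <- tx_index(txome, tx)
  idx <- (txome$ex_off[i] + 1L):txome$ex_off[i + 1L]
  cbind(start = txome$ex_start[idx], end = txome$ex_end[idx])
}

tx_segments <- function(txome, tx) {
  i <- tx_index(txome, tx)
  idx <- (txome$seg_off[i] + 1L):txome$seg_off[i + 1L]
  list(start = txome$seg_start[idx], end = txome$seg_end[idx],
       cum = txome$seg_cum[idx])
}

#' Load a transcriptome from a GTF annotation
#'
#' Reads exon features from a GTF file and assembles the isoform library.
#' Transcripts are grouped into genes by the GTF `gene_id` attribute unless
#' an explicit mapping is supplied, which allows reproducing externally
#' defined gene clusters.
#'
#' @param gtf path to a GTF file with `exon` features carrying
#'   `transcript_id` and `gene_id` attributes.
#' @param gene_map optional data.frame with columns `tx_id` and `gene_id`
#'   overriding the GTF gene assignment.
#' @return a [transcriptome()] object.
#' @export
read_transcriptome <- function(gtf, gene_map = NULL) {
  if (is.character(gtf) &&
      length(readLines(gtf, n = 1L, warn = FALSE)) == 0L)
    stop("no transcripts in annotation: ", gtf)
  gr <- rtracklayer::import(gtf, format = "gtf")
  if (length(gr) == 0L) stop("no transcripts in annotation: ", gtf)
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("no transcripts (annotation has no exon features)")
  tx_of_ex <- as.character(ex$transcript_id)
  # transcripts announced but having no exon rows are skipped with a warning
  if (!is.null(gr$transcript_id)) {
    all_tx <- unique(as.character(gr$transcript_id[gr$type %in%
                c("transcript", "mRNA", "exon") & !is.na(gr$transcript_id)]))
    missing_tx <- setdiff(all_tx, unique(tx_of_ex))
    if (length(missing_tx))
      warning("skipping ", length(missing_tx),
              " transcript(s) with zero exons")
  }
  o <- order(tx_of_ex)
  ex <- ex[o]; tx_of_ex <- tx_of_ex[o]
  first <- !duplicated(tx_of_ex)
  ids <- tx_of_ex[first]
  genes <- as.character(ex$gene_id[first])
  if (!is.null(gene_map)) {
    m <- match(ids, gene_map$tx_id)
    genes <- ifelse(is.na(m), genes, as.character(gene_map$gene_id[m]))
  }
  exl <- split(cbind(GenomicRanges::start(ex) - 1L, GenomicRanges::end(ex)),
               factor(tx_of_ex, levels = ids))
  exl <- lapply(exl, function(v) matrix(v, ncol = 2))
  transcriptome(tx_id = ids, gene_id = genes,
                chrom = as.character(GenomicRanges::seqnames(ex))[first],
                strand = as.character(GenomicRanges::strand(ex))[first],
                exons = exl)
}

#' Map genome-space alignment blocks to a transcript-coordinate interval
#'
#' An alignment (a set of sorted, disjoint genome blocks) is compatible with
#' an isoform iff every block base lies inside the isoform's exons (or
#' poly(A) tail) and every inter-block gap coincides exactly with a complete
#' intron of the isoform, i.e. the blocks are contiguous in transcript space.
#' Transcript coordinates run 5' to 3' along the isoform strand and are
#' 0-based half-open.
#'
#' @param txome a transcriptome.
#' @param tx transcript id or index.
#' @param blocks two-column matrix of genome intervals (0-based half-open),
#'   sorted and disjoint.
#' @return integer vector `c(start, end)` in transcript coordinates, or
#'   `NULL` if the alignment is incompatible with the isoform.
#' @export
transcript_interval <- function(txome, tx, blocks) {
  blocks <- matrix(as.integer(blocks), ncol = 2)
  nb <- nrow(blocks)
  stopifnot(nb >= 1)
  if (nb > 1L && (any(diff(blocks[, 1L]) <= 0) ||
                  any(blocks[-1L, 1L] < blocks[-nb, 2L])))
    stop("blocks must be sorted and disjoint")
  i <- tx_index(txome, tx)
  sg <- tx_segments(txome, i)
  L <- txome$tx$length[i] + txome$tx$polya[i]
  # first block: locate containing segment
  j <- findInterval(blocks[1L, 1L], sg$start)
  if (j == 0L) return(NULL)
  if (blocks[1L, 2L] > sg$end[j]) return(NULL)
  o_first <- sg$cum[j] + (blocks[1L, 1L] - sg$start[j])
  cur <- j
  for (b in seq_len(nb)) {
    if (b > 1L) {
      if (blocks[b - 1L, 2L] != sg$end[cur]) return(NULL)
      cur <- cur + 1L
      if (cur > length(sg$start) || blocks[b, 1L] != sg$start[cur])
        return(NULL)
    }
    if (blocks[b, 2L] > sg$end[cur] || blocks[b, 1L] < sg$start[cur])
      return(NULL)
    o_last <- sg$cum[cur] + (blocks[b, 2L] - 1L - sg$start[cur])
  }
  if (txome$tx$strand[i] == "+") c(o_first, o_last + 1)
  else c(L - 1 - o_last, L - o_first)
}

#' Project a transcript-coordinate interval back to genome blocks
#'
#' Inverse of [transcript_interval()]: returns the genome blocks covered by
#' the transcript interval `[t_start, t_end)`.  Positions inside a poly(A)
#' tail map to virtual genome coordinates immediately 3' of the terminal
#' exon.
#'
#' @inheritParams transcript_interval
#' @param t_start,t_end transcript coordinates (0-based half-open).
#' @return two-column matrix of genome intervals in ascending order.
#' @export
genome_blocks <- function(txome, tx, t_start, t_end) {
  i <- tx_index(txome, tx)
  sg <- tx_segments(txome, i)
  L <- txome$tx$length[i] + txome$tx$polya[i]
  stopifnot(t_start >= 0, t_end <= L, t_end > t_start)
  if (txome$tx$strand[i] == "+") { o0 <- t_start; o1 <- t_end }
  else { o0 <- L - t_end; o1 <- L - t_start }
  w <- sg$end - sg$start
  out <- NULL
  for (j in seq_along(sg$start)) {
    a <- max(o0, sg$cum[j]); b <- min(o1, sg$cum[j] + w[j])
    if (b > a)
      out <- rbind(out, c(sg$start[j] + (a - sg$cum[j]),
                          sg$start[j] + (b - sg$cum[j])))
  }
  colnames(out) <- c("start", "end")
  out
}

#' Extend all transcripts with a poly(A) tail
#'
#' Appends `tail` bases of poly(A) to the 3' end of every isoform.  The tail
#' occupies virtual genome coordinates adjacent to the terminal exon so that
#' reads aligned (partly) within the tail remain representable in genome
#' space; tails of isoforms sharing a 3' terminal exon coincide, making
#' tail-only reads compatible with all of them.
#'
#' @param txome a transcriptome.
#' @param tail non-negative integer, tail length in bases (default 200).
#' @return the updated transcriptome.
#' @export
extend_poly_a <- function(txome, tail = 200L) {
  stopifnot(tail >= 0)
  txome$tx$polya <- as.integer(tail)
  .build_segments(txome)
}

#' Repeat-masking correction
#'
#' Returns a predicate that flags alignments overlapping annotated repeats
#' (such reads are discarded before quantification) together with a
#' transcriptome whose `adj_length` column holds repeat-adjusted lengths:
#' for each isoform the number of transcript start positions from which a
#' read of `read_len` bases would overlap a repeat is subtracted from the
#' total length.  Adjusted lengths replace plain lengths in effective-length
#' computations when masking is enabled.
#'
#' @param txome a transcriptome.
#' @param repeats repeat intervals: a `GRanges`, a BED file path, or a
#'   data.frame with columns `chrom`, `start`, `end` (0-based half-open).
#' @param read_len read length in bases.
#' @return list with elements `discard` (function mapping a blocks matrix
#'   plus chromosome to TRUE/FALSE) and `txome` (adjusted lengths filled in).
#' @export
repeat_mask <- function(txome, repeats, read_len) {
  rep_gr <- .as_repeat_granges(repeats)
  n <- nrow(txome$tx)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    sg <- tx_segments(txome, i)
    L <- txome$tx$length[i] + txome$tx$polya[i]
    segs <- GenomicRanges::GRanges(txome$tx$chrom[i],
              IRanges::IRanges(sg$start + 1L, sg$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(segs, rep_gr))
    if (length(hits) == 0L || L < read_len) { adj[i] <- L; next }
    masked <- NULL       # transcript-space masked intervals (0-based, [a,b))
    for (h in seq_along(hits)) {
      j <- S4Vectors::queryHits(hits)[h]
      r <- rep_gr[S4Vectors::subjectHits(hits)[h]]
      gs <- max(sg$start[j], GenomicRanges::start(r) - 1L)
      ge <- min(sg$end[j], GenomicRanges::end(r))
      o0 <- sg$cum[j] + (gs - sg$start[j]); o1 <- o0 + (ge - gs)
      tt <- if (txome$tx$strand[i] == "+") c(o0, o1) else c(L - o1, L - o0)
      masked <- rbind(masked, tt)
    }
    # start positions whose read window [s, s+read_len) hits a masked base
    bad <- IRanges::reduce(IRanges::IRanges(
      start = pmax(masked[, 1L] - read_len + 1L, 0L) + 1L,
      end = masked[, 2L]))
    bad <- IRanges::restrict(bad, start = 1L, end = as.integer(L - read_len + 1L))
    adj[i] <- L - sum(IRanges::width(bad))
  }
  txome$tx$adj_length <- adj
  discard <- function(chrom, blocks) {
    b <- matrix(as.integer(blocks), ncol = 2)
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(b[, 1L] + 1L, b[, 2L]))
    any(suppressWarnings(GenomicRanges::countOverlaps(q, rep_gr)) > 0L)
  }
  list(discard = discard, txome = txome)
}

.as_repeat_granges <- function(repeats) {
  if (is(repeats, "GRanges")) return(repeats)
  if (is.character(repeats))
    return(rtracklayer::import(repeats, format = "bed"))
  GenomicRanges::GRanges(repeats$chrom,
    IRanges::IRanges(repeats$start + 1L, repeats$end))
}

#' Gene clusters of a transcriptome
#' @param txome a transcriptome.
#' @return named list mapping gene id to member transcript ids.
#' @export
gene_clusters <- function(txome) {
  split(txome$tx$tx_id, txome$tx$gene_id)
}
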