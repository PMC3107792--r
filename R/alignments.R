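#' Convert Phred quality scores to error probabilities
#'
#' `eps = 10^(-q/10)`, floored at 1e-4 and capped at 0.75 to avoid
#' degenerate per-base products.
#'
#' @param q integer Phred scores.
#' @export
phred_to_error <- function(q) pmin(pmax(10^(-q / 10), 1e-4), 0.75)

#' Probability of observing a read given its alignment (Q)
#'
#' Product over aligned bases of `1 - eps_k` for matching positions and
#' `eps_k` for mismatching positions; for read pairs, the product runs over
#' both mates.  An empty alignment yields 1 (empty product).
#'
#' @param eps per-base error probabilities.
#' @param match logical vector, TRUE where the base matches the reference.
#' @export
alignment_base_prob <- function(eps, match) {
  stopifnot(length(eps) == length(match))
  prod(ifelse(match, 1 - eps, eps))
}

#' Orientation consistency factor (O)
#'
#' 1 if the alignment is consistent with the isoform orientation, else 0.
#' Single nondirectional reads are always consistent (reads are taken from
#' either fragment end at random); single directional reads must match the
#' isoform strand.  Paired reads must have mates on opposite strands that
#' point to each other along the transcript (the 5'-most mate in transcript
#' coordinates is on the isoform's sense strand), with the first mate
#' additionally matching the isoform strand under a directional protocol.
#'
#' @param read_strand,iso_strand `+1`/`-1` genome strands (first mate for
#'   pairs).
#' @param paired,directional protocol flags.
#' @param mate2_strand genome strand of the second mate (pairs only).
#' @param t1,t2 transcript-coordinate intervals `c(start, end)` of the two
#'   mates (pairs only).
#' @return 0 or 1.
#' @export
orientation_factor <- function(read_strand, iso_strand, paired = FALSE,
                               directional = FALSE, mate2_strand = NULL,
                               t1 = NULL, t2 = NULL) {
  if (!paired) {
    if (!directional) return(1)
    return(as.numeric(read_strand == iso_strand))
  }
  if (read_strand == mate2_strand) return(0)
  left_strand <- if (t1[1L] <= t2[1L]) read_strand else mate2_strand
  if (left_strand != iso_strand) return(0)
  if (directional && read_strand != iso_strand) return(0)
  1
}

#' Upper bound on the fragment length for a single-end alignment (u)
#'
#' For a sense alignment the fragment can extend at most from the read's 5'
#' end to the isoform's 3' end; for an antisense alignment, to the isoform's
#' 5' end.  Counts include the read's 5' base.
#'
#' @param L total isoform length (including any poly(A) tail).
#' @param t_int transcript-coordinate interval `c(start, end)` of the read.
#' @param sense TRUE if the read is on the isoform's sense strand.
#' @export
single_end_length_bound <- function(L, t_int, sense) {
  if (sense) L - t_int[1L] else t_int[2L]
}

#' Fragment-length factor (F)
#'
#' For read pairs, the probability `p(k)` of the implied fragment length
#' `k` (transcript-space distance from the leftmost mate's 5' end to the
#' rightmost mate's 3' end).  For single reads, the probability of a
#' fragment of at most `u` bases, `P(K <= u)`, with `u` from
#' [single_end_length_bound()].
#'
#' @param dist a [frag_dist_normal()] object.
#' @param paired protocol flag.
#' @param k implied fragment length (pairs).
#' @param u fragment length upper bound (single).
#' @export
fragment_factor <- function(dist, paired, k = NULL, u = NULL) {
  if (paired) frag_pmf(dist, k) else frag_cdf(dist, u)
}

# internal alignment_set constructor; aln is a data.frame with columns
# read (int), chrom (char), strand, strand2 (int +1/-1/0), paired, qa;
# blocks are CSR over alignments (mate-1 rows first, each mate ascending)
.alignment_set <- function(read_id, aln, blk_off, blk_start, blk_end,
                           blk_mate, n_unmapped = 0L, n_rejected = 0L) {
  span <- cbind(
    start = vapply(seq_len(nrow(aln)), function(i) {
      if (blk_off[i + 1L] == blk_off[i]) NA_integer_
      else min(blk_start[(blk_off[i] + 1L):blk_off[i + 1L]])
    }, integer(1)),
    end = vapply(seq_len(nrow(aln)), function(i) {
      max(blk_end[(blk_off[i] + 1L):blk_off[i + 1L]])
    }, integer(1)))
  aln$start <- span[, 1L]; aln$end <- span[, 2L]
  structure(list(read_id = read_id, aln = aln, blk_off = blk_off,
                 blk_start = blk_start, blk_end = blk_end,
                 blk_mate = blk_mate, n_unmapped = n_unmapped,
                 n_rejected = n_rejected),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set: %d reads, %d alignments (%d unmapped, %d rejected)\n",
              length(x$read_id), nrow(x$aln), x$n_unmapped, x$n_rejected))
  invisible(x)
}

# number of blocks per alignment, CSR gather helper
.csr_gather <- function(off, idx) {
  lens <- off[idx + 1L] - off[idx]
  list(pos = sequence(lens, from = off[idx] + 1L), lens = lens)
}

#' Read alignments from a SAM/BAM file
#'
#' Parses alignments produced by an ungapped aligner run against the
#' transcript library (or pre-spliced genome alignments with `N` gaps) and
#' expresses every alignment as genome-space blocks.  Mates of a pair are
#' grouped, unmapped records are dropped (counted), alignments containing
#' insertions, deletions or clipping are rejected (counted), and alignments
#' of one read that are identical in genome space -- e.g. via different
#' transcripts of the same gene -- are merged so that the per-alignment sum
#' in the weight model does not double count.
#'
#' @param file SAM or BAM path.
#' @param txome a [transcriptome()]; reference names must resolve either to
#'   transcript ids (transcript-space input) or chromosome names
#'   (genome-space input).
#' @param default_phred Phred score substituted when quality strings are
#'   missing (default 30).
#' @param seqs optional named `DNAStringSet` of transcript sequences used to
#'   derive per-base match flags when the `MD` tag is absent.
#' @return an `alignment_set`.
#' @export
read_alignments <- function(file, txome, default_phred = 30L, seqs = NULL) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile()
    file <- Rsamtools::asBam(file, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual",
             "mrnm", "mpos"),
    tag = c("MD", "NM"))
  res <- Rsamtools::scanBam(file, param = p)[[1L]]
  flag <- res$flag
  n_unmapped <- sum(bitwAnd(flag, 4L) > 0L)
  keep <- bitwAnd(flag, 4L) == 0L & !is.na(res$pos)
  if (!any(keep)) {
    warning("0 mapped reads in ", file)
    return(.alignment_set(character(0),
      data.frame(read = integer(0), chrom = character(0), strand = integer(0),
                 strand2 = integer(0), paired = logical(0), qa = numeric(0),
                 stringsAsFactors = FALSE),
      0L, integer(0), integer(0), integer(0), n_unmapped))
  }
  qname <- res$qname[keep]; flag <- flag[keep]
  rname <- as.character(res$rname[keep]); pos <- res$pos[keep]
  cigar <- res$cigar[keep]
  qual <- as.character(res$qual[keep]); seqv <- as.character(res$seq[keep])
  md <- res$tag$MD[keep]
  mrnm <- as.character(res$mrnm[keep]); mpos <- res$mpos[keep]

  # resolve reference space
  in_tx <- rname %in% txome$tx$tx_id
  in_genome <- rname %in% unique(txome$tx$chrom)
  if (!all(in_tx | in_genome))
    stop("unknown reference name: ", rname[!(in_tx | in_genome)][1L])
  tx_space <- all(in_tx)

  # cigar -> reference-space blocks; only M/=/X and N allowed
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  bad <- vapply(ops, function(o) any(grepl("[IDSHP]", o)), logical(1))
  n_rejected <- sum(bad)
  if (any(bad)) {
    qname <- qname[!bad]; flag <- flag[!bad]; rname <- rname[!bad]
    pos <- pos[!bad]; qual <- qual[!bad]; seqv <- seqv[!bad]
    md <- md[!bad]; mrnm <- mrnm[!bad]; mpos <- mpos[!bad]; ops <- ops[!bad]
  }
  nrec <- length(qname)
  if (nrec == 0L) stop("no usable alignments")
  local_blocks <- vector("list", nrec)
  for (i in seq_len(nrec)) {
    len <- as.integer(sub("[MNX=]", "", ops[[i]]))
    typ <- sub("\\d+", "", ops[[i]])
    at <- pos[i] - 1L
    bl <- NULL
    for (j in seq_along(len)) {
      if (typ[j] == "N") at <- at + len[j]
      else { bl <- rbind(bl, c(at, at + len[j])); at <- at + len[j] }
    }
    local_blocks[[i]] <- bl
  }

  # per-base error probabilities and match flags -> Q per record
  rev <- bitwAnd(flag, 16L) > 0L
  q_rec <- numeric(nrec)
  for (i in seq_len(nrec)) {
    rl <- sum(local_blocks[[i]][, 2L] - local_blocks[[i]][, 1L])
    qv <- if (is.na(qual[i]) || qual[i] == "*") integer(0)
      else utf8ToInt(qual[i]) - 33L
    eps <- if (length(qv) != rl || any(qv < 0))  # absent or placeholder qual
      rep(phred_to_error(default_phred), rl)
    else phred_to_error(qv)
    mism <- if (!is.null(md) && !is.na(md[i])) .md_mismatch_offsets(md[i])
      else if (tx_space && !is.null(seqs))
        .seq_mismatch_offsets(seqv[i], seqs[[rname[i]]], pos[i])
      else integer(0)
    match <- rep(TRUE, rl); match[mism + 1L] <- FALSE
    q_rec[i] <- alignment_base_prob(eps, match)
  }

  # convert transcript-space records to genome blocks
  g_chrom <- character(nrec); g_strand <- integer(nrec)
  g_blocks <- vector("list", nrec)
  if (tx_space) {
    ti <- match(rname, txome$tx$tx_id)
    L <- total_length(txome)[ti]
    rl <- vapply(local_blocks, function(b) sum(b[, 2L] - b[, 1L]), integer(1))
    if (any(vapply(local_blocks, nrow, integer(1)) != 1L))
      stop("gapped alignment against a transcript reference")
    t0 <- pos - 1L
    pr <- cpp_genome_blocks(ti, as.numeric(t0), as.numeric(t0 + rl),
                            ifelse(txome$tx$strand[ti] == "+", 1L, -1L),
                            as.numeric(L), txome$seg_start, txome$seg_end,
                            txome$seg_cum, txome$seg_off)
    for (i in seq_len(nrec))
      g_blocks[[i]] <- cbind(pr$start[(pr$off[i] + 1L):pr$off[i + 1L]],
                             pr$end[(pr$off[i] + 1L):pr$off[i + 1L]])
    g_chrom <- txome$tx$chrom[ti]
    iso_sgn <- ifelse(txome$tx$strand[ti] == "+", 1L, -1L)
    g_strand <- ifelse(rev, -iso_sgn, iso_sgn)
  } else {
    g_blocks <- local_blocks
    g_chrom <- rname
    g_strand <- ifelse(rev, -1L, 1L)
  }

  # group into alignments: singles directly, mates paired via position keys
  is_paired <- bitwAnd(flag, 1L) > 0L
  is_first <- bitwAnd(flag, 64L) > 0L | !is_paired
  read_id <- unique(qname)
  ridx <- match(qname, read_id)
  aln_rows <- list(); blk_rows <- list()
  rec_key <- paste(qname, rname, pos, sep = "\r")
  mate_key <- paste(qname, mrnm, mpos, sep = "\r")
  used <- rep(FALSE, nrec)
  for (i in seq_len(nrec)) {
    if (used[i] || !is_first[i]) next
    used[i] <- TRUE
    if (!is_paired[i]) {
      aln_rows[[length(aln_rows) + 1L]] <- list(
        read = ridx[i], chrom = g_chrom[i], strand = g_strand[i],
        strand2 = 0L, paired = FALSE, qa = q_rec[i],
        b1 = g_blocks[[i]], b2 = NULL)
    } else {
      j <- which(!used & !is_first & rec_key == mate_key[i] &
                   mate_key == rec_key[i])[1L]
      if (is.na(j)) next  # orphan mate, drop
      used[j] <- TRUE
      aln_rows[[length(aln_rows) + 1L]] <- list(
        read = ridx[i], chrom = g_chrom[i], strand = g_strand[i],
        strand2 = g_strand[j], paired = TRUE, qa = q_rec[i] * q_rec[j],
        b1 = g_blocks[[i]], b2 = g_blocks[[j]])
    }
  }
  # deduplicate alignments identical in genome space
  keys <- vapply(aln_rows, function(a)
    paste(a$read, a$chrom, a$strand, a$strand2,
          paste(a$b1, collapse = ","), paste(a$b2, collapse = ","),
          sep = "|"), character(1))
  aln_rows <- aln_rows[!duplicated(keys)]

  na <- length(aln_rows)
  aln <- data.frame(
    read = vapply(aln_rows, `[[`, integer(1), "read"),
    chrom = vapply(aln_rows, `[[`, character(1), "chrom"),
    strand = vapply(aln_rows, `[[`, integer(1), "strand"),
    strand2 = vapply(aln_rows, `[[`, integer(1), "strand2"),
    paired = vapply(aln_rows, `[[`, logical(1), "paired"),
    qa = vapply(aln_rows, `[[`, numeric(1), "qa"),
    stringsAsFactors = FALSE)
  bs <- integer(0); be <- integer(0); bm <- integer(0); off <- integer(na + 1L)
  for (i in seq_len(na)) {
    a <- aln_rows[[i]]
    bs <- c(bs, a$b1[, 1L], if (!is.null(a$b2)) a$b2[, 1L])
    be <- c(be, a$b1[, 2L], if (!is.null(a$b2)) a$b2[, 2L])
    bm <- c(bm, rep(1L, nrow(a$b1)),
            if (!is.null(a$b2)) rep(2L, nrow(a$b2)))
    off[i + 1L] <- length(bs)
  }
  .alignment_set(read_id, aln, off, bs, be, bm, n_unmapped, n_rejected)
}

# MD tag -> 0-based offsets of mismatching aligned bases
.md_mismatch_offsets <- function(md) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1L]]
  at <- 0L; out <- integer(0)
  for (tk in toks) {
    if (grepl("^[0-9]+$", tk)) at <- at + as.integer(tk)
    else if (startsWith(tk, "^")) next  # deletion (rejected upstream)
    else { out <- c(out, at); at <- at + 1L }
  }
  out
}

.seq_mismatch_offsets <- function(read_seq, ref_seq, pos1) {
  r <- strsplit(read_seq, "")[[1L]]
  ref <- strsplit(as.character(Biostrings::subseq(ref_seq, pos1,
                    pos1 + length(r) - 1L)), "")[[1L]]
  which(r != ref) - 1L
}
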