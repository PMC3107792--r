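#' Simulate a synthetic transcriptome with alternative isoforms
#'
#' Generates multi-exon genes whose isoforms share exons (alternative
#' inclusion of internal exons), so that reads are genuinely ambiguous
#' between isoforms of a gene.  Exon counts, exon and intron lengths are
#' drawn so that isoform lengths span roughly 500-5000 bases.  Genes are
#' laid out on one chromosome with large intergenic gaps and random
#' sequence.
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene integer vector sampled uniformly for the
#'   per-gene isoform count (default 1-5).
#' @param seed optional RNG seed for reproducibility.
#' @param chrom chromosome name.
#' @param intergenic_gap bases between consecutive genes.
#' @return list with `txome` (a [transcriptome()]) and `seqs` (named
#'   `DNAStringSet` of transcript sequences).
#' @export
simulate_transcriptome <- function(n_genes = 500L, isoforms_per_gene = 1:5,
                                   seed = NULL, chrom = "chr1",
                                   intergenic_gap = 10000L) {
  stopifnot(n_genes >= 1)
  if (!is.null(seed)) set.seed(seed)
  cursor <- 0L
  tx_id <- vector("list", n_genes); gene_id <- vector("list", n_genes)
  strand <- vector("list", n_genes)
  exons <- vector("list", n_genes); seqs <- vector("list", n_genes)
  base_raw <- charToRaw("ACGT")
  for (g in seq_len(n_genes)) {
    k <- if (length(isoforms_per_gene) == 1L) isoforms_per_gene
         else sample(isoforms_per_gene, 1L)
    need_internal <- max(2L, ceiling(log2(max(k, 2L))) + 1L)
    n_ex <- sample(seq(need_internal + 2L, 12L), 1L)
    ex_len <- sample(100:400, n_ex, replace = TRUE)
    intr_len <- sample(200:800, n_ex - 1L, replace = TRUE)
    ex_start <- cursor + cumsum(c(0L, head(ex_len, -1L) + intr_len))
    ex_end <- ex_start + ex_len
    gstrand <- sample(c("+", "-"), 1L)
    # distinct exon subsets; first and last exon always included
    subsets <- list()
    tries <- 0L
    while (length(subsets) < k && tries < 200L) {
      tries <- tries + 1L
      incl <- c(TRUE, runif(n_ex - 2L) < 0.75, TRUE)
      key <- paste(which(incl), collapse = ",")
      if (!key %in% names(subsets)) subsets[[key]] <- incl
    }
    subsets <- subsets[seq_len(min(k, length(subsets)))]
    gseq <- rawToChar(base_raw[sample.int(4L, ex_end[n_ex] - cursor,
                                          replace = TRUE)])
    gname <- sprintf("G%05d", g)
    kk <- length(subsets)
    tx_id[[g]] <- sprintf("%s.I%d", gname, seq_len(kk))
    gene_id[[g]] <- rep(gname, kk)
    strand[[g]] <- rep(gstrand, kk)
    gex <- vector("list", kk); gsq <- character(kk)
    for (j in seq_len(kk)) {
      incl <- subsets[[j]]
      gex[[j]] <- cbind(ex_start[incl], ex_end[incl])
      parts <- substring(gseq, ex_start[incl] - cursor + 1L,
                         ex_end[incl] - cursor)
      gsq[j] <- paste(parts, collapse = "")
    }
    if (gstrand == "-")
      gsq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(gsq)))
    exons[[g]] <- gex; seqs[[g]] <- gsq
    cursor <- ex_end[n_ex] + intergenic_gap
  }
  tx_id <- unlist(tx_id); gene_id <- unlist(gene_id)
  strand <- unlist(strand); seqs <- unlist(seqs)
  exons <- do.call(c, exons)
  txome <- transcriptome(tx_id, gene_id, rep(chrom, length(tx_id)), strand,
                         exons)
  list(txome = txome,
       seqs = Biostrings::DNAStringSet(setNames(seqs, tx_id)))
}

#' Assign true isoform frequencies
#'
#' Each gene g receives an abundance a(g) (log-normal by default, mimicking
#' the heavy-tailed dynamic range of tissue expression atlases) and a
#' within-gene probability distribution over its isoforms: uniform
#' `p(j) = 1/k`, or truncated geometric with ratio 1/2,
#' `p(j) = 1/2^j` for `j < k` and `p(k) = 1/2^(k-1)`.  The true frequency
#' of isoform j is `a(g) p(j)`; isoform order within each gene is
#' randomized.
#'
#' @param txome a [transcriptome()].
#' @param mode `"geometric"` or `"uniform"`.
#' @param gene_abundance optional named vector of positive per-gene
#'   abundances (normalized internally); default log-normal
#'   (`meanlog = 0`, `sdlog = 1.5`).
#' @param seed optional RNG seed.
#' @return data.frame (the truth table) with columns `tx_id`, `gene_id`,
#'   `gene_abundance`, `p_iso`, `true_freq`; `true_freq` sums to 1.
#' @export
assign_true_frequencies <- function(txome, mode = c("geometric", "uniform"),
                                    gene_abundance = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  genes <- unique(txome$tx$gene_id)
  if (is.null(gene_abundance)) {
    a <- rlnorm(length(genes), meanlog = 0, sdlog = 1.5)
    names(a) <- genes
  } else {
    stopifnot(all(genes %in% names(gene_abundance)),
              all(gene_abundance > 0))
    a <- gene_abundance[genes]
  }
  a <- a / sum(a)
  p_iso <- numeric(nrow(txome$tx))
  for (g in genes) {
    idx <- which(txome$tx$gene_id == g)
    k <- length(idx)
    p <- if (mode == "uniform") rep(1 / k, k)
         else if (k == 1L) 1
         else c(1 / 2^seq_len(k - 1L), 1 / 2^(k - 1L))
    p_iso[idx] <- p[sample.int(k)]
  }
  data.frame(tx_id = txome$tx$tx_id, gene_id = txome$tx$gene_id,
             gene_abundance = unname(a[txome$tx$gene_id]),
             p_iso = p_iso,
             true_freq = unname(a[txome$tx$gene_id]) * p_iso,
             stringsAsFactors = FALSE)
}

# inject uniform substitution errors; returns mutated reads and error count
# per read
.inject_errors <- function(reads, rate) {
  n <- length(reads)
  n_err <- integer(n)
  if (rate <= 0 || n == 0L) return(list(reads = reads, n_err = n_err))
  rl <- nchar(reads[1L])
  hit <- which(runif(n * rl) < rate)
  if (length(hit)) {
    ri <- (hit - 1L) %/% rl + 1L
    off <- (hit - 1L) %% rl + 1L
    bases <- c("A", "C", "G", "T")
    for (t in seq_along(hit)) {
      i <- ri[t]
      cur <- substr(reads[i], off[t], off[t])
      sub <- sample(setdiff(bases, cur), 1L)
      substr(reads[i], off[t], off[t]) <- sub
      n_err[i] <- n_err[i] + 1L
    }
  }
  list(reads = reads, n_err = n_err)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate RNA-Seq reads from a transcriptome
#'
#' Fragments are sampled consistently with the quantification model: a
#' fragment length k is drawn from `dist`, an isoform is chosen with
#' probability proportional to `true_freq(j) * max(l(j) - k + 1, 0)` (true
#' frequency times the number of valid start positions), and the start is
#' uniform among valid positions.  Single-end mode sequences one fragment
#' end (a random end under a nondirectional protocol); paired mode
#' sequences both.  Uniform substitution errors are injected with matching
#' constant-quality strings.
#'
#' @param txome a [transcriptome()].
#' @param seqs transcript sequences (`DNAStringSet` or named character).
#' @param truth truth table from [assign_true_frequencies()].
#' @param n_reads number of reads (or read pairs).
#' @param read_len read length; must not exceed the shortest fragment.
#' @param paired,directional protocol flags.
#' @param dist fragment-length distribution.
#' @param error_rate per-base substitution probability.
#' @param polya poly(A) tail length appended to transcripts before
#'   fragmenting (0 = off).
#' @param seed optional RNG seed.
#' @param fastq optional output path (single) or prefix (paired ->
#'   `<prefix>_1.fastq`, `<prefix>_2.fastq`).
#' @return object of class `"sim_reads"`: read sequences, origin table
#'   (true isoform and coordinates of every read), and the (possibly
#'   tail-extended) transcriptome.
#' @export
simulate_reads <- function(txome, seqs, truth, n_reads, read_len = 25L,
                           paired = FALSE, directional = FALSE,
                           dist = frag_dist_normal(250, 25),
                           error_rate = 0.001, polya = 0L, seed = NULL,
                           fastq = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(read_len <= dist$k[1L], n_reads >= 1)
  sc <- as.character(seqs)
  sc <- sc[txome$tx$tx_id]
  if (polya > 0L) {
    txome <- extend_poly_a(txome, polya)
    sc <- paste0(sc, strrep("A", polya))
  }
  L <- total_length(txome)
  f <- truth$true_freq[match(txome$tx$tx_id, truth$tx_id)]
  stopifnot(!anyNA(f))
  n <- as.integer(n_reads)
  k_r <- sample(dist$k, n, replace = TRUE, prob = dist$pmf)
  k_feas <- max(L[f > 0])
  n_resampled <- 0L
  while (any(bad <- k_r > k_feas)) {  # no isoform can hold the fragment
    n_resampled <- n_resampled + sum(bad)
    k_r[bad] <- sample(dist$k, sum(bad), replace = TRUE, prob = dist$pmf)
  }
  if (n_resampled > 0L)
    message("resampled ", n_resampled, " infeasible fragment length(s)")
  iso <- integer(n)
  for (kk in unique(k_r)) {
    idx <- which(k_r == kk)
    prob <- f * pmax(L - kk + 1, 0)
    iso[idx] <- sample.int(length(L), length(idx), replace = TRUE,
                           prob = prob)
  }
  s <- as.integer(floor(runif(n) * (L[iso] - k_r + 1)))
  q <- max(2L, as.integer(round(-10 * log10(max(error_rate, 1e-9)))))
  qual <- strrep(intToUtf8(33L + min(q, 40L)), read_len)
  if (!paired) {
    end5 <- if (directional) rep(TRUE, n) else runif(n) < 0.5
    reads <- character(n)
    reads[end5] <- substring(sc[iso[end5]], s[end5] + 1L,
                             s[end5] + read_len)
    if (any(!end5))
      reads[!end5] <- .revcomp(substring(sc[iso[!end5]],
        s[!end5] + k_r[!end5] - read_len + 1L, s[!end5] + k_r[!end5]))
    inj <- .inject_errors(reads, error_rate)
    origin <- data.frame(read_id = sprintf("r%07d", seq_len(n)),
                         tx = iso, tx_id = txome$tx$tx_id[iso],
                         frag_start = s, frag_len = k_r, end5 = end5,
                         n_err1 = inj$n_err, n_err2 = NA_integer_,
                         stringsAsFactors = FALSE)
    sim <- list(reads = inj$reads, mate2 = NULL, qual = qual,
                origin = origin, txome = txome, tx_seq = sc,
                read_len = read_len, paired = FALSE,
                directional = directional, error_rate = error_rate,
                dist = dist)
  } else {
    m1 <- unname(substring(sc[iso], s + 1L, s + read_len))
    m2 <- unname(.revcomp(substring(sc[iso], s + k_r - read_len + 1L,
                                    s + k_r)))
    i1 <- .inject_errors(m1, error_rate)
    i2 <- .inject_errors(m2, error_rate)
    origin <- data.frame(read_id = sprintf("r%07d", seq_len(n)),
                         tx = iso, tx_id = txome$tx$tx_id[iso],
                         frag_start = s, frag_len = k_r, end5 = TRUE,
                         n_err1 = i1$n_err, n_err2 = i2$n_err,
                         stringsAsFactors = FALSE)
    sim <- list(reads = i1$reads, mate2 = i2$reads, qual = qual,
                origin = origin, txome = txome, tx_seq = sc,
                read_len = read_len, paired = TRUE,
                directional = directional, error_rate = error_rate,
                dist = dist)
  }
  class(sim) <- "sim_reads"
  if (!is.null(fastq)) write_fastq(sim, fastq)
  sim
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("sim_reads: %d %s reads of length %d (error rate %g)\n",
              nrow(x$origin), if (x$paired) "paired" else "single",
              x$read_len, x$error_rate))
  invisible(x)
}

#' Write simulated reads to FASTQ
#'
#' @param sim a [simulate_reads()] object.
#' @param path output file (single-end) or prefix (paired-end).
#' @export
write_fastq <- function(sim, path) {
  emit <- function(ids, reads, file) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(paste0("@", ids, "\n", reads, "\n+\n", sim$qual), con)
  }
  if (!sim$paired) emit(sim$origin$read_id, sim$reads, path)
  else {
    emit(paste0(sim$origin$read_id, "/1"), sim$reads,
         paste0(path, "_1.fastq"))
    emit(paste0(sim$origin$read_id, "/2"), sim$mate2,
         paste0(path, "_2.fastq"))
  }
  invisible(path)
}

#' True alignments of simulated reads ("align-free" mode)
#'
#' Converts the simulator's origin table into an `alignment_set` as a
#' perfect aligner would produce: each read gets one alignment at its true
#' genome location, with the base-quality term Q computed from the injected
#' error counts.
#'
#' @param sim a [simulate_reads()] object.
#' @return an `alignment_set` suitable for [compute_weights()] /
#'   [quantify()].
#' @export
reads_to_alignments <- function(sim) {
  txome <- sim$txome
  o <- sim$origin
  n <- nrow(o)
  rl <- sim$read_len
  L <- total_length(txome)[o$tx]
  iso_sgn <- ifelse(txome$tx$strand[o$tx] == "+", 1L, -1L)
  eps <- phred_to_error(round(-10 * log10(max(sim$error_rate, 1e-9))))
  if (!sim$paired) {
    t0 <- ifelse(o$end5, o$frag_start, o$frag_start + o$frag_len - rl)
    pr <- cpp_genome_blocks(o$tx, as.numeric(t0), as.numeric(t0 + rl),
                            iso_sgn, as.numeric(L), txome$seg_start,
                            txome$seg_end, txome$seg_cum, txome$seg_off)
    aln <- data.frame(read = seq_len(n), chrom = txome$tx$chrom[o$tx],
                      strand = ifelse(o$end5, iso_sgn, -iso_sgn),
                      strand2 = 0L, paired = FALSE,
                      qa = (1 - eps)^(rl - o$n_err1) * eps^o$n_err1,
                      stringsAsFactors = FALSE)
    .alignment_set(o$read_id, aln, pr$off, pr$start, pr$end,
                   rep(1L, length(pr$start)))
  } else {
    t0a <- o$frag_start
    t0b <- o$frag_start + o$frag_len - rl
    p1 <- cpp_genome_blocks(o$tx, as.numeric(t0a), as.numeric(t0a + rl),
                            iso_sgn, as.numeric(L), txome$seg_start,
                            txome$seg_end, txome$seg_cum, txome$seg_off)
    p2 <- cpp_genome_blocks(o$tx, as.numeric(t0b), as.numeric(t0b + rl),
                            iso_sgn, as.numeric(L), txome$seg_start,
                            txome$seg_end, txome$seg_cum, txome$seg_off)
    aln <- data.frame(read = seq_len(n), chrom = txome$tx$chrom[o$tx],
                      strand = iso_sgn, strand2 = -iso_sgn, paired = TRUE,
                      qa = (1 - eps)^(2 * rl - o$n_err1 - o$n_err2) *
                           eps^(o$n_err1 + o$n_err2),
                      stringsAsFactors = FALSE)
    # interleave mate blocks per alignment
    l1 <- diff(p1$off); l2 <- diff(p2$off)
    off <- c(0L, cumsum(l1 + l2))
    pos1 <- sequence(l1, from = p1$off[-length(p1$off)] + 1L)
    pos2 <- sequence(l2, from = p2$off[-length(p2$off)] + 1L)
    dst1 <- sequence(l1, from = off[-length(off)] + 1L)
    dst2 <- sequence(l2, from = off[-length(off)] + l1 + 1L)
    bs <- integer(off[n + 1L]); be <- integer(off[n + 1L])
    bm <- integer(off[n + 1L])
    bs[dst1] <- p1$start[pos1]; be[dst1] <- p1$end[pos1]; bm[dst1] <- 1L
    bs[dst2] <- p2$start[pos2]; be[dst2] <- p2$end[pos2]; bm[dst2] <- 2L
    .alignment_set(o$read_id, aln, off, bs, be, bm)
  }
}

#' Write simulated reads as transcript-space SAM
#'
#' Emits one record per read (two for pairs) aligned against the transcript
#' sequences, with CIGAR, MD and NM tags, exercising the same input path an
#' external ungapped aligner would produce.
#'
#' @param sim a [simulate_reads()] object.
#' @param path output SAM path.
#' @export
write_sam <- function(sim, path) {
  txome <- sim$txome
  o <- sim$origin
  rl <- sim$read_len
  L <- total_length(txome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", txome$tx$tx_id, L)), con)
  md_of <- function(seq_fwd, tx, pos0) {
    ref <- substr(sim$tx_seq[tx], pos0 + 1L, pos0 + nchar(seq_fwd))
    r <- strsplit(seq_fwd, "")[[1L]]; rf <- strsplit(ref, "")[[1L]]
    mm <- which(r != rf)
    if (!length(mm)) return(list(md = as.character(nchar(seq_fwd)), nm = 0L))
    runs <- diff(c(0L, mm)) - 1L
    md <- paste0(paste0(runs, rf[mm], collapse = ""),
                 nchar(seq_fwd) - mm[length(mm)])
    list(md = md, nm = length(mm))
  }
  if (!sim$paired) {
    t0 <- ifelse(o$end5, o$frag_start, o$frag_start + o$frag_len - rl)
    for (i in seq_len(nrow(o))) {
      fwd <- if (o$end5[i]) sim$reads[i] else .revcomp(sim$reads[i])
      md <- md_of(fwd, o$tx[i], t0[i])
      writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tMD:Z:%s\tNM:i:%d",
        o$read_id[i], if (o$end5[i]) 0L else 16L, o$tx_id[i], t0[i] + 1L,
        rl, fwd, sim$qual, md$md, md$nm), con)
    }
  } else {
    t0a <- o$frag_start; t0b <- o$frag_start + o$frag_len - rl
    for (i in seq_len(nrow(o))) {
      fwd1 <- sim$reads[i]
      fwd2 <- .revcomp(sim$mate2[i])
      md1 <- md_of(fwd1, o$tx[i], t0a[i])
      md2 <- md_of(fwd2, o$tx[i], t0b[i])
      tlen <- o$frag_len[i]
      writeLines(c(
        sprintf("%s\t%d\t%s\t%d\t255\t%dM\t=\t%d\t%d\t%s\t%s\tMD:Z:%s\tNM:i:%d",
          o$read_id[i], 1L + 32L + 64L, o$tx_id[i], t0a[i] + 1L, rl,
          t0b[i] + 1L, tlen, fwd1, sim$qual, md1$md, md1$nm),
        sprintf("%s\t%d\t%s\t%d\t255\t%dM\t=\t%d\t%d\t%s\t%s\tMD:Z:%s\tNM:i:%d",
          o$read_id[i], 1L + 16L + 128L, o$tx_id[i], t0b[i] + 1L, rl,
          t0a[i] + 1L, -tlen, fwd2, sim$qual, md2$md, md2$nm)), con)
    }
  }
  invisible(path)
}

#' Export a transcriptome as GTF
#'
#' @param txome a [transcriptome()].
#' @param path output GTF path.
#' @export
write_gtf <- function(txome, path) {
  rows <- list()
  for (i in seq_len(nrow(txome$tx))) {
    ex <- tx_exons(txome, i)
    rows[[i]] <- data.frame(chrom = txome$tx$chrom[i], start = ex[, 1L] + 1L,
                            end = ex[, 2L], strand = txome$tx$strand[i],
                            gene = txome$tx$gene_id[i],
                            tx = txome$tx$tx_id[i])
  }
  d <- do.call(rbind, rows)
  lines <- sprintf(
    "%s\ttxem\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    d$chrom, d$start, d$end, d$strand, d$gene, d$tx)
  writeLines(lines, path)
  invisible(path)
}
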