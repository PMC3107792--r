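test_that("GTF loading builds lengths, clusters, and handles degenerate input", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G"; transcript_id "T1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "G"; transcript_id "T1";',
    'chr1\tsrc\texon\t101\t250\t.\t+\t.\tgene_id "G"; transcript_id "T2";',
    'chr2\tsrc\texon\t11\t40\t.\t-\t.\tgene_id "H"; transcript_id "T3";'),
    gtf)
  tx <- read_transcriptome(gtf)
  expect_equal(tx$tx$length[tx$tx$tx_id == "T1"], 200L)  # 100 + 100
  cl <- gene_clusters(tx)
  expect_equal(sort(cl$G), c("T1", "T2"))
  expect_equal(length(unlist(cl)), nrow(tx$tx))        # exact partition
  expect_equal(anyDuplicated(unlist(cl)), 0L)

  empty <- tempfile(fileext = ".gtf")
  writeLines(character(0), empty)
  expect_error(read_transcriptome(empty), "no transcripts")

  # a transcript feature without exon rows is skipped with a warning
  gtf2 <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t1\t500\t.\t+\t.\tgene_id "G"; transcript_id "TX";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G"; transcript_id "T1";'),
    gtf2)
  expect_warning(tx2 <- read_transcriptome(gtf2), "zero exons")
  expect_equal(tx2$tx$tx_id, "T1")

  # external gene map overrides GTF gene ids
  tx3 <- read_transcriptome(gtf, gene_map = data.frame(
    tx_id = c("T1", "T2"), gene_id = c("C1", "C2")))
  expect_equal(sort(unique(tx3$tx$gene_id)), c("C1", "C2", "H"))
})

test_that("transcript_interval maps blocks with exact intron contiguity", {
  tx <- toy_txome()
  # fully inside two exons of A1 (+ strand)
  expect_equal(transcript_interval(tx, "A1", rbind(c(150, 200), c(300, 310))),
               c(50, 110))
  # extending into the intron is incompatible
  expect_null(transcript_interval(tx, "A1", rbind(c(150, 210))))
  # skipping only part of the intron is incompatible
  expect_null(transcript_interval(tx, "A1", rbind(c(150, 200), c(290, 310))))
  expect_null(transcript_interval(tx, "A1", rbind(c(150, 190), c(300, 310))))
  # minus strand: same blocks on a mirrored isoform reverse the interval
  txm <- transcriptome("M1", "GM", "chr1", "-",
                       list(cbind(c(100L, 300L), c(200L, 400L))))
  expect_equal(transcript_interval(txm, "M1", rbind(c(150, 200), c(300, 310))),
               c(90, 150))
  expect_error(transcript_interval(tx, "A1", rbind(c(300, 310), c(150, 200))),
               "sorted")
})

test_that("genome projection round-trips through transcript_interval", {
  tr <- simulate_transcriptome(5, 1:4, seed = 42)
  tx <- tr$txome
  set.seed(99)
  for (rep in 1:50) {
    i <- sample.int(nrow(tx$tx), 1)
    L <- total_length(tx)[i]
    t0 <- sample.int(L - 30L, 1) - 1L
    t1 <- t0 + sample.int(min(30L, L - t0), 1)
    bl <- genome_blocks(tx, i, t0, t1)
    expect_equal(transcript_interval(tx, i, bl), c(t0, t1))
  }
})

test_that("poly(A) extension lengthens transcripts and aligns tail reads", {
  tx <- toy_txome()
  expect_identical(extend_poly_a(tx, 0L)$tx$length + 0L, tx$tx$length)
  txp <- extend_poly_a(tx, 200L)
  expect_equal(total_length(txp), tx$tx$length + 200L)
  # a block entirely inside the shared tail region of A1/A2: A1 and A2 do
  # not share a terminal exon, but two isoforms that do share one also
  # share the virtual tail coordinates
  tx2 <- transcriptome(c("X1", "X2"), c("GX", "GX"), c("c", "c"),
                       c("+", "+"),
                       list(cbind(c(0L, 500L), c(100L, 700L)),
                            cbind(c(300L, 500L), c(400L, 700L))))
  tx2 <- extend_poly_a(tx2, 200L)
  tail_block <- rbind(c(720, 745))  # 20 bases past the shared 3' exon end
  expect_false(is.null(transcript_interval(tx2, "X1", tail_block)))
  expect_false(is.null(transcript_interval(tx2, "X2", tail_block)))
})

test_that("repeat masking adjusts lengths and flags overlapping reads", {
  tx1 <- transcriptome("T", "G", "chr1", "+",
                       list(cbind(100L, 200L)))  # single 100-base exon
  # no repeats: predicate false, lengths unchanged
  rm0 <- repeat_mask(tx1, data.frame(chrom = "chrX", start = 0, end = 10), 10)
  expect_equal(rm0$txome$tx$adj_length, 100)
  expect_false(rm0$discard("chr1", rbind(c(120, 145))))
  # one masked base, read_len 1 removes exactly one start
  rm1 <- repeat_mask(tx1, data.frame(chrom = "chr1", start = 150, end = 151), 1)
  expect_equal(rm1$txome$tx$adj_length, 99)
  # repeat [150,160) inside exon [100,200), read_len 10: transcript starts
  # 41..59 are masked, adjustment 19
  rm2 <- repeat_mask(tx1, data.frame(chrom = "chr1", start = 150, end = 160), 10)
  expect_equal(rm2$txome$tx$adj_length, 100 - 19)
  expect_true(rm2$discard("chr1", rbind(c(155, 165))))
  expect_false(rm2$discard("chr1", rbind(c(100, 110))))
})

test_that("repeat-adjusted length matches brute-force start enumeration", {
  set.seed(7)
  for (rep in 1:12) {
    # small random multi-exon isoform on a random strand
    n_ex <- sample(2:4, 1)
    len <- sample(30:80, n_ex, replace = TRUE)
    gap <- sample(20:60, n_ex - 1, replace = TRUE)
    st <- cumsum(c(50L, head(len, -1L) + gap))
    tx <- transcriptome("T", "G", "chr1", sample(c("+", "-"), 1),
                        list(cbind(st, st + len)))
    span <- c(min(st), max(st + len))
    nrep <- sample.int(3, 1)
    rs <- sort(sample(span[1]:span[2], nrep))
    reps <- data.frame(chrom = "chr1", start = rs,
                       end = rs + sample(3:25, nrep, replace = TRUE))
    rl <- sample(5:20, 1)
    rm_ <- repeat_mask(tx, reps, rl)
    L <- total_length(tx)[1]
    bad <- 0L
    for (s in 0:(L - rl)) {
      bl <- genome_blocks(tx, 1, s, s + rl)
      if (rm_$discard("chr1", bl)) bad <- bad + 1L
    }
    expect_equal(rm_$txome$tx$adj_length[1], L - bad)
  }
})
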