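test_that("true frequency assignment follows the stated distributions", {
  tx4 <- transcriptome(paste0("T", 1:4), rep("G", 4), rep("c", 4),
                       rep("+", 4),
                       replicate(4, cbind(0L, 1000L), simplify = FALSE))
  tu <- assign_true_frequencies(tx4, "uniform", seed = 1)
  expect_equal(tu$p_iso, rep(0.25, 4))
  tx3 <- transcriptome(paste0("T", 1:3), rep("G", 3), rep("c", 3),
                       rep("+", 3),
                       replicate(3, cbind(0L, 1000L), simplify = FALSE))
  tg <- assign_true_frequencies(tx3, "geometric", seed = 2)
  expect_equal(sort(tg$p_iso, decreasing = TRUE), c(1 / 2, 1 / 4, 1 / 4))
  tx1 <- transcriptome("T1", "G", "c", "+", list(cbind(0L, 1000L)))
  expect_equal(assign_true_frequencies(tx1, "geometric")$p_iso, 1)
  expect_equal(sum(tg$true_freq), 1)
  # external abundances are honored
  tg2 <- assign_true_frequencies(tx3, "uniform",
                                 gene_abundance = c(G = 7))
  expect_equal(sum(tg2$true_freq), 1)
})

test_that("simulated transcriptomes are deterministic and self-consistent", {
  a <- simulate_transcriptome(5, 1:4, seed = 9)
  b <- simulate_transcriptome(5, 1:4, seed = 9)
  expect_identical(a$txome$tx, b$txome$tx)
  expect_identical(as.character(a$seqs), as.character(b$seqs))
  # isoform length = sum of exon lengths = sequence length
  for (i in seq_len(nrow(a$txome$tx))) {
    ex <- txem:::tx_exons(a$txome, i)
    expect_equal(a$txome$tx$length[i], sum(ex[, 2] - ex[, 1]))
  }
  expect_equal(unname(nchar(as.character(a$seqs))), a$txome$tx$length)
  one <- simulate_transcriptome(1, 1, seed = 3)
  expect_equal(nrow(one$txome$tx), 1L)
})

test_that("error-free reads are exact transcript substrings", {
  tr <- simulate_transcriptome(3, 1:3, seed = 21)
  truth <- assign_true_frequencies(tr$txome, "uniform", seed = 22)
  sim <- simulate_reads(tr$txome, tr$seqs, truth, 300, error_rate = 0,
                        seed = 23)
  sc <- as.character(tr$seqs)[sim$origin$tx_id]
  o <- sim$origin
  ref_sense <- substring(sc, o$frag_start + 1, o$frag_start + 25)
  ref_anti <- substring(sc, o$frag_start + o$frag_len - 24,
                        o$frag_start + o$frag_len)
  got_sense <- sim$reads[o$end5]
  expect_identical(got_sense, unname(ref_sense[o$end5]))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sim$reads[!o$end5])))
  expect_identical(rc, unname(ref_anti[!o$end5]))
})

test_that("reads and FASTQ output are reproducible under a fixed seed", {
  tr <- simulate_transcriptome(3, 1:3, seed = 31)
  truth <- assign_true_frequencies(tr$txome, "geometric", seed = 32)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  s1 <- simulate_reads(tr$txome, tr$seqs, truth, 200, seed = 33, fastq = f1)
  s2 <- simulate_reads(tr$txome, tr$seqs, truth, 200, seed = 33, fastq = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$origin, s2$origin)
  expect_equal(length(readLines(f1)), 4 * 200)
  expect_equal(nrow(s1$origin), 200L)   # origin row per read
})

test_that("paired mode emits proper mate pairs covering the fragment ends", {
  tr <- simulate_transcriptome(2, 2, seed = 41)
  truth <- assign_true_frequencies(tr$txome, "uniform", seed = 42)
  sim <- simulate_reads(tr$txome, tr$seqs, truth, 100, paired = TRUE,
                        error_rate = 0, seed = 43)
  expect_equal(length(sim$reads), 100L)
  expect_equal(length(sim$mate2), 100L)
  sc <- as.character(tr$seqs)[sim$origin$tx_id]
  o <- sim$origin
  expect_identical(sim$reads,
                   unname(substring(sc, o$frag_start + 1, o$frag_start + 25)))
  # mate 2 reads the 3' fragment end on the opposite strand
  m2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sim$mate2)))
  expect_identical(m2, unname(substring(sc, o$frag_start + o$frag_len - 24,
                                 o$frag_start + o$frag_len)))
  alns <- reads_to_alignments(sim)
  expect_true(all(alns$aln$strand == -alns$aln$strand2))
})

test_that("poly(A) simulation keeps reads alignable in the extended space", {
  tr <- simulate_transcriptome(2, 1:2, seed = 51)
  truth <- assign_true_frequencies(tr$txome, "uniform", seed = 52)
  sim <- simulate_reads(tr$txome, tr$seqs, truth, 200, polya = 200L,
                        error_rate = 0, seed = 53)
  expect_equal(total_length(sim$txome), tr$txome$tx$length + 200L)
  # some fragments should reach into the tail; all reads must still map
  w <- compute_weights(reads_to_alignments(sim), sim$txome, sim$dist)
  expect_equal(w$n_dropped, 0L)
})
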