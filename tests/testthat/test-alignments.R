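test_that("base-quality factor Q multiplies match and mismatch probabilities", {
  expect_equal(alignment_base_prob(c(0.01, 0.1), c(TRUE, TRUE)), 0.99 * 0.9)
  expect_equal(alignment_base_prob(c(0.01, 0.1), c(TRUE, FALSE)), 0.99 * 0.1)
  expect_equal(alignment_base_prob(numeric(0), logical(0)), 1)
})

test_that("orientation factor O encodes the protocol rules", {
  # single nondirectional: antisense reads are fine (random fragment end)
  expect_equal(orientation_factor(-1L, 1L, paired = FALSE,
                                  directional = FALSE), 1)
  # single directional: must match the isoform strand
  expect_equal(orientation_factor(-1L, 1L, paired = FALSE,
                                  directional = TRUE), 0)
  # paired: mates on the same strand never consistent
  expect_equal(orientation_factor(1L, 1L, paired = TRUE, mate2_strand = 1L,
                                  t1 = c(0, 25), t2 = c(200, 225)), 0)
  # proper pair pointing at each other
  expect_equal(orientation_factor(1L, 1L, paired = TRUE, mate2_strand = -1L,
                                  t1 = c(0, 25), t2 = c(200, 225)), 1)
  # outward-facing pair (leftmost mate antisense) is inconsistent
  expect_equal(orientation_factor(-1L, 1L, paired = TRUE, mate2_strand = 1L,
                                  t1 = c(0, 25), t2 = c(200, 225)), 0)
})

test_that("single-end fragment length bound u counts to the proper end", {
  expect_equal(single_end_length_bound(1000, c(100, 125), sense = TRUE), 900)
  expect_equal(single_end_length_bound(1000, c(375, 400), sense = FALSE), 400)
  expect_equal(single_end_length_bound(1000, c(0, 25), sense = TRUE), 1000)
})

test_that("fragment factor F uses pmf for pairs and cdf for single ends", {
  d <- frag_dist_normal(250, 25, 150, 350)
  expect_equal(fragment_factor(d, TRUE, k = 250), max(d$pmf))
  expect_equal(fragment_factor(d, FALSE, u = 900), 1)
  expect_equal(fragment_factor(d, FALSE, u = 100), 0)
  expect_equal(fragment_factor(d, TRUE, k = 500), 0)
})

test_that("SAM round trip reproduces align-free alignments", {
  inst <- rand_instance(301, n_genes = 3, n_reads = 60)
  sam <- tempfile(fileext = ".sam")
  write_sam(inst$sim, sam)
  parsed <- read_alignments(sam, inst$sim$txome)
  direct <- inst$alns
  expect_equal(length(parsed$read_id), length(direct$read_id))
  m <- match(direct$read_id, parsed$read_id)
  expect_false(anyNA(m))
  pa <- parsed$aln[order(parsed$aln$read), ]
  da <- direct$aln
  # same genome span, strand and Q for every read
  expect_equal(pa$start[order(m[da$read])], da$start[order(da$read)])
  expect_equal(pa$strand[order(m[da$read])], da$strand[order(da$read)])
  expect_equal(sort(pa$qa), sort(da$qa), tolerance = 1e-12)
  # and identical downstream weights
  d <- inst$sim$dist
  wp <- compute_weights(parsed, inst$sim$txome, d)
  wd <- compute_weights(direct, inst$sim$txome, d)
  wp$weights$read <- parsed$read_id[wp$weights$read]
  wd$weights$read <- direct$read_id[wd$weights$read]
  wp$weights <- wp$weights[order(wp$weights$read, wp$weights$tx), ]
  wd$weights <- wd$weights[order(wd$weights$read, wd$weights$tx), ]
  expect_equal(wp$weights$w, wd$weights$w, tolerance = 1e-12)
  expect_equal(wp$weights$tx, wd$weights$tx)
})

test_that("paired SAM parsing groups mates and computes pair weights", {
  inst <- rand_instance(707, n_genes = 2, n_reads = 30, paired = TRUE)
  sam <- tempfile(fileext = ".sam")
  write_sam(inst$sim, sam)
  parsed <- read_alignments(sam, inst$sim$txome)
  expect_true(all(parsed$aln$paired))
  d <- inst$sim$dist
  wp <- compute_weights(parsed, inst$sim$txome, d)
  wd <- compute_weights(inst$alns, inst$sim$txome, d)
  expect_equal(nrow(wp$weights), nrow(wd$weights))
  expect_equal(sort(wp$weights$w), sort(wd$weights$w), tolerance = 1e-12)
})

test_that("parser handles missing qualities, bad references, empty input", {
  tx <- toy_txome()
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", tx$tx$tx_id, total_length(tx)),
               "r1\t0\tA1\t11\t255\t10M\t*\t0\t0\tACGTACGTAC\t*\tMD:Z:10"),
             sam)
  a <- read_alignments(sam, tx)
  expect_equal(a$aln$qa, (1 - phred_to_error(30))^10)

  sam2 <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:nope\tLN:500",
               "r1\t0\tnope\t11\t255\t10M\t*\t0\t0\tACGTACGTAC\t*"), sam2)
  expect_error(read_alignments(sam2, tx), "unknown reference")

  sam3 <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", tx$tx$tx_id, total_length(tx)),
               "r1\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t*"), sam3)
  expect_warning(a3 <- read_alignments(sam3, tx), "0 mapped")
  expect_equal(nrow(a3$aln), 0L)
  expect_equal(a3$n_unmapped, 1L)
})

test_that("alignments identical in genome space are merged before weighting", {
  tx <- toy_txome()  # A1 and A2 share exons [100,200) and [300,400)
  sam <- tempfile(fileext = ".sam")
  # the same read reported against both transcripts at the same locus
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", tx$tx$tx_id, total_length(tx)),
               "r1\t0\tA1\t11\t255\t10M\t*\t0\t0\tACGTACGTAC\t*\tMD:Z:10",
               "r1\t0\tA2\t11\t255\t10M\t*\t0\t0\tACGTACGTAC\t*\tMD:Z:10"),
             sam)
  a <- read_alignments(sam, tx)
  expect_equal(nrow(a$aln), 1L)  # deduplicated: same genome blocks
  w <- compute_weights(a, tx, frag_dist_normal(150, 10, 100, 200))
  # one alignment contributes once per isoform (no double counting)
  expect_equal(nrow(w$weights), 2L)
})

test_that("alignments with indels or clipping are rejected with a count", {
  tx <- toy_txome()
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", tx$tx$tx_id, total_length(tx)),
               "r1\t0\tA1\t11\t255\t4M2I4M\t*\t0\t0\tACGTACGTAC\t*",
               "r2\t0\tA1\t11\t255\t10M\t*\t0\t0\tACGTACGTAC\t*\tMD:Z:10"),
             sam)
  a <- read_alignments(sam, tx)
  expect_equal(a$n_rejected, 1L)
  expect_equal(nrow(a$aln), 1L)
})
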