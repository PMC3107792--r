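# Shared fixtures and independent oracles used across the test files.

# hand-built two-gene transcriptome:
#   gene GA (+): A1 = [100,200)+[300,400), A2 = [100,200)+[300,400)+[500,600)
#   gene GB (-): B1 = [1000,1200)+[1400,1500)
toy_txome <- function() {
  transcriptome(
    tx_id = c("A1", "A2", "B1"),
    gene_id = c("GA", "GA", "GB"),
    chrom = rep("chr1", 3),
    strand = c("+", "+", "-"),
    exons = list(cbind(c(100L, 300L), c(200L, 400L)),
                 cbind(c(100L, 300L, 500L), c(200L, 400L, 600L)),
                 cbind(c(1000L, 1400L), c(1200L, 1500L))))
}

# blocks of alignment i / mate m from an alignment_set
aln_blocks <- function(alns, i, mate = 1L) {
  idx <- (alns$blk_off[i] + 1L):alns$blk_off[i + 1L]
  sel <- alns$blk_mate[idx] == mate
  cbind(alns$blk_start[idx][sel], alns$blk_end[idx][sel])
}

# brute-force all-pairs compatibility oracle, built from the R-level
# primitives (transcript_interval / orientation_factor / fragment_factor)
# and therefore independent of the C++ line sweep it checks
brute_weights <- function(alns, txome, dist, directional = FALSE) {
  L <- total_length(txome)
  sgn <- ifelse(txome$tx$strand == "+", 1L, -1L)
  res <- list()
  for (i in seq_len(nrow(alns$aln))) {
    a <- alns$aln[i, ]
    for (j in seq_len(nrow(txome$tx))) {
      if (txome$tx$chrom[j] != a$chrom) next
      t1 <- transcript_interval(txome, j, aln_blocks(alns, i, 1L))
      if (is.null(t1)) next
      if (!a$paired) {
        sense <- a$strand == sgn[j]
        O <- orientation_factor(a$strand, sgn[j], paired = FALSE,
                                directional = directional)
        u <- single_end_length_bound(L[j], t1, sense)
        w <- a$qa * fragment_factor(dist, FALSE, u = u) * O
      } else {
        t2 <- transcript_interval(txome, j, aln_blocks(alns, i, 2L))
        if (is.null(t2)) next
        O <- orientation_factor(a$strand, sgn[j], paired = TRUE,
                                directional = directional,
                                mate2_strand = a$strand2, t1 = t1, t2 = t2)
        k <- max(t1[2L], t2[2L]) - min(t1[1L], t2[1L])
        w <- a$qa * fragment_factor(dist, TRUE, k = k) * O
      }
      if (w > 0)
        res[[length(res) + 1L]] <- data.frame(read = a$read, tx = j, w = w)
    }
  }
  if (!length(res))
    return(data.frame(read = integer(0), tx = integer(0), w = numeric(0)))
  d <- do.call(rbind, res)
  agg <- stats::aggregate(w ~ read + tx, d, sum)
  agg <- agg[order(agg$read, agg$tx), c("read", "tx", "w")]
  rownames(agg) <- NULL
  agg
}

# small random instance: transcriptome + simulated single/paired reads
rand_instance <- function(seed, n_genes = 3, n_reads = 40, paired = FALSE,
                          read_len = 25, dist = frag_dist_normal(250, 25)) {
  tr <- simulate_transcriptome(n_genes, 1:4, seed = seed)
  truth <- assign_true_frequencies(tr$txome, "uniform", seed = seed + 1)
  sim <- simulate_reads(tr$txome, tr$seqs, truth, n_reads,
                        read_len = read_len, paired = paired, dist = dist,
                        error_rate = 0.002, seed = seed + 2)
  list(tr = tr, truth = truth, sim = sim, alns = reads_to_alignments(sim))
}

# exhaustive simplex grid search of the component log-likelihood
# (independent EM oracle); step applies to each coordinate
grid_search_mle <- function(W, m, ltilde, step = 1e-3) {
  k <- ncol(W)
  ll <- function(fmat) {  # columns are candidate frequency vectors
    A <- W %*% fmat
    A[A <= 0] <- NA
    colSums(m * log(A)) - sum(m) * log(as.numeric(ltilde %*% fmat))
  }
  if (k == 1L) return(1)
  g <- seq(0, 1, by = step)
  if (k == 2L) {
    fmat <- rbind(g, 1 - g)
    v <- ll(fmat)
    return(fmat[, which.max(v)])
  }
  stopifnot(k == 3L)
  best <- NULL; best_v <- -Inf
  n1 <- length(g)
  chunk <- 200L
  for (lo in seq(1L, n1, by = chunk)) {
    hi <- min(lo + chunk - 1L, n1)
    cand <- list()
    for (ii in lo:hi) {
      f1 <- g[ii]
      f2 <- seq(0, 1 - f1 + 1e-12, by = step)
      cand[[length(cand) + 1L]] <- rbind(f1, f2, pmax(1 - f1 - f2, 0))
    }
    fmat <- do.call(cbind, cand)
    v <- ll(fmat)
    i <- which.max(v)
    if (length(i) && v[i] > best_v) { best_v <- v[i]; best <- fmat[, i] }
  }
  best
}

# random small component (read classes with discrete weights so classes
# genuinely collapse); every isoform is guaranteed support
rand_component <- function(seed, max_iso = 3, n_reads = 200) {
  set.seed(seed)
  k <- sample.int(max_iso, 1)
  ltilde <- runif(k, 500, 1500)
  levels <- c(0.5, 1)
  ent_tx <- integer(0); ent_w <- numeric(0); off <- 0L
  # ensure a unique read per isoform, then random supports
  supports <- c(lapply(seq_len(k), function(j) j),
                replicate(n_reads - k, {
                  s <- which(runif(k) < 0.6)
                  if (!length(s)) s <- sample.int(k, 1)
                  s
                }, simplify = FALSE))
  W <- matrix(0, length(supports), k)
  for (i in seq_along(supports)) {
    s <- supports[[i]]
    W[i, s] <- sample(levels, length(s), replace = TRUE)
  }
  # collapse identical rows into classes
  key <- apply(W, 1, paste, collapse = ",")
  u <- !duplicated(key)
  m <- as.numeric(table(factor(key, levels = key[u])))
  list(W = W[u, , drop = FALSE], m = m, ltilde = ltilde)
}
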