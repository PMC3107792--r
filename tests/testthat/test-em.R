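test_that("E-step allocates class multiplicities by posterior weight", {
  W <- matrix(c(1, 1), nrow = 1)
  expect_equal(e_step(W, 10, c(0.5, 0.5)), c(5, 5))
  expect_equal(e_step(W, 10, c(0.8, 0.2)), c(8, 2))
  expect_equal(e_step(matrix(c(0.9, 0.1), nrow = 1), 10, c(0.5, 0.5)),
               c(9, 1))
  # zero-denominator classes are skipped
  W2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(e_step(W2, c(5, 3), c(1, 0)), c(5, 0))
})

test_that("M-step renormalizes length-corrected coverages", {
  expect_equal(m_step(c(100, 100), c(1000, 500)), c(1 / 3, 2 / 3))
  expect_equal(m_step(50, 700), 1)
  expect_equal(m_step(c(0, 100), c(800, 800)), c(0, 1))
  expect_warning(f <- m_step(c(0, 0), c(1, 1)), "uniform")
  expect_equal(f, c(0.5, 0.5))
})

test_that("unambiguous classes converge in one step to coverage shares", {
  W <- diag(3)
  m <- c(60, 30, 10)
  lt <- c(1000, 500, 250)
  res <- run_component_em(W, m, lt, tol = 1e-12)
  cv <- m / lt
  expect_equal(res$f, cv / sum(cv), tolerance = 1e-12)
  expect_lte(res$iterations, 2L)
  expect_equal(sum(res$n), sum(m))
})

test_that("EM matches the grid-search likelihood maximizer on a 2-isoform toy", {
  # 60 reads unique to A, 20 unique to B, 20 shared with equal weights
  W <- rbind(c(1, 0), c(0, 1), c(1, 1))
  m <- c(60, 20, 20)
  lt <- c(800, 800)
  em <- run_component_em(W, m, lt, tol = 1e-12, max_iter = 100000L)
  grid <- grid_search_mle(W, m, lt, step = 1e-4)
  expect_lt(max(abs(em$f - grid)), 1e-3)
})

test_that("log-likelihood is non-decreasing on random components", {
  for (seed in c(1, 2, 3, 4, 5)) {
    cp <- rand_component(seed, max_iso = 3, n_reads = 120)
    res <- run_component_em(cp$W, cp$m, cp$ltilde, trace = TRUE,
                            max_iter = 2000L)
    expect_true(all(diff(res$ll_trace) >= -1e-12))
    expect_equal(sum(res$n), sum(cp$m), tolerance = 1e-6)
  }
})

test_that("results are invariant to isoform permutation", {
  cp <- rand_component(77, max_iso = 3, n_reads = 150)
  res <- run_component_em(cp$W, cp$m, cp$ltilde, tol = 1e-12)
  p <- rev(seq_len(ncol(cp$W)))
  res_p <- run_component_em(cp$W[, p, drop = FALSE], cp$m, cp$ltilde[p],
                            tol = 1e-12)
  expect_equal(res_p$f, res$f[p], tolerance = 1e-9)
})

test_that("random initialization with a seed is reproducible", {
  cp <- rand_component(12, max_iso = 3, n_reads = 100)
  r1 <- run_component_em(cp$W, cp$m, cp$ltilde, init = "random", seed = 4)
  r2 <- run_component_em(cp$W, cp$m, cp$ltilde, init = "random", seed = 4)
  expect_identical(r1$f, r2$f)
})

test_that("component combination preserves normalization and zeros", {
  lt <- c(1000, 1000, 500, 800)
  r1 <- list(f = c(0.5, 0.5), n = c(50, 50))
  r2 <- list(f = 1, n = 30)
  glob <- combine_components(list(r1, r2), list(c(1L, 2L), 3L), 4L, lt)
  expect_equal(sum(glob$f), 1)
  expect_equal(glob$f[4], 0)   # isoform with no compatible reads
  # two identical single-isoform components get equal global frequency
  g2 <- combine_components(list(list(n = 10), list(n = 10)),
                           list(1L, 2L), 2L, c(700, 700))
  expect_equal(g2$f[1], g2$f[2])
})

test_that("joint EM equals per-component EM plus combination", {
  cpA <- rand_component(31, max_iso = 3, n_reads = 150)
  cpB <- rand_component(32, max_iso = 2, n_reads = 100)
  kA <- ncol(cpA$W); kB <- ncol(cpB$W)
  W <- rbind(cbind(cpA$W, matrix(0, nrow(cpA$W), kB)),
             cbind(matrix(0, nrow(cpB$W), kA), cpB$W))
  m <- c(cpA$m, cpB$m)
  lt <- c(cpA$ltilde, cpB$ltilde)
  joint <- run_component_em(W, m, lt, tol = 1e-11, max_iter = 50000L)
  rA <- run_component_em(cpA$W, cpA$m, cpA$ltilde, tol = 1e-11,
                         max_iter = 50000L)
  rB <- run_component_em(cpB$W, cpB$m, cpB$ltilde, tol = 1e-11,
                         max_iter = 50000L)
  glob <- combine_components(list(rA, rB),
                             list(seq_len(kA), kA + seq_len(kB)),
                             kA + kB, lt)
  expect_lt(max(abs(joint$f - glob$f)), 1e-9)
})

test_that("gene expression sums member isoform frequencies", {
  f <- c(0.2, 0.3, 0.5)
  g <- gene_expression(f, c("G1", "G1", "G2"))
  expect_equal(unname(g["G1"]), 0.5)
  expect_equal(unname(g["G2"]), 0.5)
  expect_equal(sum(g), 1)
})
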