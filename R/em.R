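#' Expectation step: expected read counts per isoform
#'
#' Given current frequencies `f`, allocates each read class fractionally to
#' its compatible isoforms: the posterior probability that a class-`c` read
#' came from isoform `j` is `f(j) w_cj / sum_j' f(j') w_cj'`, and
#' `n(j)` sums these posteriors weighted by class multiplicities.  Classes
#' whose denominator is zero (no support under `f`) are skipped.
#'
#' @param W class-by-isoform weight matrix.
#' @param m class multiplicities.
#' @param f isoform frequencies (non-negative, positive sum).
#' @return expected counts `n`, one per isoform.
#' @export
e_step <- function(W, m, f) {
  stopifnot(all(f >= 0), sum(f) > 0, nrow(W) == length(m),
            ncol(W) == length(f))
  denom <- as.numeric(W %*% f)
  pos <- denom > 0
  if (!all(pos)) { W <- W[pos, , drop = FALSE]; m <- m[pos]; denom <- denom[pos] }
  f * as.numeric(crossprod(W, m / denom))
}

#' Maximization step: length-normalized frequency re-estimation
#'
#' Converts expected counts to length-normalized coverages
#' `c(j) = n(j) / ltilde(j)` and renormalizes: `f(j) = c(j) / sum(c)`.
#'
#' @param n expected counts from [e_step()].
#' @param ltilde effective lengths (positive).
#' @return updated frequencies summing to 1.
#' @export
m_step <- function(n, ltilde) {
  stopifnot(all(ltilde > 0), length(n) == length(ltilde))
  cv <- n / ltilde
  s <- sum(cv)
  if (s == 0) {
    warning("all coverages zero; falling back to uniform frequencies")
    return(rep(1 / length(n), length(n)))
  }
  cv / s
}

# observed-data log-likelihood (up to an additive constant):
# sum_c m_c log(sum_j f_j w_cj) - M log(sum_j f_j ltilde_j),
# i.e. the fragment-sampling model with per-fragment isoform probability
# proportional to f(j) * ltilde(j) and P(r | j) = w_rj / ltilde(j).
component_loglik <- function(W, m, f, ltilde) {
  denom <- as.numeric(W %*% f)
  pos <- denom > 0
  sum(m[pos] * log(denom[pos])) - sum(m[pos]) * log(sum(f * ltilde))
}

#' Run EM on one compatibility component
#'
#' Alternates [e_step()] and [m_step()] until the maximum absolute
#' frequency change drops below `tol` or `max_iter` is reached.  The
#' observed-data log-likelihood is non-decreasing across iterations.
#'
#' @param W,m read classes (weight matrix, multiplicities).
#' @param ltilde effective lengths of the component's isoforms.
#' @param init `"uniform"` (deterministic default) or `"random"`.
#' @param seed optional seed for random initialization.
#' @param tol convergence tolerance on `max |delta f|`.
#' @param max_iter iteration cap.
#' @param trace keep the per-iteration log-likelihood.
#' @return list with `f`, `n`, `iterations`, `converged`, `loglik` and
#'   (optionally) `ll_trace`.
#' @export
run_component_em <- function(W, m, ltilde, init = c("uniform", "random"),
                             seed = NULL, tol = 1e-8, max_iter = 10000L,
                             trace = FALSE) {
  init <- match.arg(init)
  k <- length(ltilde)
  stopifnot(nrow(W) >= 1, ncol(W) == k)
  if (init == "uniform") f <- rep(1 / k, k)
  else {
    if (!is.null(seed)) set.seed(seed)
    f <- runif(k); f <- f / sum(f)
  }
  ll_trace <- if (trace) numeric(0) else NULL
  converged <- FALSE
  n <- numeric(k)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    n <- e_step(W, m, f)
    f_new <- m_step(n, ltilde)
    if (trace) ll_trace <- c(ll_trace, component_loglik(W, m, f_new, ltilde))
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(f = f, n = e_step(W, m, f), iterations = iter, converged = converged,
       loglik = component_loglik(W, m, f, ltilde), ll_trace = ll_trace)
}

#' Assemble a global frequency estimate from per-component EM results
#'
#' Components are independent: isoform frequencies in one component do not
#' affect any other, so per-component expected counts are converted to
#' coverages `c(j) = n(j) / ltilde(j)` and normalized globally.  Isoforms in
#' no component (no compatible reads) get frequency 0.
#'
#' @param results list of [run_component_em()] results.
#' @param iso_sets list of isoform index vectors, parallel to `results`.
#' @param n_tx total number of isoforms.
#' @param ltilde global effective lengths (length `n_tx`).
#' @return list with global `f` (sums to 1) and `n` (expected counts).
#' @export
combine_components <- function(results, iso_sets, n_tx, ltilde) {
  n <- numeric(n_tx)
  for (i in seq_along(results)) n[iso_sets[[i]]] <- results[[i]]$n
  cv <- ifelse(ltilde > 0, n / ltilde, 0)
  s <- sum(cv)
  list(f = if (s > 0) cv / s else cv, n = n)
}

#' Gene-level expression from isoform frequencies
#'
#' Gene expression is the sum of its member isoform frequencies.
#'
#' @param f isoform frequencies.
#' @param gene_id gene of each isoform.
#' @return named numeric vector of gene frequencies.
#' @export
gene_expression <- function(f, gene_id) {
  v <- rowsum(f, gene_id)
  setNames(as.numeric(v), rownames(v))
}
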