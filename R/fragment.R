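#' Discretized normal fragment-length distribution
#'
#' RNA-Seq library preparation tightly controls the cDNA fragment (insert)
#' length; the resulting distribution p(k) is modeled as a normal
#' discretized over an integer support and renormalized.  `sd = 0` yields a
#' point mass at `round(mean)`.
#'
#' @param mean mean fragment length (bases).
#' @param sd standard deviation (bases).
#' @param k_min,k_max integer support bounds; default `mean +/- 4 sd`,
#'   clipped at 1.
#' @return object of class `"frag_dist"` with fields `k` (support), `pmf`,
#'   `cdf`, `mean`, `sd` (moments of the discretized distribution) and `mu`
#'   (the nominal mean, used by the fast effective-length approximation).
#' @examples
#' d <- frag_dist_normal(250, 25)
#' sum(d$pmf)  # 1
#' @export
frag_dist_normal <- function(mean, sd, k_min = NULL, k_max = NULL) {
  stopifnot(sd >= 0, mean > 0)
  if (is.null(k_min)) k_min <- max(1, round(mean - 4 * sd))
  if (is.null(k_max)) k_max <- round(mean + 4 * sd)
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  stopifnot(k_min >= 1, k_max >= k_min)
  if (sd == 0) {
    m <- as.integer(round(mean))
    if (m < k_min || m > k_max)
      stop("point-mass mean outside [k_min, k_max]")
    k <- k_min:k_max
    pmf <- as.numeric(k == m)
  } else {
    k <- k_min:k_max
    pmf <- pnorm(k + 0.5, mean, sd) - pnorm(k - 0.5, mean, sd)
    pmf <- pmf / sum(pmf)
  }
  .frag_dist(k, pmf, mu = mean)
}

#' Empirical fragment-length distribution
#'
#' Histogram of observed fragment lengths (e.g. from uniquely mapping proper
#' pairs), lightly smoothed with a 3-point moving average and renormalized.
#'
#' @param lengths integer vector of observed fragment lengths.
#' @param smooth logical, apply the moving-average smoothing.
#' @return a `"frag_dist"` object.
#' @export
frag_dist_empirical <- function(lengths, smooth = TRUE) {
  stopifnot(length(lengths) > 0, all(lengths >= 1))
  k <- min(lengths):max(lengths)
  cnt <- tabulate(lengths - min(lengths) + 1L, nbins = length(k))
  p <- cnt / sum(cnt)
  if (smooth && length(p) >= 3) {
    sm <- stats::filter(p, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- p[is.na(sm)]
    p <- as.numeric(sm) / sum(sm)
  }
  .frag_dist(k, p, mu = sum(k * p))
}

.frag_dist <- function(k, pmf, mu) {
  cdf <- cumsum(pmf)
  cdf[length(cdf)] <- 1  # guard rounding
  structure(list(k = k, pmf = pmf, cdf = cdf,
                 mean = sum(k * pmf),
                 sd = sqrt(max(sum(k^2 * pmf) - sum(k * pmf)^2, 0)),
                 mu = mu,
                 # partial expectation S(u) = sum_{k<=u} k p(k), for O(1)
                 # effective-length evaluation
                 pexp = cumsum(k * pmf)),
            class = "frag_dist")
}

#' @export
print.frag_dist <- function(x, ...) {
  cat(sprintf("fragment length distribution on [%d, %d], mean %.2f, sd %.2f\n",
              min(x$k), max(x$k), x$mean, x$sd))
  invisible(x)
}

# P(K <= u), vectorized over integer u
frag_cdf <- function(dist, u) {
  idx <- findInterval(u, dist$k)
  out <- numeric(length(u))
  pos <- idx > 0L
  out[pos] <- dist$cdf[idx[pos]]
  out
}

# p(k), vectorized
frag_pmf <- function(dist, k) {
  out <- numeric(length(k))
  ok <- k >= dist$k[1L] & k <= dist$k[length(dist$k)]
  out[ok] <- dist$pmf[k[ok] - dist$k[1L] + 1L]
  out
}

#' Insert-size-aware effective length
#'
#' Expected number of valid fragment start positions in a transcript of
#' length `l`: `sum_k p(k) * max(l - k + 1, 0)`.  This is the quantity that
#' converts expected fragment counts n(j) into length-normalized coverages
#' c(j) = n(j) / effective_length(l(j)).
#'
#' @param dist a `"frag_dist"`.
#' @param l numeric vector of transcript lengths.
#' @return numeric vector of effective lengths (>= 0).
#' @export
effective_length <- function(dist, l) {
  # sum_{k<=l} p(k)(l-k+1) = (l+1) F(l) - S(l)
  idx <- findInterval(l, dist$k)
  out <- numeric(length(l))
  pos <- idx > 0L
  out[pos] <- (l[pos] + 1) * dist$cdf[idx[pos]] - dist$pexp[idx[pos]]
  pmax(out, 0)
}

#' Fast effective-length approximation
#'
#' For transcripts much longer than the mean fragment length mu the
#' effective length is well approximated by `l - mu + 1`.
#'
#' @param l transcript lengths; every element must exceed `mu` (shorter
#'   transcripts require the exact [effective_length()]).
#' @param mu mean fragment length.
#' @export
approx_effective_length <- function(l, mu) {
  if (any(l <= mu))
    stop("approximation requires l > mu; use effective_length()")
  l - mu + 1
}
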