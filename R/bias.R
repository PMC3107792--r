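#' Positional hexamer distributions of a read set
#'
#' Random-hexamer priming of reverse transcription biases which fragments
#' are sampled: hexamers favoured by the primer pool are overrepresented at
#' the very start of reads relative to read-internal positions.  This
#' function tabulates the observed proportion `o_i(h)` of reads carrying
#' hexamer `h` at position `i`, for `i = 1 .. l - 5`.  Reads containing `N`
#' are excluded from the counts.
#'
#' @param reads character vector of read sequences, uniform length >= 12.
#' @return object of class `"hexamer_profile"`: a `(l - 5) x 4096`
#'   proportion matrix (rows sum to 1) plus the read length.
#' @export
hexamer_distributions <- function(reads) {
  if (length(reads) == 0L) stop("empty read set")
  l <- unique(nchar(reads))
  if (length(l) != 1L) stop("reads must have uniform length")
  if (l < 12L) {
    warning("reads shorter than 12 bases; hexamer correction disabled")
    return(NULL)
  }
  reads <- reads[!grepl("N", reads, fixed = TRUE)]
  if (length(reads) == 0L) stop("no N-free reads")
  hex <- all_hexamers()
  np <- l - 5L
  o <- matrix(0, nrow = np, ncol = length(hex),
              dimnames = list(NULL, hex))
  for (i in seq_len(np)) {
    h <- substr(reads, i, i + 5L)
    cnt <- tabulate(match(h, hex), nbins = length(hex))
    o[i, ] <- cnt / sum(cnt)
  }
  structure(list(o = o, read_len = l), class = "hexamer_profile")
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
  sort(do.call(paste0, g))
}

#' Hexamer bias weights
#'
#' Each read is weighted by `b(h)` for its starting hexamer `h`:
#' the mean proportion of `h` across read-internal positions
#' (`mid_start .. l - 5`) divided by its proportion at position 1.  Hexamers
#' never seen at position 1 get weight 1.  Reads with overrepresented start
#' hexamers are thus down-weighted and vice versa, under the assumption that
#' read-internal hexamer frequencies are unaffected by priming bias.  Read
#' class multiplicities become `m = sum over member reads of b(h(r))`.
#'
#' @param profile a [hexamer_distributions()] result.
#' @param mid_start first position considered "middle of read"; default
#'   `ceiling(l / 2)`.
#' @return named numeric vector `b` over all 4096 hexamers.
#' @export
hexamer_weight_table <- function(profile, mid_start = NULL) {
  l <- profile$read_len
  if (is.null(mid_start)) mid_start <- as.integer(ceiling(l / 2))
  stopifnot(mid_start >= 2L, mid_start <= l - 5L)
  mid <- colMeans(profile$o[mid_start:(l - 5L), , drop = FALSE])
  o1 <- profile$o[1L, ]
  b <- ifelse(o1 > 0, mid / o1, 1)
  b
}

#' Per-read bias multiplicities
#'
#' @param reads character vector of read sequences.
#' @param b weight table from [hexamer_weight_table()].
#' @return numeric vector of multiplicities (1 for reads whose starting
#'   hexamer contains `N`).
#' @export
hexamer_read_weights <- function(reads, b) {
  h <- substr(reads, 1L, 6L)
  w <- unname(b[h])
  w[is.na(w)] <- 1
  w
}
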