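#' Relative estimation error
#'
#' `|est - truth| / truth` when the true frequency is nonzero; 0 when both
#' are zero; `Inf` when the truth is zero but the estimate is not.
#' Vectorized.
#'
#' @param estimate,truth non-negative frequency vectors.
#' @export
relative_error <- function(estimate, truth) {
  stopifnot(length(estimate) == length(truth),
            all(estimate >= 0), all(truth >= 0))
  out <- numeric(length(truth))
  nz <- truth != 0
  out[nz] <- abs(estimate[nz] - truth[nz]) / truth[nz]
  out[!nz & estimate != 0] <- Inf
  out
}

#' Error fraction at a threshold
#'
#' Percentage of entries with relative error greater than or equal to
#' `tau`.  Infinite errors count as larger than any threshold.
#'
#' @param errors relative errors.
#' @param tau threshold (>= 0).
#' @return percent in `[0, 100]`.
#' @export
error_fraction <- function(errors, tau) {
  if (length(errors) == 0L) stop("empty error list")
  stopifnot(tau >= 0)
  100 * mean(errors >= tau)
}

#' Median percent error
#'
#' The threshold tau at which the error fraction crosses 50%, i.e. the
#' median relative error expressed in percent.  Even-length inputs use the
#' lower median so that `EF(MPE) >= 50` holds exactly.
#'
#' @param errors relative errors.
#' @export
median_percent_error <- function(errors) {
  stopifnot(length(errors) >= 1)
  s <- sort(errors)
  100 * s[ceiling(length(s) / 2)]
}

#' Coefficient of determination
#'
#' Squared Pearson correlation between estimated and true values (the
#' default); `method = "ss"` gives the regression-through-truth variant
#' `1 - SS_res / SS_tot` instead.
#'
#' @param estimate,truth numeric vectors of equal length >= 2; the truth
#'   must have positive variance.
#' @param method `"pearson"` (default) or `"ss"`.
#' @export
r_squared <- function(estimate, truth, method = c("pearson", "ss")) {
  method <- match.arg(method)
  stopifnot(length(estimate) == length(truth), length(truth) >= 2)
  if (stats::var(truth) == 0) stop("truth has zero variance")
  if (method == "pearson") stats::cor(estimate, truth)^2
  else 1 - sum((estimate - truth)^2) / sum((truth - mean(truth))^2)
}

#' Accuracy summary of an estimate against a truth table
#'
#' Computes r-squared, MPE and error fractions overall and within
#' true-expression bins (default bin limits 0, 1e-6, 1e-5, 1e-4, 1e-3,
#' 1e-2, 1).
#'
#' @param estimate,truth frequency vectors over the same isoforms (or
#'   genes).
#' @param thresholds EF thresholds to report.
#' @param bins upper limits of the expression bins.
#' @return list with `r2`, `summary` (a data.frame, one row per bin plus
#'   one for all entries) and the per-entry `errors`.
#' @export
evaluate_estimates <- function(estimate, truth, thresholds = c(0.15),
                               bins = c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2, 1)) {
  err <- relative_error(estimate, truth)
  grp <- findInterval(truth, c(0, bins), left.open = TRUE)  # 0 for truth==0
  labels <- c("0", paste0("(", c(0, head(bins, -1L)), ",", bins, "]"))
  rows <- lapply(0:length(bins), function(g) {
    e <- err[grp == g]
    if (length(e) == 0L) return(NULL)
    cbind(data.frame(range = labels[g + 1L], n = length(e),
                     mpe = median_percent_error(e)),
          setNames(as.data.frame(lapply(thresholds, function(t)
            error_fraction(e, t))), paste0("ef_", thresholds)))
  })
  all_row <- cbind(data.frame(range = "all", n = length(err),
                              mpe = median_percent_error(err)),
                   setNames(as.data.frame(lapply(thresholds, function(t)
                     error_fraction(err, t))), paste0("ef_", thresholds)))
  list(r2 = r_squared(estimate, truth),
       summary = rbind(do.call(rbind, rows), all_row),
       errors = err)
}
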