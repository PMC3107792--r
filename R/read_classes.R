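#' Canonical signature of a read's compatibility entries
#'
#' Two reads are equivalent (and collapse into one read class) iff they are
#' compatible with the same set of isoforms with proportional weights.  The
#' signature sorts entries by isoform index, divides weights by their
#' maximum and rounds to 9 significant digits; equal signatures define
#' equivalence.
#'
#' @param tx integer isoform indices.
#' @param w positive compatibility weights.
#' @return character scalar.
#' @export
canonical_signature <- function(tx, w) {
  stopifnot(length(tx) == length(w), length(tx) >= 1, all(w > 0))
  o <- order(tx)
  paste0(sprintf("%d:%.8e;", tx[o], w[o] / max(w)), collapse = "")
}

#' Create an empty compatibility forest
#'
#' The forest is an online union-find over isoform nodes: as reads are
#' added, trees are united so that each tree spans one connected component
#' of the bipartite read-isoform compatibility graph, and read classes are
#' stored in hash tables at the lowest common ancestor (LCA) of their
#' isoforms' nodes, where any equivalent read is guaranteed to be found and
#' merged.  Path compression is deferred until [forest_collect()] since it
#' would change LCAs while reads are still arriving.
#'
#' @param collapse if `FALSE`, every read keeps its own class (debugging /
#'   equivalence testing); components are still computed.
#' @return an object of class `"compat_forest"`.
#' @export
class_forest <- function(collapse = TRUE) {
  structure(list(ptr = cpp_forest_new(), collapse = isTRUE(collapse)),
            class = "compat_forest")
}

#' Add one read to a compatibility forest
#'
#' @param forest a [class_forest()].
#' @param tx integer isoform indices the read is compatible with.
#' @param w positive weights, one per isoform.
#' @param m multiplicity contributed by this read (1, or a hexamer bias
#'   weight).
#' @return the forest, invisibly (updated by reference).
#' @export
forest_add_read <- function(forest, tx, w, m = 1) {
  cpp_forest_add(forest$ptr, as.integer(tx), as.numeric(w), as.numeric(m),
                 forest$collapse)
  invisible(forest)
}

# batch insertion over CSR entries (rows sorted by read)
forest_add_reads <- function(forest, ent_tx, ent_w, read_off, read_m) {
  cpp_forest_add_batch(forest$ptr, as.integer(ent_tx), as.numeric(ent_w),
                       as.integer(read_off), as.numeric(read_m),
                       forest$collapse)
  invisible(forest)
}

#' Forest statistics
#'
#' Node-level union-find state: parents, heights, represented isoforms and
#' current roots, plus read/class counters.  Useful for verifying the
#' union-by-height invariant (tree height at most `log2(size) + 1`).
#'
#' @param forest a [class_forest()].
#' @export
forest_stats <- function(forest) cpp_forest_stats(forest$ptr)

#' Collect compatibility components and read classes
#'
#' Finalizes the forest: one component per union-find tree, with the read
#' classes of all its nodes concatenated (classes are distinct by
#' construction).  Components are returned ordered by smallest member
#' isoform index; each is ready for [run_component_em()].
#'
#' @param forest a [class_forest()].
#' @return list of components, each a list with `iso` (sorted isoform
#'   indices), `m` (class multiplicities) and `W` (dense class-by-isoform
#'   weight matrix, rows max-normalized).
#' @export
forest_collect <- function(forest) {
  raw <- cpp_forest_collect(forest$ptr)
  nc <- raw$n_components
  out <- vector("list", nc)
  for (c in seq_len(nc)) {
    iso <- raw$iso[(raw$iso_off[c] + 1L):raw$iso_off[c + 1L]]
    cls <- if (raw$cls_off[c + 1L] > raw$cls_off[c])
      (raw$cls_off[c] + 1L):raw$cls_off[c + 1L] else integer(0)
    k <- length(iso); ncls <- length(cls)
    W <- matrix(0, nrow = ncls, ncol = k)
    m <- numeric(ncls)
    if (ncls) {
      m <- raw$cls_m[cls]
      for (ci in seq_along(cls)) {
        e <- (raw$ent_off[cls[ci]] + 1L):raw$ent_off[cls[ci] + 1L]
        W[ci, match(raw$ent_iso[e], iso)] <- raw$ent_w[e]
      }
    }
    out[[c]] <- list(iso = iso, m = m, W = W)
  }
  out
}
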