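#' Compress a partition sample into weighted equivalence classes
#'
#' MCMC samplers over a discrete space revisit partitions, and every loss
#' used here is invariant to label permutations, so the sample can be
#' collapsed to its unique partitions (up to relabelling) with multiplicity
#' weights without changing the expected posterior loss of any decision.
#' Rows are canonically relabelled (linear in T x N), ordered
#' lexicographically by their canonical label sequence, and runs of equal
#' rows are merged, accumulating weights.
#'
#' @param s a \code{\link{partition_sample}} or label matrix.
#' @return A \code{partition_sample} whose rows are canonical and pairwise
#'   non-equivalent, sorted lexicographically, with weights summing to the
#'   input total weight.
#' @export
compress_sample <- function(s) {
  s <- canonicalise_rows(as_partition_sample(s))
  ord <- do.call(order, split(s$labels, col(s$labels)))
  lab <- s$labels[ord, , drop = FALSE]
  w <- s$weights[ord]
  if (nrow(lab) > 1L) {
    ## a row starts a new class iff it differs from its predecessor
    new_class <- c(TRUE, rowSums(lab[-1L, , drop = FALSE] !=
                                   lab[-nrow(lab), , drop = FALSE]) > 0)
  } else {
    new_class <- TRUE
  }
  cls <- cumsum(new_class)
  partition_sample(lab[new_class, , drop = FALSE],
                   as.vector(rowsum(w, cls)))
}

#' Modal partition of a sample
#'
#' The equivalence class with the largest total weight, i.e. the exact
#' minimiser of the estimated expected 0-1 loss over the partitions visited
#' by the sampler. This is the sample-based proxy for the maximum a
#' posteriori clustering (the summariser never sees posterior densities, so
#' the true MAP is not computable here). Ties are broken by lexicographic
#' order of the canonical label sequence, which is deterministic.
#'
#' @param s a \code{\link{partition_sample}} or label matrix.
#' @return An integer label vector in canonical form.
#' @export
modal_partition <- function(s) {
  cs <- compress_sample(s)
  ## rows are already in lexicographic order, so which.max's first-match
  ## rule realises the tie-break
  cs$labels[which.max(cs$weights), ]
}
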