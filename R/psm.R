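#' Posterior similarity matrix
#'
#' Estimates, for every pair of items, the posterior probability that they
#' are allocated to the same cluster, as the weighted co-clustering
#' frequency across the sample. The matrix is symmetric with unit diagonal
#' and costs O(T N^2) to build from T unique rows.
#'
#' @param s a \code{\link{partition_sample}} or label matrix.
#' @return An N x N numeric matrix with entries in [0, 1].
#' @export
posterior_similarity <- function(s) {
  s <- compress_sample(s)
  N <- s$n_items
  b <- matrix(0, N, N)
  for (t in seq_len(s$n_draws)) {
    z <- s$labels[t, ]
    b <- b + s$weights[t] * (outer(z, z, "==") * 1)
  }
  b / s$total_weight
}

#' Binder score of a decision from the posterior similarity matrix
#'
#' The pair-sum \eqn{\sum_{i<j} 1\{a_i = a_j\} (1 - 2 b_{ij})}. For a fixed
#' sample this differs from the expected posterior Binder loss of \code{a}
#' by an additive constant that does not depend on \code{a} (the expected
#' number of co-clustered pairs under the sample), so minimising it over
#' decisions is equivalent to minimising the Binder expected loss. This
#' PSM representation is specific to Binder's loss; it is used here as an
#' independent cross-check of the expected-loss machinery.
#'
#' @param a integer label vector.
#' @param m posterior similarity matrix from
#'   \code{\link{posterior_similarity}}.
#' @return The pair-sum score (lower is better).
#' @export
binder_psm_objective <- function(a, m) {
  a <- validate_partition(a)
  if (!is.matrix(m) || nrow(m) != length(a) || ncol(m) != length(a))
    stop("similarity matrix dimensions must match the decision length",
         call. = FALSE)
  same <- outer(a, a, "==")
  up <- upper.tri(m)
  sum((1 - 2 * m[up])[same[up]])
}
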