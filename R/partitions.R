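#' Canonical relabelling of a partition
#'
#' Relabels the allocation vector so that group labels are assigned in order
#' of first appearance: the first item gets label 1, and each subsequent item
#' either reuses the label of an earlier item in the same group or receives
#' the smallest unused label. Two allocation vectors describe the same
#' partition (differ only by a label permutation) if and only if their
#' canonical forms are identical, so this is the workhorse behind equivalence
#' testing and sample compression.
#'
#' @param labels integer vector of positive cluster labels, one per item.
#' @return An integer vector of the same length using labels exactly
#'   \code{1:K} with first occurrences in increasing order. Idempotent.
#' @examples
#' canonical_relabel(c(2, 2, 1, 3))  # 1 1 2 3
#' @export
canonical_relabel <- function(labels) {
  labels <- validate_partition(labels)
  ## match() against the unique labels realises the first-appearance rule in
  ## linear time: unique() preserves order of first occurrence
  match(labels, unique(labels))
}

## shared validation: positive integral labels, no NA, length >= 1
validate_partition <- function(labels) {
  if (length(labels) < 1L)
    stop("a partition must contain at least one item", call. = FALSE)
  if (anyNA(labels))
    stop("partition labels must not be missing", call. = FALSE)
  if (!is.numeric(labels) || any(labels != as.integer(labels)))
    stop("partition labels must be integers", call. = FALSE)
  labels <- as.integer(labels)
  if (any(labels < 1L))
    stop("partition labels must be positive integers", call. = FALSE)
  labels
}

#' Test whether two allocation vectors describe the same partition
#'
#' Partitions are label-permutation equivalent (written a == z up to a
#' permutation sigma with sigma(a_i) = z_i for all i) exactly when their
#' canonical relabellings coincide.
#'
#' @param p,q integer label vectors of equal length.
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' partitions_equivalent(c(1, 1, 2), c(2, 2, 1))  # TRUE
#' @export
partitions_equivalent <- function(p, q) {
  if (length(p) != length(q))
    stop("partitions must allocate the same number of items", call. = FALSE)
  identical(canonical_relabel(p), canonical_relabel(q))
}

#' Contingency table between two partitions
#'
#' Cross-classifies the N items by their group in \code{a} (rows) and their
#' group in \code{z} (columns). All losses implemented in this package are
#' functions of these counts and their margins only.
#'
#' @param a,z integer label vectors of equal length.
#' @return An object of class \code{"contingency_table"}: a list with
#'   \code{counts} (K_a x K_z integer matrix), \code{row_margins} (group
#'   sizes of \code{a}), \code{col_margins} (group sizes of \code{z}) and
#'   \code{N}.
#' @export
contingency_table <- function(a, z) {
  if (length(a) != length(z))
    stop("partitions must allocate the same number of items", call. = FALSE)
  a <- canonical_relabel(a)
  z <- canonical_relabel(z)
  ka <- max(a)
  kz <- max(z)
  counts <- matrix(tabulate(a + ka * (z - 1L), nbins = ka * kz),
                   nrow = ka, ncol = kz)
  structure(
    list(counts = counts,
         row_margins = as.integer(rowSums(counts)),
         col_margins = as.integer(colSums(counts)),
         N = length(a)),
    class = "contingency_table")
}

## -log2 plug-in entropy term, with the convention x log2 x = 0 at x = 0
neg_plogp <- function(counts, N) {
  p <- counts[counts > 0] / N
  -sum(p * log2(p))
}

#' Entropy of a partition (bits)
#'
#' Plug-in entropy of the group-size distribution, \eqn{-\sum_g (n_g/N)
#' \log_2(n_g/N)}, measuring the uncertainty carried by the allocation.
#'
#' @param p integer label vector.
#' @return Entropy in bits, between 0 (single group) and log2(N).
#' @export
partition_entropy <- function(p) {
  p <- validate_partition(p)
  neg_plogp(tabulate(canonical_relabel(p)), length(p))
}

#' Joint entropy of two partitions (bits)
#'
#' Entropy of the cross-classification distribution n_gh / N from a
#' contingency table; always at least as large as either marginal entropy.
#'
#' @param t a \code{contingency_table}.
#' @return Joint entropy in bits.
#' @export
joint_entropy <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  neg_plogp(t$counts, t$N)
}

#' Mutual information between two partitions (bits)
#'
#' Computed from the entropies as H(a) + H(z) - H(a, z); nonnegative up to
#' floating-point tolerance and bounded above by min(H(a), H(z)).
#'
#' @param t a \code{contingency_table}.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  ha <- neg_plogp(t$row_margins, t$N)
  hz <- neg_plogp(t$col_margins, t$N)
  ha + hz - joint_entropy(t)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Contingency table: %d x %d groups, N = %d items\n",
              nrow(x$counts), ncol(x$counts), x$N))
  print(x$counts)
  invisible(x)
}
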