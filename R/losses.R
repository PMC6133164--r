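#' Loss specifications in the contingency-table decomposition
#'
#' Every loss handled by this package depends on two partitions only through
#' their contingency table, and decomposes as
#' \deqn{L = f_0\left(\sum_{g,h} f_1(n_{gh}),\ \sum_g f_2(n^a_g),\
#'   \sum_h f_3(n^z_h)\right)}
#' with \code{f1}, \code{f2}, \code{f3} evaluable per count in constant time.
#' This structure is what makes single-item reallocation updates O(1) per
#' sample draw inside the greedy optimiser: a move touches two group sizes
#' and two table entries per draw, so the three inner sums are adjusted
#' rather than recomputed.
#'
#' Available losses:
#' \describe{
#'   \item{\code{"B"}}{Binder's loss, \eqn{\frac12\sum_g (n^a_g)^2 +
#'     \frac12\sum_h (n^z_h)^2 - \sum_{gh} n_{gh}^2}; equivalent to the
#'     count of pairwise co-clustering disagreements.}
#'   \item{\code{"VI"}}{Variation of information, \eqn{2H(a,z) - H(a) -
#'     H(z)} in bits; a metric on the space of partitions.}
#'   \item{\code{"NVI"}}{Normalised VI, \eqn{1 - I(a,z)/H(a,z)}, in [0,1].}
#'   \item{\code{"NID"}}{Normalised information distance,
#'     \eqn{1 - I(a,z)/\max\{H(a),H(z)\}}, in [0,1].}
#' }
#' For the normalised losses a zero denominator can only occur when both
#' partitions consist of a single group, i.e. they are identical; the loss
#' is then defined as 0 by continuity with "zero iff equivalent".
#'
#' @param name one of \code{"B"}, \code{"VI"}, \code{"NVI"}, \code{"NID"}.
#' @return An object of class \code{"loss_spec"}: a list with the loss
#'   \code{name}, per-count component functions \code{f1(n, N)},
#'   \code{f2(n, N)}, \code{f3(n, N)} (vectorised over \code{n}) and the
#'   combiner \code{f0(S1, S2, S3)}.
#' @export
loss_spec <- function(name = c("VI", "B", "NVI", "NID")) {
  if (inherits(name, "loss_spec")) return(name)
  name <- match.arg(toupper(name), c("VI", "B", "NVI", "NID"))
  sq <- function(n, N) as.numeric(n)^2
  ## entropy summand -(n/N) log2(n/N), with the 0 log 0 = 0 convention
  ent <- function(n, N) {
    out <- numeric(length(n))
    pos <- n > 0
    p <- n[pos] / N
    out[pos] <- -p * log2(p)
    out
  }
  spec <- switch(name,
    B = list(f1 = sq, f2 = sq, f3 = sq,
             f0 = function(S1, S2, S3) 0.5 * S2 + 0.5 * S3 - S1),
    VI = list(f1 = ent, f2 = ent, f3 = ent,
              f0 = function(S1, S2, S3) 2 * S1 - S2 - S3),
    NVI = list(f1 = ent, f2 = ent, f3 = ent,
               f0 = function(S1, S2, S3)
                 ifelse(S1 > 0, 1 - (S2 + S3 - S1) / S1, 0)),
    NID = list(f1 = ent, f2 = ent, f3 = ent,
               f0 = function(S1, S2, S3) {
                 m <- pmax(S2, S3)
                 ifelse(m > 0, 1 - (S2 + S3 - S1) / m, 0)
               }))
  spec$name <- name
  class(spec) <- "loss_spec"
  spec
}

#' @export
print.loss_spec <- function(x, ...) {
  cat(sprintf("Loss specification: %s\n", x$name))
  invisible(x)
}

#' Evaluate a loss through its component decomposition
#'
#' Computes the three component sums over a contingency table and combines
#' them with \code{f0}. This is the evaluation path used throughout the
#' optimiser; the named direct-formula functions
#' (\code{\link{binder_loss}} etc.) provide an independent route.
#'
#' @param t a \code{\link{contingency_table}}.
#' @param loss a loss name or \code{\link{loss_spec}}.
#' @return The loss value (bits for the information losses).
#' @export
loss_value <- function(t, loss = "VI") {
  stopifnot(inherits(t, "contingency_table"))
  spec <- loss_spec(loss)
  spec$f0(sum(spec$f1(t$counts, t$N)),
          sum(spec$f2(t$row_margins, t$N)),
          sum(spec$f3(t$col_margins, t$N)))
}

#' Binder's loss
#'
#' Direct formula: half the sum of squared row margins plus half the sum of
#' squared column margins minus the sum of squared table entries. Equals the
#' number of item pairs on which the two partitions disagree about
#' co-clustering.
#'
#' @param t a \code{\link{contingency_table}}.
#' @return Nonnegative count; 0 iff the partitions are equivalent.
#' @export
binder_loss <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  0.5 * sum(as.numeric(t$row_margins)^2) +
    0.5 * sum(as.numeric(t$col_margins)^2) -
    sum(as.numeric(t$counts)^2)
}

#' Variation of information loss (bits)
#'
#' Direct formula 2H(a,z) - H(a) - H(z); a label-permutation-invariant
#' metric on partitions.
#'
#' @param t a \code{\link{contingency_table}}.
#' @return Nonnegative value in bits; 0 iff the partitions are equivalent.
#' @export
vi_loss <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  2 * joint_entropy(t) - neg_plogp(t$row_margins, t$N) -
    neg_plogp(t$col_margins, t$N)
}

#' Normalised variation of information loss
#'
#' Direct formula 1 - I(a,z) / H(a,z), in [0,1]; defined as 0 when the
#' joint entropy vanishes (both partitions a single group).
#'
#' @param t a \code{\link{contingency_table}}.
#' @return Value in [0, 1].
#' @export
nvi_loss <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  hj <- joint_entropy(t)
  if (hj <= 0) return(0)
  1 - mutual_information(t) / hj
}

#' Normalised information distance
#'
#' Direct formula 1 - I(a,z) / max(H(a), H(z)), in [0,1]; defined as 0 when
#' both marginal entropies vanish.
#'
#' @param t a \code{\link{contingency_table}}.
#' @return Value in [0, 1].
#' @export
nid_loss <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  hm <- max(neg_plogp(t$row_margins, t$N), neg_plogp(t$col_margins, t$N))
  if (hm <= 0) return(0)
  1 - mutual_information(t) / hm
}

#' Loss between two allocation vectors
#'
#' Convenience wrapper building the contingency table and evaluating the
#' requested loss.
#'
#' @param a,z integer label vectors of equal length.
#' @param loss a loss name or \code{\link{loss_spec}}.
#' @return The loss value.
#' @export
partition_loss <- function(a, z, loss = "VI") {
  loss_value(contingency_table(a, z), loss)
}

#' Estimated expected posterior loss of a decision
#'
#' The weighted average loss of the candidate partition \code{a} against the
#' draws of a posterior sample,
#' \deqn{\psi(a) = \frac{1}{\sum_t \omega^{(t)}} \sum_t \omega^{(t)}
#'   L(a, z^{(t)}),}
#' which for a raw sample (unit weights) is the plain sample average. The
#' normalisation by total weight, rather than by the number of stored rows,
#' makes the value identical on a sample and its compressed form; the
#' minimiser is unaffected by this choice of constant.
#'
#' @param a integer label vector (the decision).
#' @param s a \code{\link{partition_sample}} or label matrix.
#' @param loss a loss name or \code{\link{loss_spec}}.
#' @return The estimated expected posterior loss.
#' @export
expected_posterior_loss <- function(a, s, loss = "VI") {
  s <- as_partition_sample(s)
  if (length(a) != s$n_items)
    stop("decision and sample must allocate the same number of items",
         call. = FALSE)
  spec <- loss_spec(loss)
  vals <- vapply(seq_len(s$n_draws), function(t)
    loss_value(contingency_table(a, s$labels[t, ]), spec), numeric(1))
  sum(s$weights * vals) / s$total_weight
}
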