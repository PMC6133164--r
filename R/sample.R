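#' Construct a partition sample
#'
#' Wraps a T x N matrix of integer cluster labels (one MCMC draw per row)
#' together with optional positive per-row weights. A raw posterior sample
#' has unit weights; \code{\link{compress_sample}} produces weighted samples
#' where the weight of a row counts how many draws fell in its equivalence
#' class. Weighted samples also cover the cluster-ensemble use case, where
#' weights encode the relative importance of each candidate clustering.
#'
#' @param labels integer matrix (draws in rows, items in columns), or a
#'   single label vector interpreted as one draw.
#' @param weights optional numeric vector of strictly positive weights, one
#'   per row; defaults to 1 for every row.
#' @return An object of class \code{"partition_sample"} with elements
#'   \code{labels}, \code{weights}, \code{n_draws}, \code{n_items} and
#'   \code{total_weight}.
#' @export
partition_sample <- function(labels, weights = NULL) {
  if (is.vector(labels)) labels <- matrix(labels, nrow = 1L)
  if (!is.matrix(labels) || nrow(labels) < 1L || ncol(labels) < 1L)
    stop("a partition sample needs at least one draw and one item",
         call. = FALSE)
  if (anyNA(labels) || any(labels != as.integer(labels)) || any(labels < 1L))
    stop("all cluster labels must be positive integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (is.null(weights)) weights <- rep(1, nrow(labels))
  if (length(weights) != nrow(labels))
    stop("need exactly one weight per draw", call. = FALSE)
  if (anyNA(weights) || any(weights <= 0))
    stop("weights must be strictly positive", call. = FALSE)
  structure(
    list(labels = labels,
         weights = as.numeric(weights),
         n_draws = nrow(labels),
         n_items = ncol(labels),
         total_weight = sum(weights)),
    class = "partition_sample")
}

#' @export
print.partition_sample <- function(x, ...) {
  cat(sprintf(
    "Partition sample: %d draw(s) over %d items (total weight %g)\n",
    x$n_draws, x$n_items, x$total_weight))
  k <- apply(x$labels, 1L, function(r) length(unique(r)))
  cat(sprintf("Groups per draw: min %d, median %g, max %d\n",
              min(k), stats::median(k), max(k)))
  invisible(x)
}

as_partition_sample <- function(x) {
  if (inherits(x, "partition_sample")) x else partition_sample(x)
}

## canonicalise every row; returns the sample with relabelled rows
canonicalise_rows <- function(s) {
  s$labels <- t(apply(s$labels, 1L, canonical_relabel))
  if (s$n_items == 1L) s$labels <- matrix(1L, nrow = s$n_draws)
  s
}
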