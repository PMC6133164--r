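#' Enumerate all set partitions of n items
#'
#' Generates every partition of \code{1:n} as a restricted growth string,
#' i.e. in canonical first-appearance labelling, one per row. The number of
#' rows is the Bell number B(n) (see \code{\link{bell_number}}), which grows
#' super-exponentially; this is intended for exact reference computations at
#' small n only.
#'
#' @param n number of items (kept small; B(12) is already ~4.2 million).
#' @return An integer matrix with B(n) rows and n columns.
#' @export
enumerate_set_partitions <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  P <- matrix(1L, 1L, 1L)
  kmax <- c(1L)
  for (i in seq_len(n - 1L)) {
    ## each existing string with k groups extends to k + 1 children
    reps <- kmax + 1L
    parent <- rep(seq_len(nrow(P)), times = reps)
    newlab <- sequence(reps)
    P <- cbind(P[parent, , drop = FALSE], newlab)
    kmax <- pmax(kmax[parent], newlab)
  }
  dimnames(P) <- NULL
  P
}

#' Exhaustive minimisation of the expected posterior loss
#'
#' Evaluates the estimated expected posterior loss of every set partition of
#' the items against the (compressed) sample and returns the exact minimiser
#' for each requested loss. Feasible only for small item counts, where it
#' serves as the exact reference for \code{\link{minimise_epl}}.
#'
#' @param s a \code{\link{partition_sample}} or label matrix with few items.
#' @param loss character vector of loss names among \code{"B"}, \code{"VI"},
#'   \code{"NVI"}, \code{"NID"}.
#' @return If a single loss is requested, a list with \code{partition},
#'   \code{epl} and \code{loss}; otherwise a named list of such lists, one
#'   per loss, computed in a single enumeration pass.
#' @export
minimise_epl_exhaustive <- function(s, loss = "VI") {
  s <- compress_sample(s)
  N <- s$n_items
  if (N > 12L)
    stop("exhaustive search is only sensible for small item counts",
         call. = FALSE)
  losses <- vapply(loss, function(l) loss_spec(l)$name, character(1))
  Tt <- s$n_draws
  Z <- s$labels
  w <- s$weights
  Kz <- max(Z)
  ## lookup of the entropy summand for counts 0..N
  htab <- c(0, -(1:N / N) * log2(1:N / N))
  ## per-draw component sums over the column margins (fixed across decisions)
  zsizes <- vapply(seq_len(Tt), function(t) tabulate(Z[t, ], Kz),
                   integer(Kz))
  zsizes <- matrix(zsizes, nrow = Kz)
  S3_sq <- colSums(matrix(as.numeric(zsizes)^2, nrow = Kz))
  S3_h <- colSums(matrix(htab[zsizes + 1L], nrow = Kz))
  ## linear offsets so that one tabulate() call yields all Tt tables at once
  zbase <- N * ((as.integer(t(Z)) - 1L) + Kz * rep(seq_len(Tt) - 1L,
                                                   each = N))

  cand <- enumerate_set_partitions(N)
  best_val <- stats::setNames(rep(Inf, length(losses)), losses)
  best_idx <- stats::setNames(rep(NA_integer_, length(losses)), losses)
  need_sq <- "B" %in% losses
  need_h <- any(losses != "B")
  for (ci in seq_len(nrow(cand))) {
    a <- cand[ci, ]
    cnt <- tabulate(a + zbase, N * Kz * Tt)
    M <- matrix(cnt, N * Kz, Tt)
    sizes <- tabulate(a, N)
    for (l in losses) {
      if (l == "B") {
        val <- sum(w * (0.5 * sum(as.numeric(sizes)^2) + 0.5 * S3_sq -
                          colSums(M * M))) / s$total_weight
      } else {
        S1 <- colSums(matrix(htab[M + 1L], N * Kz, Tt))
        S2 <- sum(htab[sizes + 1L])
        val <- switch(l,
          VI = sum(w * (2 * S1 - S2 - S3_h)),
          NVI = sum(w * ifelse(S1 > 0, 1 - (S2 + S3_h - S1) / S1, 0)),
          NID = sum(w * {
            m <- pmax(S2, S3_h)
            ifelse(m > 0, 1 - (S2 + S3_h - S1) / m, 0)
          })) / s$total_weight
      }
      if (val < best_val[[l]]) {
        best_val[[l]] <- val
        best_idx[[l]] <- ci
      }
    }
  }
  out <- lapply(losses, function(l)
    list(partition = cand[best_idx[[l]], ], epl = best_val[[l]], loss = l))
  names(out) <- losses
  if (length(out) == 1L) out[[1L]] else out
}

#' Exact Bell numbers via the Bell triangle
#'
#' Counts the set partitions of \code{n} items with exact integer
#' arithmetic. The count explodes quickly (for 100 items it has more than
#' 100 decimal digits), which is why exhaustive minimisation over the
#' partition space is hopeless beyond toy sizes and a greedy search is used
#' instead. Values are carried as base-1e9 limb vectors so there is no
#' overflow at any n.
#'
#' @param n nonnegative integer.
#' @return The Bell number B(n) as a decimal character string.
#' @examples
#' bell_number(6)  # "203"
#' nchar(bell_number(100))  # 116 digits
#' @export
bell_number <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  if (n <= 1L) return("1")
  ## big integers as little-endian base-1e9 limb vectors
  add <- function(x, y) {
    ln <- max(length(x), length(y))
    x <- c(x, numeric(ln - length(x)))
    y <- c(y, numeric(ln - length(y)))
    z <- x + y
    carry <- 0
    for (i in seq_len(ln)) {
      z[i] <- z[i] + carry
      carry <- z[i] %/% 1e9
      z[i] <- z[i] %% 1e9
    }
    if (carry > 0) z <- c(z, carry)
    z
  }
  row <- list(1)
  for (k in seq_len(n - 1L)) {
    nxt <- vector("list", k + 1L)
    nxt[[1L]] <- row[[k]]
    for (j in seq_len(k)) nxt[[j + 1L]] <- add(nxt[[j]], row[[j]])
    row <- nxt
  }
  limbs <- rev(row[[length(row)]])
  paste0(format(limbs[1L], scientific = FALSE),
         paste(sprintf("%09.0f", limbs[-1L]), collapse = ""))
}
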