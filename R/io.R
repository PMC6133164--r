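#' Read a partition sample from a plain-text file
#'
#' Each line holds one draw: integer labels separated by whitespace or
#' commas. A single leading header line is ignored if it contains anything
#' non-numeric. An optional weights file supplies one strictly positive
#' number per draw. Files are validated for rectangularity and label
#' positivity, with errors naming the offending line.
#'
#' @param path path to the sample file.
#' @param weights_path optional path to a weights file.
#' @return A \code{\link{partition_sample}}.
#' @export
read_partition_sample <- function(path, weights_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty sample file: ", path, call. = FALSE)
  tokens <- lapply(lines, function(l)
    strsplit(trimws(l), "[,[:space:]]+")[[1L]])
  first <- suppressWarnings(as.numeric(tokens[[1L]]))
  start <- 1L
  if (anyNA(first)) {
    start <- 2L  # header line
    if (length(tokens) < 2L)
      stop("sample file contains a header but no draws: ", path,
           call. = FALSE)
  }
  rows <- vector("list", length(tokens) - start + 1L)
  width <- length(tokens[[start]])
  for (k in seq_along(rows)) {
    ln <- start + k - 1L
    vals <- suppressWarnings(as.numeric(tokens[[ln]]))
    if (anyNA(vals))
      stop(sprintf("non-integer label on line %d of %s", ln, path),
           call. = FALSE)
    if (any(vals != round(vals)))
      stop(sprintf("non-integer label on line %d of %s", ln, path),
           call. = FALSE)
    if (length(vals) != width)
      stop(sprintf("ragged row on line %d of %s (expected %d labels, got %d)",
                   ln, path, width, length(vals)), call. = FALSE)
    rows[[k]] <- as.integer(vals)
  }
  Z <- do.call(rbind, rows)
  weights <- NULL
  if (!is.null(weights_path)) {
    weights <- scan(weights_path, what = numeric(), quiet = TRUE)
    if (length(weights) != nrow(Z))
      stop(sprintf("weights file has %d entries but the sample has %d draws",
                   length(weights), nrow(Z)), call. = FALSE)
  }
  partition_sample(Z, weights)
}

#' Write a partition sample to a plain-text file
#'
#' One draw per line, space-separated labels; an optional companion weights
#' file (one weight per line) is written when the sample carries non-unit
#' weights or \code{weights_path} is given.
#'
#' @param s a \code{\link{partition_sample}}.
#' @param path output file for the label rows.
#' @param weights_path optional output file for the weights.
#' @export
write_partition_sample <- function(s, path, weights_path = NULL) {
  s <- as_partition_sample(s)
  writeLines(apply(s$labels, 1L, paste, collapse = " "), path)
  if (is.null(weights_path) && any(s$weights != 1))
    weights_path <- paste0(path, ".weights")
  if (!is.null(weights_path))
    writeLines(format(s$weights, scientific = FALSE, trim = TRUE),
               weights_path)
  invisible(path)
}

#' Read a single partition from file
#'
#' Reads one allocation vector: either a single line of labels or one label
#' per line.
#'
#' @param path input file.
#' @return An integer label vector.
#' @export
read_partition <- function(path) {
  s <- read_partition_sample(path)
  if (s$n_draws == 1L) return(as.integer(s$labels[1L, ]))
  if (s$n_items == 1L) return(as.integer(s$labels[, 1L]))
  stop("expected a single partition in ", path, call. = FALSE)
}

#' Write an optimisation result and its run report
#'
#' Writes the optimal partition as one line of canonical 1-based labels, and
#' a companion key/value text report carrying the loss name, the attained
#' expected posterior loss, the number of groups, how many restarts reached
#' the best value, the sweeps per restart and the seed. Re-reading the
#' partition and recomputing its expected loss against the input sample
#' reproduces the reported value.
#'
#' @param r a \code{\link{minimise_epl}} result.
#' @param path output file for the partition.
#' @param report_path optional output file for the report (default:
#'   \code{path} with a \code{.report} suffix).
#' @export
write_result <- function(r, path, report_path = paste0(path, ".report")) {
  stopifnot(inherits(r, "greedy_epl"))
  writeLines(paste(canonical_relabel(r$partition), collapse = " "), path)
  rep_lines <- c(
    sprintf("loss: %s", r$loss),
    sprintf("epl: %.15g", r$epl),
    sprintf("K: %d", r$K),
    sprintf("K_up: %d", r$K_up),
    sprintf("restarts: %d", r$restarts),
    sprintf("restarts_hit_best: %d", r$restarts_hit_best),
    sprintf("sweeps: %s", paste(r$sweeps, collapse = " ")),
    sprintf("seed: %s", if (is.null(r$seed)) "NA" else as.character(r$seed)))
  writeLines(rep_lines, report_path)
  invisible(path)
}
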