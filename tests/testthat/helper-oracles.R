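# Shared generators and brute-force oracles, kept deliberately naive and
# independent of the package's evaluation paths.

rand_partition <- function(n, kmax = max(2L, n %/% 2L)) {
  sample.int(kmax, n, replace = TRUE)
}

rand_sample <- function(n_draws, n, kmax = 4L) {
  partition_sample(matrix(sample.int(kmax, n_draws * n, replace = TRUE),
                          n_draws, n))
}

# Binder's loss counted pair by pair: partitions disagree on a pair when
# exactly one of them co-clusters it.
pair_binder <- function(a, z) {
  n <- length(a)
  loss <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      loss <- loss + ((a[i] == a[j]) != (z[i] == z[j]))
    }
  }
  loss
}

# expected posterior loss by direct weighted averaging of per-row losses
brute_epl <- function(a, s, loss) {
  s <- eplclust:::as_partition_sample(s)
  vals <- sapply(seq_len(s$n_draws), function(t)
    partition_loss(a, s$labels[t, ], loss))
  sum(s$weights * vals) / s$total_weight
}

all_losses <- c("B", "VI", "NVI", "NID")
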