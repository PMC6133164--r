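test_that("incremental reallocation deltas match full recomputation", {
  set.seed(14)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    s <- rand_sample(sample(5:20, 1), n, kmax = 3L)
    a <- rand_partition(n, kmax = n)
    for (l in all_losses) {
      st <- sweep_state(a, s, l, K_up = n)
      i <- sample.int(n, 1)
      r <- st$a[i]
      expect_equal(delta_epl(st, i, r, r), 0)
      targets <- setdiff(seq_len(n), r)
      ss <- sample(targets, 1)
      a_new <- st$a; a_new[i] <- ss
      scratch <- expected_posterior_loss(a_new, s, l) -
        expected_posterior_loss(st$a, s, l)
      expect_equal(delta_epl(st, i, r, ss), scratch, tolerance = 1e-9)
    }
  }
  s <- rand_sample(5, 4)
  st <- sweep_state(c(1, 1, 2, 2), s, "VI", K_up = 4)
  expect_error(delta_epl(st, 1, 2, 3), "not currently")
  expect_error(delta_epl(st, 9, 1, 2), "out of range")
})

test_that("any move away from a point-mass sample's partition raises the VI expected loss", {
  z <- c(1, 1, 2, 2, 3)
  s <- partition_sample(matrix(rep(z, 12), 12, 5, byrow = TRUE))
  st <- sweep_state(z, s, "VI", K_up = 5)
  for (i in 1:5) {
    # moves that change the partition: into another occupied group, or into
    # an empty group when the item is not already a singleton (a singleton
    # moved to an empty group is a pure relabelling, delta exactly 0)
    occupied <- setdiff(unique(z), z[i])
    targets <- if (sum(z == z[i]) > 1L) c(occupied, 4L) else occupied
    for (ss in targets) {
      expect_gt(delta_epl(st, i, z[i], ss), 0)
    }
    if (sum(z == z[i]) == 1L) expect_equal(delta_epl(st, i, z[i], 4L), 0)
  }
})

test_that("a greedy sweep only applies strict improvements and reports movement", {
  # at a local optimum nothing moves and the decision is untouched
  z <- c(1, 1, 2, 2)
  s <- partition_sample(matrix(rep(z, 8), 8, 4, byrow = TRUE))
  st <- sweep_state(z, s, "VI", K_up = 4)
  res <- greedy_sweep(st)
  expect_false(res$changed)
  expect_equal(st$a, z)
  # single item: no reallocation is possible
  st1 <- sweep_state(1L, partition_sample(matrix(1L, 3, 1)), "B", K_up = 1)
  expect_false(greedy_sweep(st1)$changed)
  # an improvable state moves and the expected loss strictly decreases
  set.seed(24)
  st2 <- sweep_state(c(1, 2, 1, 2), s, "VI", K_up = 4)
  psi0 <- st2$psi
  res2 <- greedy_sweep(st2)
  expect_true(res2$changed)
  expect_lt(st2$psi, psi0)
  # the chosen move is at least as good as every single move the oracle finds
  best_single <- min(sapply(1:4, function(i) {
    sapply(setdiff(1:4, c(1, 2, 1, 2)[i]), function(g) {
      a2 <- c(1, 2, 1, 2); a2[i] <- g
      expected_posterior_loss(a2, s, "VI")
    })
  }))
  expect_lte(st2$psi, best_single + 1e-9)
})

test_that("greedy minimisation recovers a point-mass sample exactly for every loss", {
  z <- c(1, 1, 2, 3, 3, 2)
  s <- partition_sample(matrix(rep(z, 15), 15, 6, byrow = TRUE))
  for (l in all_losses) {
    fit <- minimise_epl(s, l, restarts = 4, seed = 5)
    expect_true(partitions_equivalent(fit$partition, z))
    expect_equal(fit$epl, 0, tolerance = 1e-12)
  }
})

test_that("greedy attains the exhaustive minimum on small instances", {
  set.seed(34)
  for (rep in 1:3) {
    truth <- rand_partition(6, 3L)
    s <- perturb_partition_sample(truth, 20, 0.2, K_up = 3L,
                                  seed = sample.int(1e6, 1))
    ex <- minimise_epl_exhaustive(s, all_losses)
    for (l in all_losses) {
      fit <- minimise_epl(s, l, K_up = 6, restarts = 10, seed = rep)
      expect_equal(fit$epl, ex[[l]]$epl, tolerance = 1e-9)
      expect_gte(fit$epl, ex[[l]]$epl - 1e-9)
    }
  }
})

test_that("expected loss traces are monotone and runs terminate within the sweep cap", {
  set.seed(44)
  s <- rand_sample(30, 10, kmax = 4L)
  fit <- minimise_epl(s, "VI", K_up = 10, restarts = 6, seed = 9,
                      max_sweeps = 50)
  for (tr in fit$traces) {
    expect_true(all(diff(tr) <= 1e-9))
  }
  expect_true(all(fit$sweeps <= 50))
  expect_gte(fit$restarts_hit_best, 1)
  expect_equal(fit$epl, expected_posterior_loss(fit$partition, s, "VI"),
               tolerance = 1e-9)
})

test_that("the optimum is invariant to row order and to duplicating every draw", {
  set.seed(54)
  s <- perturb_partition_sample(rep(1:3, each = 4), 25, 0.15, seed = 77)
  fit <- minimise_epl(s, "VI", K_up = 6, restarts = 6, seed = 3)
  shuffled <- partition_sample(s$labels[sample(s$n_draws), ])
  fit_sh <- minimise_epl(shuffled, "VI", K_up = 6, restarts = 6, seed = 3)
  expect_true(partitions_equivalent(fit$partition, fit_sh$partition))
  expect_equal(fit$epl, fit_sh$epl, tolerance = 1e-9)
  doubled <- partition_sample(rbind(s$labels, s$labels))
  fit_db <- minimise_epl(doubled, "VI", K_up = 6, restarts = 6, seed = 3)
  expect_true(partitions_equivalent(fit$partition, fit_db$partition))
  expect_equal(fit$epl, fit_db$epl, tolerance = 1e-9)
})

test_that("results are reproducible from the seed alone", {
  set.seed(64)
  s <- rand_sample(40, 12, kmax = 4L)
  f1 <- minimise_epl(s, "NID", K_up = 8, restarts = 5, seed = 101)
  f2 <- minimise_epl(s, "NID", K_up = 8, restarts = 5, seed = 101)
  expect_identical(f1$partition, f2$partition)
  expect_identical(f1$traces, f2$traces)
})
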