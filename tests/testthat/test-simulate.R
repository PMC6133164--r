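test_that("the stock mixture designs carry the intended parameters", {
  cfg <- mixture_preset("four_gaussians")
  expect_equal(cfg$weights, rep(0.25, 4))
  expect_equal(cfg$means, rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)))
  expect_equal(cfg$covariances[, , 1], diag(1, 2))
  expect_equal(cfg$covariances[, , 2], diag(0.5, 2))
  expect_equal(cfg$covariances[, , 3], diag(1, 2))
  expect_equal(cfg$covariances[, , 4], diag(1.5, 2))
  expect_equal(cfg$N, 400L)
  iso <- mixture_preset("isotropic", sigma = 0.8)
  for (g in 1:4) expect_equal(iso$covariances[, , g], diag(0.8, 2))
  expect_error(mixture_sim_config(c(0.5, 0.5), rbind(c(0, 0), c(1, 1)),
                                  array(c(1, 2, 2, 1), c(2, 2, 2)), 10),
               "positive definite")
  expect_error(mixture_sim_config(c(0.7, 0.6), rbind(c(0, 0), c(1, 1)),
                                  array(diag(2), c(2, 2, 2)), 10),
               "sum to 1")
})

test_that("mixture data respect the configured weights, means and degenerate limits", {
  cfg <- mixture_preset("four_gaussians", N = 0L)
  d0 <- generate_mixture_data(cfg)
  expect_equal(nrow(d0$Y), 0L)
  expect_length(d0$z, 0L)
  big <- mixture_preset("four_gaussians", N = 100000L)
  d <- generate_mixture_data(big, seed = 8)
  freq <- tabulate(d$z, 4) / big$N
  expect_true(all(abs(freq - 0.25) < 4 * sqrt(0.25 * 0.75 / big$N)))
  for (g in 1:4) {
    expect_equal(colMeans(d$Y[d$z == g, ]), big$means[g, ], tolerance = 0.05)
  }
  tiny <- mixture_sim_config(rep(0.25, 4), big$means,
                             array(diag(1e-12, 2), c(2, 2, 4)), 500L)
  dt <- generate_mixture_data(tiny, seed = 9)
  expect_true(all(abs(dt$Y - tiny$means[dt$z, ]) < 1e-4))
})

test_that("perturbed samples concentrate at the truth and compress exactly at zero noise", {
  truth <- rep(1:4, each = 5)
  s0 <- perturb_partition_sample(truth, 30, 0, seed = 3)
  for (t in seq_len(s0$n_draws))
    expect_true(partitions_equivalent(s0$labels[t, ], truth))
  cs0 <- compress_sample(s0)
  expect_equal(cs0$n_draws, 1L)
  expect_equal(cs0$weights, 30)
  expect_identical(cs0$labels[1, ], canonical_relabel(truth))
  # moderate noise: the truth is still the closest partition on average
  s1 <- perturb_partition_sample(truth, 200, 0.1, seed = 4)
  vi_truth <- expected_posterior_loss(truth, s1, "VI")
  set.seed(5)
  others <- replicate(20, expected_posterior_loss(rand_partition(20, 4), s1, "VI"))
  expect_true(all(vi_truth < others))
})

test_that("with the likelihood off the allocation sampler targets the CRP prior", {
  Y <- matrix(rnorm(10), 5, 2)
  s <- dpgmm_collapsed_gibbs(Y, alpha = 1, n_draws = 20000, burn_in = 500,
                             thin = 2, seed = 16, likelihood = FALSE)
  k <- apply(s$labels, 1, max)
  expected_k <- sum(1 / (1 + 0:4))  # 2.2833 for alpha = 1, N = 5
  se <- stats::sd(k) / sqrt(length(k))
  expect_lt(abs(mean(k) - expected_k), 3 * se + 0.01)
})

test_that("the allocation sampler respects concentration limits and seeds", {
  set.seed(26)
  Y <- matrix(rnorm(60, sd = 0.3), 30, 2)
  s_tiny <- dpgmm_collapsed_gibbs(Y, alpha = 1e-8, n_draws = 100,
                                  burn_in = 200, thin = 1, seed = 6)
  expect_gt(mean(apply(s_tiny$labels, 1, max) == 1), 0.95)
  s_a <- dpgmm_collapsed_gibbs(Y, n_draws = 50, burn_in = 100, thin = 1, seed = 7)
  s_b <- dpgmm_collapsed_gibbs(Y, n_draws = 50, burn_in = 100, thin = 1, seed = 7)
  expect_identical(s_a$labels, s_b$labels)
  expect_error(dpgmm_collapsed_gibbs(matrix(rnorm(9), 3, 3)), "two-dimensional")
  expect_error(dpgmm_collapsed_gibbs(matrix(rnorm(2), 1, 2)), "at least two")
})

test_that("the sampler separates well-separated components", {
  means <- rbind(c(4, 4), c(-4, 4), c(-4, -4), c(4, -4))
  cfg <- mixture_sim_config(rep(0.25, 4), means,
                            array(diag(0.3, 2), c(2, 2, 4)), 120L)
  d <- generate_mixture_data(cfg, seed = 36)
  s <- dpgmm_collapsed_gibbs(d$Y, n_draws = 300, burn_in = 800, thin = 2,
                             seed = 37)
  fit <- minimise_epl(s, "VI", K_up = 10, restarts = 4, seed = 38)
  expect_equal(fit$K, 4L)
  expect_true(partitions_equivalent(fit$partition, d$z))
})

test_that("the closed-form predictive matches Monte Carlo integration of the posterior", {
  set.seed(46)
  a <- 0.1; nu <- 4; u <- 0.5
  D <- matrix(c(0.3, -0.2, 1.1, 0.9, -0.5, 0.4), 3, 2, byrow = TRUE)
  y <- c(0.7, -0.3)
  n <- nrow(D); sums <- colSums(D); Q <- t(D) %*% D
  kap <- a + n; nun <- nu + n
  mun <- sums / kap
  Ln <- u * nu * diag(2) + Q - sums %*% t(sums) / kap
  # brute-force predictive: average the Gaussian density over draws of
  # (mu, Sigma) from the normal-inverse-Wishart posterior
  M <- 20000
  dens <- replicate(M, {
    Sig <- solve(stats::rWishart(1, nun, solve(Ln))[, , 1])
    mu <- MASS::mvrnorm(1, mun, Sig / kap)
    d <- y - mu
    exp(-0.5 * drop(t(d) %*% solve(Sig) %*% d)) / (2 * pi * sqrt(det(Sig)))
  })
  # the sampler's own closed-form bivariate-t predictive
  lt <- eplclust:::dpgmm_log_predictive_cpp(n, sums[1], sums[2],
                                            Q[1, 1], Q[1, 2], Q[2, 2],
                                            y[1], y[2], a, nu, u)
  se <- stats::sd(dens) / sqrt(M)
  expect_lt(abs(mean(dens) - exp(lt)), 4 * se)
})

test_that("the overlapping four-Gaussian design caps agreement even for the oracle classifier", {
  cfg <- mixture_preset("four_gaussians", N = 200)
  d <- generate_mixture_data(cfg, seed = 56)
  loglik <- sapply(1:4, function(g) {
    v <- cfg$covariances[1, 1, g]
    -rowSums(sweep(d$Y, 2, cfg$means[g, ])^2) / (2 * v) - log(v)
  })
  bayes <- max.col(loglik)
  expect_lt(mclust::adjustedRandIndex(bayes, d$z), 0.6)
})
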