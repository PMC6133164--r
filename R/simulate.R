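#' Configuration of a bivariate Gaussian mixture simulation
#'
#' Describes a finite mixture of K bivariate Gaussians from which labelled
#' data can be drawn with \code{\link{generate_mixture_data}}.
#'
#' @param weights mixture weights, positive and summing to 1.
#' @param means K x 2 matrix of component means.
#' @param covariances 2 x 2 x K array of symmetric positive-definite
#'   component covariance matrices.
#' @param N number of observations to draw.
#' @return An object of class \code{"mixture_sim_config"}.
#' @seealso \code{\link{mixture_preset}} for the two stock designs.
#' @export
mixture_sim_config <- function(weights, means, covariances, N) {
  weights <- as.numeric(weights)
  K <- length(weights)
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-8)
    stop("mixture weights must be positive and sum to 1", call. = FALSE)
  means <- as.matrix(means)
  if (!identical(dim(means), c(K, 2L)) && !identical(dim(means), as.integer(c(K, 2))))
    stop("means must be a K x 2 matrix", call. = FALSE)
  if (!is.array(covariances) || !all(dim(covariances) == c(2, 2, K)))
    stop("covariances must be a 2 x 2 x K array", call. = FALSE)
  for (g in seq_len(K)) {
    Sg <- covariances[, , g]
    if (max(abs(Sg - t(Sg))) > 1e-10 || any(eigen(Sg, symmetric = TRUE,
                                                  only.values = TRUE)$values <= 0))
      stop("each covariance must be symmetric positive definite",
           call. = FALSE)
  }
  N <- as.integer(N)
  stopifnot(N >= 0L)
  structure(list(weights = weights, means = means,
                 covariances = covariances, K = K, N = N),
            class = "mixture_sim_config")
}

#' Stock mixture designs
#'
#' Two standard four-component bivariate designs used throughout the
#' package's demonstrations and tests. \code{"four_gaussians"} places equal
#' weight 0.25 on components centred at (1,1), (-1,1), (-1,-1) and (1,-1)
#' with isotropic covariances of variance 1, 0.5, 1 and 1.5 respectively,
#' giving heavily overlapping clusters. \code{"isotropic"} keeps the same
#' means and weights but gives every component the common isotropic
#' covariance \code{sigma * I}; increasing \code{sigma} makes the
#' clustering task harder.
#'
#' @param name \code{"four_gaussians"} or \code{"isotropic"}.
#' @param N number of observations (default 400 for the first design, 100
#'   for the second, matching the scales at which these designs are
#'   typically run).
#' @param sigma common variance for the \code{"isotropic"} design.
#' @return A \code{\link{mixture_sim_config}}.
#' @export
mixture_preset <- function(name = c("four_gaussians", "isotropic"),
                           N = NULL, sigma = 0.9) {
  name <- match.arg(name)
  means <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  if (name == "four_gaussians") {
    if (is.null(N)) N <- 400L
    v <- c(1, 0.5, 1, 1.5)
  } else {
    if (is.null(N)) N <- 100L
    stopifnot(sigma > 0)
    v <- rep(sigma, 4)
  }
  covs <- array(0, dim = c(2, 2, 4))
  for (g in 1:4) covs[, , g] <- diag(v[g], 2)
  mixture_sim_config(rep(0.25, 4), means, covs, N)
}

#' Draw labelled data from a Gaussian mixture
#'
#' Samples component allocations from the mixture weights and then each
#' observation from its allocated bivariate Gaussian.
#'
#' @param config a \code{\link{mixture_sim_config}}.
#' @param seed optional integer seed.
#' @return A list of class \code{"mixture_data"} with \code{Y} (N x 2
#'   observation matrix) and \code{z} (true allocation vector, canonical
#'   labels not enforced: labels index the configured components).
#' @export
generate_mixture_data <- function(config, seed = NULL) {
  stopifnot(inherits(config, "mixture_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  N <- config$N
  z <- if (N > 0)
    sample.int(config$K, N, replace = TRUE, prob = config$weights)
  else integer(0)
  Y <- matrix(NA_real_, N, 2)
  for (g in seq_len(config$K)) {
    idx <- which(z == g)
    if (length(idx) > 0)
      Y[idx, ] <- MASS::mvrnorm(length(idx), config$means[g, ],
                                config$covariances[, , g])
  }
  structure(list(Y = Y, z = z), class = "mixture_data")
}

#' Synthetic posterior sample concentrated near a known partition
#'
#' Emulates the output of a well-mixed MCMC run whose posterior is
#' concentrated at a ground-truth partition: each draw copies the truth,
#' independently reassigns every item with probability \code{epsilon} to a
#' uniform label in \code{1:K_up}, and finally applies a uniformly random
#' permutation of the labels to mimic label switching between draws. With
#' \code{epsilon = 0} every draw is equivalent to the truth (and compresses
#' to a single row).
#'
#' @param truth integer label vector, the ground-truth partition.
#' @param n_draws number of draws to generate.
#' @param epsilon per-item reallocation probability in [0, 1].
#' @param K_up label range for reassignment and permutation; defaults to
#'   the number of groups in \code{truth}.
#' @param seed optional integer seed.
#' @return A \code{\link{partition_sample}} with unit weights.
#' @export
perturb_partition_sample <- function(truth, n_draws, epsilon,
                                     K_up = NULL, seed = NULL) {
  truth <- canonical_relabel(truth)
  stopifnot(epsilon >= 0, epsilon <= 1, n_draws >= 1)
  if (is.null(K_up)) K_up <- max(truth)
  K_up <- as.integer(K_up)
  stopifnot(K_up >= max(truth))
  if (!is.null(seed)) set.seed(seed)
  N <- length(truth)
  Z <- matrix(0L, n_draws, N)
  for (t in seq_len(n_draws)) {
    row <- truth
    flip <- stats::runif(N) < epsilon
    row[flip] <- sample.int(K_up, sum(flip), replace = TRUE)
    perm <- sample.int(K_up)
    Z[t, ] <- perm[row]
  }
  partition_sample(Z)
}

#' Demonstration collapsed Gibbs sampler for a Dirichlet-process Gaussian
#' mixture
#'
#' Produces a posterior sample of allocation vectors for bivariate data
#' under a Dirichlet-process mixture of Gaussians with a conjugate
#' normal-inverse-Wishart base measure: per new group,
#' Sigma ~ Inverse-Wishart(nu, u * nu * I) and mu | Sigma ~ N(0, Sigma / a).
#' The sampler is collapsed: component parameters are integrated out
#' analytically, and each Gibbs update reallocates one item with
#' probability proportional to (group size, or alpha for a new group) times
#' the multivariate-t posterior predictive density of the item under the
#' group. The concentration alpha and the hyperparameters a, nu, u are held
#' fixed (no hyperpriors): this sampler exists to exercise the summarisation
#' pipeline end-to-end, not to be a production mixture sampler.
#'
#' Centring and scaling the data beforehand is recommended, as the prior is
#' centred at the origin.
#'
#' @param Y N x 2 numeric matrix of observations (or a
#'   \code{\link{generate_mixture_data}} result).
#' @param alpha Dirichlet-process concentration (> 0).
#' @param a prior precision scaling of the mean (> 0).
#' @param nu inverse-Wishart degrees of freedom (> 1 in two dimensions).
#' @param u inverse-Wishart scale multiplier (> 0).
#' @param n_draws number of retained draws.
#' @param burn_in discarded initial sweeps.
#' @param thin keep one draw every \code{thin} sweeps after burn-in.
#' @param seed optional integer seed.
#' @param likelihood set \code{FALSE} to switch the data likelihood off, in
#'   which case the chain targets the Chinese-restaurant-process prior on
#'   partitions (useful for validating the allocation mechanics).
#' @return A \code{\link{partition_sample}} of \code{n_draws} rows.
#' @export
dpgmm_collapsed_gibbs <- function(Y, alpha = 1, a = 0.1, nu = 4, u = 0.5,
                                  n_draws = 1000L, burn_in = 2000L,
                                  thin = 5L, seed = NULL,
                                  likelihood = TRUE) {
  if (inherits(Y, "mixture_data")) Y <- Y$Y
  Y <- as.matrix(Y)
  if (ncol(Y) != 2L)
    stop("the demonstration sampler handles two-dimensional data only",
         call. = FALSE)
  if (nrow(Y) < 2L)
    stop("at least two observations are required", call. = FALSE)
  if (anyNA(Y)) stop("observations must not contain missing values",
                     call. = FALSE)
  stopifnot(alpha > 0, a > 0, nu > 1, u > 0,
            n_draws >= 1, burn_in >= 0, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- dpgmm_gibbs_cpp(Y, alpha, a, nu, u,
                           as.integer(n_draws), as.integer(burn_in),
                           as.integer(thin), isTRUE(likelihood))
  partition_sample(draws)
}
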