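# eplclust

Optimal clustering point estimates from posterior partition samples.

## The problem

MCMC samplers for Bayesian clustering models — finite and infinite
mixtures, hidden Markov models, stochastic and latent block models — return
a `T × N` matrix of posterior draws of the allocation vector
`z = (z_1, …, z_N)`. That matrix is the full clustering answer, but it is
hard to use: allocations are categorical (no means or quantiles), and
labels are only identified up to permutation, so draws cannot be compared
entry-wise. `eplclust` condenses the sample into one optimal partition by
Bayesian decision theory: pick a loss `L(a, z)` between partitions, estimate
the expected posterior loss of any candidate decision `a` as

    ψ(a) = (1/T) Σ_t L(a, z⁽ᵗ⁾),

and report `â = argmin_a ψ(a)`, minimised over *all* partitions of the N
items by a greedy single-item reallocation search with random restarts. The
number of groups of `â` is selected automatically by the same
optimisation. Supported losses (all functions of the contingency table
between `a` and `z`, hence label-switching invariant):

* `"B"` — Binder's loss, the count of pairwise co-clustering disagreements;
* `"VI"` — variation of information `2H(a,z) − H(a) − H(z)` (bits), a
  metric on partition space;
* `"NVI"` / `"NID"` — normalised information losses
  `1 − I/H(a,z)` and `1 − I/max{H(a), H(z)}` in `[0, 1]`.

A single move's effect on `ψ` is evaluated incrementally in `O(T̃)` (unique
draws), so a full sweep costs `O(T̃·N·K_up)`; samples are first compressed
into weighted equivalence classes, which leaves `ψ` unchanged and often
shrinks `T` substantially. The intended users are statisticians and applied
researchers who already have a sample of partitions — from any model — and
need the defensible point summary.

## Worked example

Summarise a noisy sample concentrated near a three-group truth:

```r
library(eplclust)

truth <- rep(1:3, each = 20)                       # 60 items, 3 groups
s <- perturb_partition_sample(truth, n_draws = 300,
                              epsilon = 0.1, seed = 2024)
fit <- minimise_epl(s, loss = "VI", K_up = 10, restarts = 8, seed = 1)
print(fit)
#> Greedy expected posterior loss minimisation (VI loss)
#>   optimal partition: 60 items in 3 groups
#>   expected posterior loss: 0.708505
#>   restarts reaching the best value: 8 of 8
#>   sweeps to convergence: 2 2 2 2 3 2 2 2

partitions_equivalent(fit$partition, truth)
#> [1] TRUE
expected_posterior_loss(modal_partition(s), s, "VI")
#> [1] 0.843699
```

The sample here mimics an MCMC run: each draw flips 10% of the items and
randomly permutes labels. The optimiser recovers the generating partition
in every restart; its expected VI of 0.71 bits is the average information
distance between the summary and the individual draws (the noise floor of
this sample), and it beats the best single sampled partition (the sample
mode, 0.84 bits). The full pipeline also runs end-to-end on synthetic
Gaussian mixtures: `generate_mixture_data()` draws labelled data from stock
two-dimensional designs and `dpgmm_collapsed_gibbs()` produces a posterior
partition sample from a demonstration Dirichlet-process mixture sampler.

A command-line wrapper with subcommands `summarise`, `compress`, `compare`,
`psm`, `simulate` and `sample` is installed at
`system.file("exec", "eplclust", package = "eplclust")`.

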