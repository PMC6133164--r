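Package: eplclust
Title: Optimal Clustering Point Estimates from Posterior Partition Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarises an MCMC sample of partitions (cluster allocation
    vectors) into a single optimal clustering by greedy minimisation of the
    estimated expected posterior loss, under a family of contingency-table
    loss functions: Binder's loss, the variation of information (VI) and its
    normalised variants (NVI, NID). The number of groups is selected
    automatically. Includes compression of the sample into weighted
    equivalence classes, posterior similarity matrix utilities, exact
    exhaustive minimisation for small problems, synthetic Gaussian-mixture
    generators and a demonstration collapsed Gibbs sampler for a
    Dirichlet-process Gaussian mixture, so the full pipeline can be
    exercised without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
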