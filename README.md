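# branchcov

Fast estimation of the covariance between pairwise maximum-likelihood
(ML) evolutionary distances.

## The problem

Pairwise evolutionary distances are leaf-to-leaf path lengths on a
phylogenetic tree, estimated by ML under a Markov substitution model.
Two estimates whose paths overlap — `d_ij` and `d_kl` when both paths
traverse a shared branch segment of length `δ_m` — covary, because the
mutations on the shared segment enter both estimates.  Distance-based
tree building, progressive-alignment guide trees and any test on
distance differences gain precision when that covariance is available,
yet the distances are estimated one alignment at a time, so joint-ML
covariance theory does not apply.

`branchcov` implements a constant-time estimator built on a structural
identity: the covariance of two distance estimates with shared path
length `δ_m` equals the variance of a single pairwise ML distance
estimate whose true distance is `δ_m`,

    cov(d̂_ij, d̂_kl) = [ n · I₁(δ̂_m) ]⁻¹ ,

where `I₁` is the per-site Fisher information of a pairwise distance and
`δ̂_m` is recovered from the six pairwise distances of the quartet
`(i, j, k, l)` by weighted least squares.  Under the r-state symmetric
(Jukes–Cantor-type) model the identity is exact and closed-form, with
`β = (r−1)/r`:

    cov(d̂_ij, d̂_kl) = β[(1−β)e^{2δ_m/β} + (2β−1)e^{δ_m/β} − β] / n .

The package provides, for users in phylogenetics and comparative
genomics:

* pairwise ML distances with inverse-information and sample-average
  variances, for the built-in r-state symmetric models and for any
  PAML-format general Markov model (`estimate_distance_ml`,
  `pairwise_distance_table`);
* the branch-covariance pipeline — WLS topology selection, shared-path
  estimation, covariance evaluation, batch all-pairs application and a
  precomputed lookup table (`branch_covariance`, `covariance_matrix`,
  `build_info_table`);
* the linear-time sample-average (Susko) covariance baseline
  (`susko_covariance`);
* a quartet simulator with exact pattern-probability oracle, optional
  Zipfian indels and global re-alignment, plus a Monte-Carlo harness
  that validates every estimator against replicate sample covariances
  (`evolve_quartet`, `joint_pattern_probability`,
  `monte_carlo_experiment`, `mse_comparison`).

## Worked example

Simulate a quartet under Jukes–Cantor, estimate all six distances, and
ask for the covariance between the two distances that cross the middle
branch (true length 0.08):

```r
library(branchcov)
model <- make_nr_model(4)                     # Jukes-Cantor, beta = 3/4
q <- quartet(c(0.12, 0.18, 0.15, 0.10, 0.08),
             labels = c("t1", "t2", "t3", "t4"))
aln <- evolve_quartet(model, q, length = 2000, seed = 42)
dt <- pairwise_distance_table(model, apply(aln, 2, paste, collapse = ""))
dt
#>   taxon_a taxon_b  d_hat  variance    n saturated
#> 1      t1      t2 0.3907 0.0003001 2000     FALSE
#> 2      t1      t3 0.2783 0.0001874 2000     FALSE
#> ...
res <- covariance_matrix(model, dt)
subset(res$records, pair_a == "t1:t2" & pair_b == "t3:t4")
#>   pair_a pair_b topology delta_m_hat       cov zero_reason
#> 6  t1:t2  t3:t4       T1     0.09034 4.954e-05        none
```

The WLS step recovers the shared path (`delta_m_hat` 0.090 vs the true
0.08 at this sequence length) and the covariance `4.95e-05` is the
inverse Fisher information at that length — compare the analytic value
`nr_covariance(4, 0.08, 2000) = 4.34e-05`.  Pairs of distances that the
topology test finds edge-disjoint get `cov = 0` with
`zero_reason = "independent-topology"`.

The Monte-Carlo harness confirms the estimate against the replicate
sample covariance (the unbiased reference):

```r
monte_carlo_experiment(model, q, 2000, 5000, seed = 7)
#> Monte-Carlo experiment (dependence case): n = 2000, reps = 5000 (5000 used)
#>   true shared path 0.08, analytic covariance 4.34e-05
#>   MC covariance 4.355e-05 (SE 3.765e-06)
#>   estimator      mean        sd       bias      mse
#> 1    branch 4.352e-05 5.206e-06 -3.285e-08 2.71e-11
#> 2     susko 4.351e-05 6.686e-06 -4.494e-08 4.47e-11
```

Both estimators are centred on the reference; the branch-covariance has
the smaller spread and mean squared error — the property that motivates
it.

A thin command-line front end wraps the same functions
(`inst/cli/branchcov.R`; subcommands `estimate`, `cov`, `table`,
`simulate`, `validate`).  See the vignette
`vignettes/branch-covariance.Rmd` for the model, the derivation sketch,
all tunable parameters and the design choices.

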