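---
title: "Estimating the covariance between pairwise ML evolutionary distances"
author: "branchcov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the covariance between pairwise ML evolutionary distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchcov)
```

## The problem

Pairwise evolutionary distances summarise a set of homologous sequences by
the leaf-to-leaf path lengths of their underlying phylogenetic tree.  Two
distance estimates whose paths overlap — say $d_{ij}$ and $d_{kl}$ when the
paths $i \leadsto j$ and $k \leadsto l$ both traverse a middle branch of
length $\delta_m$ — covary, because the mutations on the shared segment
enter both estimates.  Any procedure that compares or combines distances
(distance-based tree building, BioNJ-style weighting, tests on distance
differences) gains precision when this covariance structure is available.

Joint ML estimation of all distances would deliver a covariance matrix
through the observed information, but pairwise distances are in practice
estimated *separately*, one alignment at a time, so that route is closed.
The estimator implemented here instead exploits a structural fact: under a
Markov substitution model, the covariance of two distance estimates with a
shared path of length $\delta_m$ is asymptotically the *variance of a
single pairwise ML distance estimate whose true distance is* $\delta_m$.
Evaluating that variance costs constant time in the sequence length, so
the covariance estimate is essentially free once the distances and their
variances have been computed — in contrast to the linear-time
sample-average estimator it is compared against.

## Distance machinery

For an alignment of $n$ i.i.d. character pairs with pair probabilities
$p(x, d) = \pi_u [\mathrm e^{Qd}]_{uv}$, the package maximises
$\sum_{u,v} F_{uv} \log p(x_{uv}, d)$ over $d \ge 0$.  The variance
attached to an estimate is the inverse Fisher information

$$ \hat V(\hat d) = \Big( n \sum_{u,v} \Big[
   \tfrac{(\partial_d p)^2}{p} - \partial^2_d p \Big] \Big)^{-1}, \qquad
   \partial^{(k)}_d p(x_{uv}, d) = \pi_u [Q^k \mathrm e^{Qd}]_{uv}, $$

with an observed-information (sample-average) alternative computed from
the realised counts.  Under the $r$-state symmetric model ($N_r$; uniform
frequencies, a single exchange rate, $r = 4$ is Jukes–Cantor) everything
is closed form: with $\beta = (r-1)/r$ and $I$ differing sites,

$$ \hat d = -\beta \log\left(1 - \tfrac{I}{n\beta}\right), \qquad
   \hat V(\hat d) = \beta\left[(1-\beta)\mathrm e^{2d/\beta} +
   (2\beta - 1)\mathrm e^{d/\beta} - \beta\right] / n . $$

For other models a safeguarded Newton–Raphson iteration on the score is
used, started from the mismatch fraction mapped through the symmetric
transform, with a bisection fallback whenever a step leaves the bracketing
interval $[10^{-9}, \text{ceiling}]$, and convergence declared when the
step or the score falls below $10^{-9}$.  The two routes agree to better
than $10^{-8}$ on the symmetric model (this is among the acceptance
checks).

### Units, saturation, gaps

* Distances are expressed in **expected substitutions per site**: every
  model is calibrated so that $-\sum_u \pi_u Q_{uu} = 1$.  Multiply by 100
  for PAM-style units.
* When the mismatch fraction reaches $\beta$ the symmetric-model estimate
  diverges.  Estimates are then reported at a configurable **ceiling**
  (default 10 substitutions/site) with a `saturated` flag, and the
  variance is evaluated at the ceiling point — never reported infinite.
* Alignment columns containing a gap or any character outside the model
  alphabet are excluded from the pair counts; the quartet-column input of
  the sample-average covariance drops a column if *any* of its four
  characters is unusable, since the expectation it approximates is over
  complete quartets.

## The covariance estimator

Given the six distance estimates $\{\hat d_{uv}\}$ and variances
$\{v_{uv}\}$ among four taxa $(i, j, k, l)$, the estimator proceeds in
three steps.

**1. Topology.**  The three unrooted quartet topologies
$T_1 = ((i,k),(j,l))$, $T_2 = ((i,l),(j,k))$, $T_3 = ((i,j),(k,l))$ are
scored by a weighted least-squares statistic built from the four-point
condition; for $T_1$,

$$ S(T_1) = \frac{(\hat d_{ij} + \hat d_{kl} - \hat d_{il} -
   \hat d_{jk})^2}{v_{ij} + v_{kl} + v_{il} + v_{jk}}, $$

and analogously for the other two.  The minimiser is selected.  The
numerator is **squared** by design: a signed residual is minimised by the
most negative misfit rather than the best fit (a noiseless $T_1$ input
would then select $T_3$), while the squared form makes $S(T) = 0$
characterise an exact additive fit.  Ties involving $T_3$ resolve to
$T_3$ — the conservative choice, reporting a zero covariance rather than
fabricating a positive one.  If $T_3$ wins, the two target distances
$(\hat d_{ij}, \hat d_{kl})$ use disjoint edges and the covariance is
exactly zero.

**2. Shared path length.**  Under $T_1$ the unconstrained WLS estimate of
twice the shared segment is

$$ 2\hat\delta_m(T_1) = \frac{(\hat d_{ij} + \hat d_{kl})(v_{il} + v_{jk})
   + (\hat d_{il} + \hat d_{jk})(v_{ij} + v_{kl})}
   {v_{ij} + v_{kl} + v_{il} + v_{jk}} - (\hat d_{ik} + \hat d_{jl}), $$

(mirrored for $T_2$).  On exactly additive input this recovers
$\delta_m$ to machine precision for any positive weights.  Being
unconstrained, it can come out negative on noisy input; a negative raw
value yields a zero covariance (`zero_reason = "negative-delta"`).  When
the two distances share a taxon ($d_{ij}$ and $d_{jk}$) the quartet
degenerates and the three-point formula
$(\hat d_{ij} + \hat d_{jk} - \hat d_{ik})/2$, clamped at zero, is used
instead.

**3. Covariance.**  The covariance is the inverse Fisher information of a
pairwise distance at $\hat\delta_m$:
$\widehat{\mathrm{cov}} = \big(n\, \mathcal I_1(\hat\delta_m)\big)^{-1}$,
where $\mathcal I_1$ is the per-site information above.  Under $N_r$ this
equals the closed-form variance evaluated at $\hat\delta_m$, which is how
the symmetric route `nr_covariance()` is implemented.  Below
$\delta_m = 10^{-8}$ the information diverges and the covariance is zero
by contract (this also avoids the $0/0$ in the score term at exactly
$\delta_m = 0$).

Why is the variance-at-$\delta_m$ the right quantity?  Under $N_r$ it is a
theorem, provable by enumerating the $r^4$ leaf patterns of the quartet:
the per-site covariance of the mismatch indicators of the two pairs has
the closed form

$$ \mathrm{cov}(S_{ij}, S_{kl}) = \beta\big[(1-\beta)
   \mathrm e^{-(d_{ij}+d_{kl}-2\delta_m)/\beta} + (2\beta-1)
   \mathrm e^{-(d_{ij}+d_{kl}-\delta_m)/\beta} - \beta\,
   \mathrm e^{-(d_{ij}+d_{kl})/\beta}\big], $$

and pushing it through the delta method (the derivative of the distance
transform at the expected mismatch count is $\mathrm e^{d/\beta}/n$)
collapses everything except the $\delta_m$ terms, leaving exactly the
closed-form variance at $\delta_m$.  `joint_pattern_probability()` is the
package's brute-force enumeration of those pattern probabilities; the
test suite verifies the closed form against it to $10^{-10}$ for
$r \in \{2, 3, 4\}$ at random branch lengths.  For general Markov models
the identity is a (well-corroborated) conjecture; the Monte-Carlo harness
checks it empirically.

During the derivation above we found that the intermediate closed form
for $E[S_{ij} S_{kl}]$ must open with the term $\beta$ inside the bracket
(so that the expression vanishes when all branch lengths are zero); with
that leading term the expression is consistent with the covariance
formula quoted above and with the exact enumeration.  The package treats
the enumeration as ground truth throughout.

### Batch application and the lookup table

`covariance_matrix()` applies the machinery to every pair of taxon-pairs
in a distance table: disjoint pairs run the quartet pipeline, pairs
sharing a taxon the three-point formula, and the diagonal carries the
input variances.  For large batches under expensive models,
`build_info_table()` precomputes the per-site information on a grid
(default $[0.001, 5]$, step $0.001$) so each covariance becomes a table
lookup.  Interpolation is linear **in log-log coordinates**: the
information behaves like $1/\delta$ near the origin, where raw linear
interpolation loses several digits, while $\log \mathcal I_1$ is nearly
linear in $\log \delta$ across the whole grid (the table route agrees
with direct evaluation to better than $10^{-5}$ relative in the tests).

### Open choices, resolved

* **Which variance feeds the WLS weights** is not dictated by the theory;
  the package defaults to the inverse-information (ML) variance and can
  use the sample-average variance instead (`weights = "sample"`), since
  both estimate the same quantity and the weights only enter through
  ratios.
* **Which $n$ enters the covariance** when the two alignments differ in
  length (the optimal-pairwise-alignment situation): the default is the
  rounded geometric mean of $n_{ij}$ and $n_{kl}$ — symmetric in the two
  pairs and exact when they agree — with `"min"` available as the
  conservative alternative.

## The baseline: sample-average (Susko) covariance

For distances derived from the *same* MSA columns, the score-product
estimator

$$ \widehat{\mathrm{cov}}(\hat d_{ij}, \hat d_{kl}) = n\, v_{ij} v_{kl}
   \cdot \frac1n \sum_{\text{columns}}
   \partial_d \log p_{ij}(x, d)\big|_{\hat d_{ij}} \cdot
   \partial_d \log p_{kl}(x, d)\big|_{\hat d_{kl}} $$

is unbiased and linear-time.  Scores are evaluated at the plug-in
estimates (the true distances being unknown in practice).  It serves two
roles here: the baseline against which the branch-covariance's mean
squared error is compared, and an independent estimate of the same
quantity in the cross-validation tests.  It requires an MSA, so the
Monte-Carlo harness skips it in gapped/re-aligned (OPA) runs.

## What the simulator emulates

`sample_quartet()` draws the four terminal branches uniformly from
$[0.02, 0.8]$ and the middle branch from $[0.01, 0.5]$ substitutions/site
— spanning shallow to deeply diverged quartets of the kind found across a
broad species tree — then dilates all five lengths by a common
$U(0.5, 2)$ factor, exploring more extreme regions of branch-length space
while preserving the relative structure.  `evolve_quartet()` draws root
states from $\pi$ on the middle edge and propagates them with
$\mathrm e^{Q\delta}$ along each branch; sites are i.i.d., so the site
index is the true alignment.

The indel layer (`apply_indels()`) deletes, per sequence and per site
with probability `gap_rate` (default 0.01), a stretch whose length is
Zipf-distributed with exponent 1.821 truncated at 50 — a power-law shape
with an exponent in the range repeatedly fitted to real indel length
spectra; all three parameters are configurable.  Gapped sequences are
re-aligned by global Needleman–Wunsch with affine penalties (defaults:
open 10, extend 1) under a log-odds matrix derived from the model at a
reference distance of 1 substitution/site, in half-bit units.  Insertions
are not modelled separately: for pairwise distance estimation only the
loss and misalignment of homologous columns matters, and deletions
produce both.

What the simulator deliberately does **not** model: rate heterogeneity
across sites, non-stationary or non-reversible processes, selection, and
alignment uncertainty beyond the pairwise re-alignment of truly homologous
sequences.  Tests passing on these simulations therefore demonstrate
correctness of the estimators *under their own model assumptions*; with
real data the model is always misspecified to some degree, and estimators
that read the realised character frequencies (like the sample-average
baseline) may be more robust than one that trusts $Q$ and $\pi$.

## Monte-Carlo validation

`monte_carlo_experiment()` simulates replicates, estimates the six
distances in each, applies both covariance estimators to a designated
pair, and reports each estimator's mean, bias and MSE against the
replicate sample covariance (the *Monte-Carlo covariance*), which is the
unbiased reference.  The three topological relations are realised on one
and the same quartet by choosing the target pair: $(d_{ij}, d_{kl})$
crosses the middle branch (dependence), $(d_{ij}, d_{jk})$ shares taxon
$j$ (triplet, true shared path $\delta_j + \delta_m$), and
$(d_{ik}, d_{jl})$ is edge-disjoint (independence, true covariance zero).

Replicates in which a required distance saturates are excluded and
counted; past 5% of the replicates this is escalated to a warning,
because conditioning on non-saturation biases the Monte-Carlo reference
itself.  For the same reason the acceptance checks that compare
Monte-Carlo references against closed forms draw their quartets from the
default generator *conditioned on all six true distances staying below 2
substitutions/site* — at the sequence lengths used there ($n \le 1000$),
saturation is then a $<10^{-3}$ event and the references are clean.  The
generator's dilation factor still reaches the same extremes; only the
reference comparisons are restricted.

For symmetric models on ungapped alignments the whole replicate loop is
vectorised (the mismatch counts are sufficient, and the per-column scores
of the sample-average estimator take only two values, so its column
average reduces to joint mismatch counts).  General models and gapped
runs fall back to an explicit per-replicate loop and are used at smaller
scale in the tests.

Problem sizes used by the shipped validation (chosen to give 3-standard-
error resolution on every reference while keeping a full run in the low
minutes): the conjecture check runs 10 quartets at 10,000 replicates and
$n = 1000$ plus a through-origin regression at $n = 10{,}000$; the MSE
comparison 20 quartets at 2,000 replicates and $n = 500$; the bias check
10,000 replicates at $n = 1000$.

## Numerical choices

* Matrix exponentials use the spectral decomposition of the
  $\pi$-symmetrised generator for reversible models (orthogonal, hence
  stable), a general eigendecomposition otherwise, and scaling-and-
  squaring with a Padé(6) core as the last resort; the routes agree to
  $10^{-10}$ on the shipped models and are cross-checked against an
  independent implementation in the tests.
* $d = 0$ is special-cased to the exact identity/rate-matrix limits so
  that impossible pairs have probability exactly zero (the spectral
  reconstruction would leave an $O(\epsilon)$ residue, silently turning
  $-\infty$ log-likelihoods into large finite ones).
* A mismatch observed at $d = 0$ yields a $-\infty$ log-likelihood by
  contract, not an error; degenerate variance requests ($\hat d \le 0$,
  or non-positive observed information) return 0 with a `degenerate`
  flag.
* All stochastic functions are pure functions of their seed; the
  Monte-Carlo engines chunk replicates to bound memory at about
  $2 \times 10^6$ states per node.

## Known limitations

The estimator inherits the negative bias of the inverse-information
variance (visible in the validation as a mean ML-variance/Monte-Carlo-
variance ratio slightly below one), and its accuracy degrades together
with the WLS shared-path estimate when all six quartet distances are
near saturation.  The independence-case covariance is exactly zero only
when the topology test selects $T_3$; on noisy data near-additive ties
can leak small positive covariances.  Rate heterogeneity, codon models
and ambiguity-aware likelihoods are out of scope.  The shipped 20-state
exchangeability file is a *synthetic* stand-in with the statistical
shape of an empirical amino-acid model — substitute any PAML-format
matrix of your own via `read_paml_model()`.
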