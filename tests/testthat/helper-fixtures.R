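# Shared fixtures for the test suite.  Everything is built in code.

nr4 <- make_nr_model(4)

# A fixed reversible general-Markov ("GTR-style") 4-state model with
# unequal frequencies, used wherever the closed forms must not apply.
make_test_gtr <- function(seed = 2) {
  set.seed(seed)
  pi <- c(0.35, 0.25, 0.25, 0.15)
  S <- matrix(0, 4, 4)
  S[lower.tri(S)] <- runif(6, 0.5, 2)
  S <- S + t(S)
  Q <- S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  substitution_model(Q, pi, name = "test-gtr")
}

gtr4 <- make_test_gtr()

# Exact N_r site-pair counts with I mismatches spread evenly off-diagonal
nr_counts <- function(r, I, n) {
  F <- matrix(I / (r * (r - 1)), r, r)
  diag(F) <- (n - I) / r
  site_pair_counts(F)
}

# Six additive distances (role order ij, ik, il, jk, jl, kl) of a quartet
additive_distances <- function(q) quartet_true_distances(q)

# Eq-style closed-form per-site covariance of the mismatch indicators of
# the two crossing pairs of an N_r quartet (dependence layout): the
# analytic target the pattern enumeration must reproduce.
nr_indicator_cov <- function(r, d_ij, d_kl, delta_m) {
  beta <- (r - 1) / r
  beta * ((1 - beta) * exp(-(d_ij + d_kl - 2 * delta_m) / beta) +
            (2 * beta - 1) * exp(-(d_ij + d_kl - delta_m) / beta) -
            beta * exp(-(d_ij + d_kl) / beta))
}

# Per-site E[S_ij * S_kl] and cov(S_ij, S_kl) from the exact pattern
# enumeration (the brute-force oracle)
enumeration_indicator_cov <- function(model, q) {
  jp <- joint_pattern_probability(model, q)
  r <- model$r
  idx <- as.matrix(expand.grid(a = 1:r, b = 1:r, c = 1:r, e = 1:r))
  both <- idx[, "a"] != idx[, "b"] & idx[, "c"] != idx[, "e"]
  e_ss <- sum(jp[idx[both, , drop = FALSE]])
  td <- quartet_true_distances(q)
  e_ss - nr_mutation_probability(r, td[["ij"]]) *
    nr_mutation_probability(r, td[["kl"]])
}

# Brute-force global alignment score by exhaustive enumeration (affine
# gaps: a gap of length L costs open + L * extend), independent of any
# dynamic-programming implementation.
brute_force_align_score <- function(a, b, S, open, extend) {
  rec <- function(i, j, last) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b))
      best <- max(best, S[a[i], b[j]] + rec(i + 1L, j + 1L, "M"))
    if (i <= length(a))
      best <- max(best, -extend - (if (last == "D") 0 else open) +
                    rec(i + 1L, j, "D"))
    if (j <= length(b))
      best <- max(best, -extend - (if (last == "I") 0 else open) +
                    rec(i, j + 1L, "I"))
    best
  }
  rec(1L, 1L, "M")
}
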