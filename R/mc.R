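#' Monte-Carlo validation of the covariance estimators
#'
#' Repeatedly simulates sequence evolution along a quartet, estimates the
#' pairwise distances and variances in every replicate, and applies the
#' branch-covariance (and, on true MSAs, the Susko covariance) to a
#' designated pair of distances.  The replicate sample covariance of the
#' two distance estimates (the Monte-Carlo covariance) is the unbiased
#' reference against which each estimator's bias and mean squared error
#' are reported.
#'
#' The designated pair depends on `case` (role labelling of the quartet):
#' `"dependence"` uses `(d_ij, d_kl)` whose paths share the middle branch;
#' `"triplet"` uses `(d_ij, d_jk)` which share taxon `j`; and
#' `"independence"` uses `(d_ik, d_jl)` whose paths are edge-disjoint.
#'
#' Replicates in which a required distance saturates (mismatch fraction
#' at or beyond the model's saturation level, or the estimate at the
#' ceiling) are excluded from the summaries; a warning is raised when
#' they exceed 5\% of the replicates.
#'
#' For r-state symmetric models on ungapped alignments the simulation and
#' estimation are fully vectorised over replicates; general models and
#' gapped/realigned runs fall back to a per-replicate loop and should be
#' used at smaller scale.
#'
#' @param model a [substitution_model].
#' @param q a [quartet()] (dependence layout, `sides = c(1, 3)`).
#' @param length alignment length (sites per replicate).
#' @param reps number of replicates (`>= 100`).
#' @param seed optional integer seed; the result is a pure function of it.
#' @param case which topological relation the designated pair realises.
#' @param gapped introduce indels and re-align each pair (OPA mode); the
#'   Susko estimator is skipped since it requires an MSA.
#' @param im an [indel_model()]; required when `gapped = TRUE`.
#' @param scoring alignment scoring matrix for OPA mode (default
#'   [model_score_matrix()] at reference distance 1).
#' @param ceiling distance saturation ceiling.
#' @param keep keep the per-replicate estimates in the result.
#' @return An object of class `monte_carlo_result`: list with `case`,
#'   `reps`, `reps_used`, `n_saturated`, `true` (true distances, shared
#'   path length and analytic covariance at the true shared path),
#'   `reference` (MC covariance/variances with standard errors),
#'   `estimators` (per-estimator mean, sd, bias and MSE vs the MC
#'   reference) and `ml_variance_mean` (replicate mean of the ML variance
#'   of the two designated distances, for bias assessment).
#' @export
monte_carlo_experiment <- function(model, q, length, reps, seed = NULL,
                                   case = c("dependence", "triplet",
                                            "independence"),
                                   gapped = FALSE, im = NULL,
                                   scoring = NULL, ceiling = 10,
                                   keep = FALSE) {
  stopifnot(inherits(model, "substitution_model"), inherits(q, "quartet"))
  case <- match.arg(case)
  if (reps < 100) stop("reps must be >= 100 for stable references")
  if (gapped && is.null(im)) stop("gapped simulation needs an indel_model")
  if (!is.null(seed)) set.seed(seed)
  if (!identical(q$sides, c(1L, 3L)))
    stop("monte_carlo_experiment expects the dependence layout sides = c(1, 3)")
  fast <- !gapped && !is.na(model$beta)
  per <- if (fast) mc_replicates_nr(model, q, length, reps, case, ceiling)
         else mc_replicates_general(model, q, length, reps, case, gapped,
                                    im, scoring, ceiling)
  ok <- !per$saturated
  n_sat <- sum(!ok)
  if (n_sat > 0.05 * reps)
    warning(sprintf("%d of %d replicates (%.1f%%) saturated and were excluded",
                    n_sat, reps, 100 * n_sat / reps))
  dA <- per$d_A[ok]; dB <- per$d_B[ok]
  mc_cov <- stats::cov(dA, dB)
  cov_se <- stats::sd((dA - mean(dA)) * (dB - mean(dB))) / sqrt(length(dA))
  var_se <- function(x) stats::sd((x - mean(x))^2) / sqrt(length(x))
  true_d <- quartet_true_distances(q)
  true_sp <- quartet_shared_length(q, case)
  true_cov <- if (true_sp > 0) general_covariance(model, true_sp, length)
              else 0
  summarise <- function(x) {
    x <- x[ok]
    c(mean = mean(x), sd = stats::sd(x),
      bias = mean(x) - mc_cov, mse = mean((x - mc_cov)^2))
  }
  est <- list(branch = summarise(per$branch))
  if (!is.null(per$susko)) est$susko <- summarise(per$susko)
  est <- as.data.frame(do.call(rbind, est))
  est$estimator <- rownames(est)
  rownames(est) <- NULL
  out <- structure(list(
    case = case, n = length, reps = reps, reps_used = sum(ok),
    n_saturated = n_sat,
    true = list(distances = true_d, shared_path = true_sp,
                covariance = true_cov),
    reference = list(cov = mc_cov, cov_se = cov_se,
                     var_A = stats::var(dA), var_A_se = var_se(dA),
                     var_B = stats::var(dB), var_B_se = var_se(dB)),
    estimators = est[c("estimator", "mean", "sd", "bias", "mse")],
    ml_variance_mean = c(A = mean(per$v_A[ok]), B = mean(per$v_B[ok]))),
    class = "monte_carlo_result")
  if (keep) out$replicates <- per
  out
}

#' @export
print.monte_carlo_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo experiment (%s case): n = %d, reps = %d (%d used)\n",
              x$case, x$n, x$reps, x$reps_used))
  cat(sprintf("  true shared path %.4g, analytic covariance %.4g\n",
              x$true$shared_path, x$true$covariance))
  cat(sprintf("  MC covariance %.4g (SE %.4g)\n",
              x$reference$cov, x$reference$cov_se))
  print(x$estimators, digits = 4)
  invisible(x)
}

# role pair -> leaf positions, per case
mc_target_positions <- function(case) {
  switch(case,
         dependence = list(A = c(1L, 2L), B = c(3L, 4L)),
         triplet = list(A = c(1L, 2L), B = c(2L, 3L)),
         independence = list(A = c(1L, 3L), B = c(2L, 4L)))
}

# Vectorised replicate engine for r-state symmetric models, ungapped.
# Returns per-replicate vectors: d_A, d_B, v_A, v_B, branch, susko,
# saturated.
mc_replicates_nr <- function(model, q, n, reps, case, ceiling) {
  r <- model$r; beta <- model$beta
  keep_e <- exp(-q$delta / beta)  # per-branch copy probabilities (i,j,k,l,m)
  tgt <- mc_target_positions(case)
  pair_idx <- list(ij = c(1L, 2L), ik = c(1L, 3L), il = c(1L, 4L),
                   jk = c(2L, 3L), jl = c(2L, 4L), kl = c(3L, 4L))
  need6 <- case != "triplet"
  chunk <- max(1L, min(reps, floor(2e6 / n)))
  I6 <- matrix(0L, reps, 6L, dimnames = list(NULL, names(pair_idx)))
  n11 <- integer(reps)
  done <- 0L
  propagate <- function(anc, e) {
    m <- base::length(anc)
    u <- stats::runif(m) >= e          # sites that redraw uniformly
    anc[u] <- sample.int(r, sum(u), replace = TRUE)
    anc
  }
  while (done < reps) {
    c_now <- min(chunk, reps - done)
    m <- n * c_now
    left <- sample.int(r, m, replace = TRUE)
    right <- propagate(left, keep_e["m"])
    leaves <- vector("list", 4L)
    for (pos in 1:4) {
      anc <- if (pos %in% q$sides) left else right
      leaves[[pos]] <- matrix(propagate(anc, keep_e[pos]), n, c_now)
    }
    rows <- done + seq_len(c_now)
    mm <- list()
    for (p in names(pair_idx)) {
      a <- pair_idx[[p]]
      mm[[p]] <- leaves[[a[1L]]] != leaves[[a[2L]]]
      I6[rows, p] <- colSums(mm[[p]])
    }
    pa <- names(pair_idx)[vapply(pair_idx, identical, TRUE, tgt$A)]
    pb <- names(pair_idx)[vapply(pair_idx, identical, TRUE, tgt$B)]
    n11[rows] <- colSums(mm[[pa]] & mm[[pb]])
    done <- done + c_now
  }
  d6 <- matrix(nr_distance(r, as.vector(I6), n), reps, 6L,
               dimnames = dimnames(I6))
  role_A <- "ij"
  role_B <- switch(case, dependence = "kl", triplet = "jk",
                   independence = "kl")
  # map role pairs to simulated taxon pairs (identity except independence,
  # where the target pair (d_ik, d_jl) takes the (i, j)/(k, l) roles)
  rolemap <- if (case == "independence")
    c(ij = "ik", ik = "ij", il = "il", jk = "jk", jl = "kl", kl = "jl")
  else c(ij = "ij", ik = "ik", il = "il", jk = "jk", jl = "jl", kl = "kl")
  dr <- d6[, rolemap, drop = FALSE]; colnames(dr) <- names(rolemap)
  saturated <- if (need6) apply(!is.finite(dr) | dr >= ceiling, 1L, any)
               else apply(!is.finite(dr[, c("ij", "jk", "ik")]) |
                            dr[, c("ij", "jk", "ik")] >= ceiling, 1L, any)
  dr[!is.finite(dr) | dr > ceiling] <- ceiling
  vr <- matrix(nr_delta_variance(r, as.vector(dr), n), reps, 6L,
               dimnames = dimnames(dr))
  d_A <- dr[, "ij"]; d_B <- dr[, role_B]
  v_A <- vr[, "ij"]; v_B <- vr[, role_B]
  branch <- if (case == "triplet") {
    nr_delta_variance(r, triplet_shared_path(dr[, "ij"], dr[, "jk"],
                                             dr[, "ik"]), n)
  } else {
    s <- topology_scores(dr[, "ij"], dr[, "ik"], dr[, "il"],
                         dr[, "jk"], dr[, "jl"], dr[, "kl"],
                         vr[, "ij"], vr[, "ik"], vr[, "il"],
                         vr[, "jk"], vr[, "jl"], vr[, "kl"])
    raw1 <- shared_path_raw("T1", dr[, "ij"], dr[, "ik"], dr[, "il"],
                            dr[, "jk"], dr[, "jl"], dr[, "kl"],
                            vr[, "ij"], vr[, "ik"], vr[, "il"],
                            vr[, "jk"], vr[, "jl"], vr[, "kl"])
    raw2 <- shared_path_raw("T2", dr[, "ij"], dr[, "ik"], dr[, "il"],
                            dr[, "jk"], dr[, "jl"], dr[, "kl"],
                            vr[, "ij"], vr[, "ik"], vr[, "il"],
                            vr[, "jk"], vr[, "jl"], vr[, "kl"])
    is_t3 <- s$s3 <= s$s1 & s$s3 <= s$s2
    raw <- ifelse(s$s1 <= s$s2, raw1, raw2)
    ifelse(is_t3 | raw < 0, 0, nr_delta_variance(r, pmax(raw, 0), n))
  }
  # Susko: under N_r the per-column scores take one of two values (match
  # or mismatch), so the column average reduces to the joint mismatch
  # counts of the two target pairs
  eA <- exp(-d_A / beta); eB <- exp(-d_B / beta)
  sM_A <- -eA / (1 / r + beta * eA); sM_B <- -eB / (1 / r + beta * eB)
  sm_A <- (1 / beta) * eA / (1 - eA); sm_B <- (1 / beta) * eB / (1 - eB)
  I_A <- I6[, if (case == "independence") "ik" else "ij"]
  I_B <- I6[, switch(case, dependence = "kl", triplet = "jk",
                     independence = "jl")]
  term <- function(coef, sa, sb) ifelse(coef == 0, 0, coef * sa * sb)
  sumprod <- term(n11, sm_A, sm_B) +
    term(I_A - n11, sm_A, sM_B) +
    term(I_B - n11, sM_A, sm_B) +
    term(n - I_A - I_B + n11, sM_A, sM_B)
  susko <- v_A * v_B * sumprod
  list(d_A = d_A, d_B = d_B, v_A = v_A, v_B = v_B,
       branch = branch, susko = susko, saturated = saturated)
}

# Per-replicate engine for general models and/or gapped (OPA) runs.
mc_replicates_general <- function(model, q, n, reps, case, gapped, im,
                                  scoring, ceiling) {
  tgt <- mc_target_positions(case)
  if (gapped && is.null(scoring)) scoring <- model_score_matrix(model)
  pair_idx <- list(ij = c(1L, 2L), ik = c(1L, 3L), il = c(1L, 4L),
                   jk = c(2L, 3L), jl = c(2L, 4L), kl = c(3L, 4L))
  need <- if (case == "triplet") c("ij", "jk", "ik") else names(pair_idx)
  d_A <- d_B <- v_A <- v_B <- branch <- numeric(reps)
  susko <- if (!gapped) numeric(reps) else NULL
  saturated <- logical(reps)
  role_B <- switch(case, dependence = "kl", triplet = "jk",
                   independence = "kl")
  rolemap <- if (case == "independence")
    c(ij = "ik", ik = "ij", il = "il", jk = "jk", jl = "kl", kl = "jl")
  else stats::setNames(names(pair_idx), names(pair_idx))
  for (rep in seq_len(reps)) {
    cols <- evolve_quartet(model, q, n)
    gapped_cols <- if (gapped) apply_indels(cols, im) else cols
    est <- list()
    for (p in need) {
      a <- pair_idx[[rolemap[p]]]
      if (gapped) {
        ug <- ungap_sequences(gapped_cols[, a, drop = FALSE])
        aln <- align_pair(ug[[1L]], ug[[2L]], scoring)
        cnt <- count_site_pairs(aln$a, aln$b, model)
      } else {
        cnt <- count_site_pairs(cols[, a[1L]], cols[, a[2L]], model)
      }
      est[[p]] <- estimate_distance_ml(model, cnt, ceiling = ceiling)
    }
    saturated[rep] <- any(vapply(est, function(e) e$saturated, logical(1)))
    dd <- vapply(est, function(e) e$d_hat, numeric(1))
    vv <- vapply(est, function(e) e$variance, numeric(1))
    d_A[rep] <- dd["ij"]; d_B[rep] <- dd[role_B]
    v_A[rep] <- vv["ij"]; v_B[rep] <- vv[role_B]
    branch[rep] <- if (case == "triplet") {
      dm <- triplet_shared_path(dd["ij"], dd["jk"], dd["ik"])
      general_covariance(model, dm, n)
    } else {
      qd <- quartet_distances(paste0("t", 1:4), dd, pmax(vv, 1e-12),
                              vapply(est, function(e) e$n, numeric(1)))
      branch_covariance(model, qd)$cov
    }
    if (!gapped) {
      qc <- quartet_columns(cols[, c(pair_idx[[rolemap["ij"]]],
                                     pair_idx[[rolemap[role_B]]])], model)
      susko[rep] <- if (d_A[rep] > 0 && d_B[rep] > 0)
        as.numeric(susko_covariance(model, qc, d_A[rep], d_B[rep],
                                    v_A[rep], v_B[rep]))
      else 0
    }
  }
  list(d_A = d_A, d_B = d_B, v_A = v_A, v_B = v_B,
       branch = branch, susko = susko, saturated = saturated)
}

#' Monte-Carlo variance of a pairwise ML distance at a fixed true distance
#'
#' Simulates `reps` pairwise alignments of `n` sites at true distance
#' `d_t`, estimates the ML distance in each, and returns the replicate
#' sample variance with a standard error, together with the mean of the
#' per-replicate ML variance estimates.
#'
#' @param model a [substitution_model].
#' @param d_t true distance.
#' @param n alignment length.
#' @param reps replicates.
#' @param seed optional seed.
#' @param ceiling saturation ceiling.
#' @return List with `mc_var`, `mc_var_se`, `mean_d`, `mean_ml_variance`,
#'   `reps_used`.
#' @export
mc_pairwise_variance <- function(model, d_t, n, reps, seed = NULL,
                                 ceiling = 10) {
  stopifnot(inherits(model, "substitution_model"))
  if (!is.null(seed)) set.seed(seed)
  if (!is.na(model$beta)) {
    p <- nr_mutation_probability(model$r, d_t)
    I <- stats::rbinom(reps, n, p)
    d <- nr_distance(model$r, I, n)
    ok <- is.finite(d) & d < ceiling
    d <- d[ok]
    v <- nr_delta_variance(model$r, d, n)
  } else {
    P <- transition_probability(model, d_t, 0L)
    d <- v <- numeric(reps)
    ok <- logical(reps)
    for (rep in seq_len(reps)) {
      F <- matrix(stats::rmultinom(1L, n, as.vector(P)), model$r, model$r)
      e <- estimate_distance_ml(model, site_pair_counts(F), ceiling)
      d[rep] <- e$d_hat; v[rep] <- e$variance
      ok[rep] <- !e$saturated
    }
    d <- d[ok]; v <- v[ok]
  }
  list(mc_var = stats::var(d),
       mc_var_se = stats::sd((d - mean(d))^2) / sqrt(length(d)),
       mean_d = mean(d), mean_ml_variance = mean(v),
       reps_used = length(d))
}

#' Conjecture check: Monte-Carlo covariance versus variance at the shared
#' path length
#'
#' For each quartet, computes the Monte-Carlo covariance of the two
#' dependent distance estimates and the Monte-Carlo variance of a
#' pairwise ML distance estimated at true distance equal to the quartet's
#' middle branch length.  Under the conjecture underlying the
#' branch-covariance the two agree, so the through-origin regression
#' slope of covariance on variance should be close to 1.
#'
#' @param model a [substitution_model].
#' @param quartets list of [quartet()] objects.
#' @param length alignment length.
#' @param reps replicates per quartet.
#' @param seed optional seed.
#' @return List with `table` (per-quartet `delta_m`, `mc_cov`,
#'   `mc_cov_se`, `mc_var`, `mc_var_se`), `slope`, `slope_se` and the 95\%
#'   confidence interval `slope_ci`.
#' @export
conjecture_check <- function(model, quartets, length = 1000, reps = 10000,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(quartets, function(q) {
    mc <- monte_carlo_experiment(model, q, length, reps, case = "dependence")
    pv <- mc_pairwise_variance(model, quartet_shared_length(q, "dependence"),
                               length, reps)
    data.frame(delta_m = quartet_shared_length(q, "dependence"),
               mc_cov = mc$reference$cov, mc_cov_se = mc$reference$cov_se,
               mc_var = pv$mc_var, mc_var_se = pv$mc_var_se)
  })
  tab <- do.call(rbind, rows)
  fit <- stats::lm(mc_cov ~ 0 + mc_var, data = tab)
  slope <- unname(stats::coef(fit)[1L])
  se <- unname(sqrt(diag(stats::vcov(fit)))[1L])
  list(table = tab, slope = slope, slope_se = se,
       slope_ci = slope + c(-1, 1) * stats::qt(0.975, nrow(tab) - 1L) * se)
}

#' Mean-squared-error comparison of the covariance estimators
#'
#' Runs [monte_carlo_experiment()] over a collection of quartets, sequence
#' lengths and topological cases, and summarises each estimator's MSE
#' against the Monte-Carlo reference covariance: average and median MSE
#' per estimator and case, and the average per-quartet ratio of the
#' branch-covariance MSE to the Susko-covariance MSE.
#'
#' @param model a [substitution_model].
#' @param quartets list of [quartet()] objects (>= 1; 10+ recommended for
#'   stable averages).
#' @param lengths vector of alignment lengths.
#' @param reps replicates per experiment (`>= 1000` recommended).
#' @param seed optional seed.
#' @param cases subset of the three topological cases.
#' @param conjecture also run [conjecture_check()] on the same quartets.
#' @param conjecture_length,conjecture_reps problem size for the
#'   conjecture check.
#' @return List with `rows` (one row per quartet x length x case),
#'   `summary` (per case x length aggregates) and optionally
#'   `conjecture`.
#' @export
mse_comparison <- function(model, quartets, lengths = 500, reps = 2000,
                           seed = NULL,
                           cases = c("dependence", "triplet",
                                     "independence"),
                           conjecture = FALSE, conjecture_length = 10000,
                           conjecture_reps = 2000) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (case in cases) for (n in lengths)
    for (iq in seq_along(quartets)) {
      mc <- monte_carlo_experiment(model, quartets[[iq]], n, reps,
                                   case = case)
      e <- mc$estimators
      get <- function(est, col) {
        x <- e[e$estimator == est, col]
        if (length(x)) x else NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        case = case, n = n, quartet = iq,
        shared_path = mc$true$shared_path, mc_cov = mc$reference$cov,
        mc_var_A = mc$reference$var_A,
        ml_var_mean_A = unname(mc$ml_variance_mean["A"]),
        branch_mean = get("branch", "mean"),
        branch_mse = get("branch", "mse"),
        susko_mean = get("susko", "mean"),
        susko_mse = get("susko", "mse"))
    }
  rows <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(rows, list(rows$case, rows$n),
                                     drop = TRUE), function(g)
    data.frame(case = g$case[1L], n = g$n[1L],
               branch_avg_mse = mean(g$branch_mse),
               branch_med_mse = stats::median(g$branch_mse),
               susko_avg_mse = mean(g$susko_mse),
               susko_med_mse = stats::median(g$susko_mse),
               avg_mse_ratio = mean(g$branch_mse / g$susko_mse))))
  rownames(agg) <- NULL
  out <- list(rows = rows, summary = agg)
  if (conjecture)
    out$conjecture <- conjecture_check(model, quartets, conjecture_length,
                                       conjecture_reps)
  out
}
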