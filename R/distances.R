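#' Site-pair counts for a pairwise alignment
#'
#' Summary of a gap-free pairwise alignment as an r x r matrix `F` of
#' aligned ordered character-pair counts.  `n = sum(F)` is the number of
#' homologous columns and `I` the number of differing sites (off-diagonal
#' total); under the r-state symmetric model `I` is a sufficient statistic
#' for the ML distance.
#'
#' @param F non-negative r x r count matrix (rows: first sequence).
#' @return An object of class `site_pair_counts` with elements `F`, `n`, `I`.
#' @seealso [count_site_pairs()] to build counts from aligned sequences.
#' @export
site_pair_counts <- function(F) {
  F <- as.matrix(F)
  if (nrow(F) != ncol(F)) stop("F must be square")
  if (any(F < 0)) stop("counts must be >= 0")
  n <- sum(F)
  if (n < 1) stop("n must be >= 1: empty alignment")
  structure(list(F = F, n = n, I = n - sum(diag(F))),
            class = "site_pair_counts")
}

#' @export
print.site_pair_counts <- function(x, ...) {
  cat("Site-pair counts: n =", x$n, ", differing sites I =", x$I, "\n")
  invisible(x)
}

#' Count aligned character pairs
#'
#' Tabulates the aligned columns of two equal-length sequences into a
#' [site_pair_counts()] object.  Columns in which either character is not
#' in the model alphabet (gaps, ambiguity codes) are excluded.
#'
#' @param a,b aligned sequences: single strings or character vectors of
#'   single characters, equal length after splitting.
#' @param model a [substitution_model] supplying the alphabet.
#' @return A [site_pair_counts()] object.
#' @export
count_site_pairs <- function(a, b, model) {
  stopifnot(inherits(model, "substitution_model"))
  a <- split_chars(a); b <- split_chars(b)
  if (length(a) != length(b))
    stop("aligned sequences must have equal length")
  ia <- match(a, model$alphabet)
  ib <- match(b, model$alphabet)
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) stop("no gap-free alignment columns in the model alphabet")
  r <- model$r
  F <- matrix(tabulate((ia[keep] - 1L) * r + ib[keep], nbins = r * r),
              r, r, byrow = TRUE, dimnames = list(model$alphabet, model$alphabet))
  site_pair_counts(F)
}

split_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1]] else as.character(x)
}

#' Log-likelihood of a pairwise distance
#'
#' Log of the product over alignment columns of the joint pair
#' probabilities at distance `d`:
#' `sum(F * log(pi_u [exp(Q d)]_{uv}))`.  An observed pair with zero
#' probability (e.g. a mismatch at `d = 0`) yields `-Inf`.
#'
#' @param model a [substitution_model].
#' @param counts a [site_pair_counts()] object.
#' @param d distance `>= 0`.
#' @return The log-likelihood (possibly `-Inf`).
#' @export
pair_log_likelihood <- function(model, counts, d) {
  stopifnot(inherits(counts, "site_pair_counts"))
  P <- transition_probability(model, d, 0L)
  lp <- suppressWarnings(log(pmax(P, 0)))
  used <- counts$F > 0
  if (any(used & P <= 0)) return(-Inf)
  sum(counts$F[used] * lp[used])
}

#' Closed-form ML distance under the r-state symmetric model
#'
#' `d = -beta * log(1 - I / (n beta))` with `beta = (r-1)/r`: the ML
#' distance given `I` differing sites out of `n`.  When `I/n >= beta` the
#' estimate is saturated and `Inf` is returned; the caller decides the
#' ceiling (see [estimate_distance_ml()]).
#'
#' @param r alphabet size.
#' @param I number of differing sites (vectorised).
#' @param n alignment length.
#' @return Distance(s); `Inf` where saturated.
#' @export
nr_distance <- function(r, I, n) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(I < 0 | I > n)) stop("I must satisfy 0 <= I <= n")
  beta <- (r - 1) / r
  arg <- 1 - I / (n * beta)
  ifelse(arg <= 0, Inf, -beta * log(pmax(arg, 0)))
}

# Per-site expected Fisher information for distance d:
# -sum_{u,v} [ d2p_uv - (dp_uv)^2 / p_uv ]  with p_uv = pi_u [e^{Qd}]_{uv}
info_per_site <- function(model, d) {
  P0 <- transition_probability(model, d, 0L)
  P1 <- transition_probability(model, d, 1L)
  P2 <- transition_probability(model, d, 2L)
  pos <- P0 > 0
  -(sum(P2[pos]) - sum(P1[pos]^2 / P0[pos]))
}

#' Fisher information of a pairwise distance
#'
#' Expected information about the distance carried by `n` i.i.d. aligned
#' character pairs: `-n * E[d^2/dd^2 log p(X, d)]`, assembled from the
#' pair probabilities and their first two distance derivatives.  Its
#' inverse is the asymptotic variance of the ML distance estimate.
#'
#' @param model a [substitution_model].
#' @param d distance `> 0` (the information diverges as `d -> 0`).
#' @param n number of alignment columns.
#' @return The Fisher information (positive).
#' @seealso [ml_variance()]
#' @export
fisher_information <- function(model, d, n) {
  if (d <= 0) stop("d must be > 0: the information diverges as d -> 0")
  n * info_per_site(model, d)
}

#' ML (inverse-information) variance of a distance estimate
#'
#' The large-sample variance of the ML distance: the reciprocal of the
#' Fisher information evaluated at the estimate.  For `d_hat <= 0` the
#' information diverges and the variance is reported as 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param model a [substitution_model].
#' @param d_hat estimated distance.
#' @param n supporting column count.
#' @return The variance estimate.
#' @export
ml_variance <- function(model, d_hat, n) {
  if (d_hat <= 0) {
    v <- 0
    attr(v, "degenerate") <- TRUE
    return(v)
  }
  1 / fisher_information(model, d_hat, n)
}

#' Sample-average (observed-information) variance
#'
#' Observed-information analogue of [ml_variance()]: minus the reciprocal
#' of the sum over the realised alignment columns of the second derivative
#' of the log pair probability, evaluated at `d_hat`.  For r-state
#' symmetric counts it coincides with the expected-information variance at
#' the MLE.
#'
#' @param model a [substitution_model].
#' @param counts a [site_pair_counts()] object.
#' @param d_hat estimated distance `> 0`.
#' @return The variance estimate; attribute `degenerate = TRUE` when the
#'   observed information is not positive.
#' @export
sample_average_variance <- function(model, counts, d_hat) {
  stopifnot(inherits(counts, "site_pair_counts"))
  if (d_hat <= 0) {
    v <- 0; attr(v, "degenerate") <- TRUE
    return(v)
  }
  P0 <- transition_probability(model, d_hat, 0L)
  P1 <- transition_probability(model, d_hat, 1L)
  P2 <- transition_probability(model, d_hat, 2L)
  used <- counts$F > 0
  # d2/dd2 log p = p''/p - (p'/p)^2, summed with multiplicity F
  obs <- -sum(counts$F[used] *
                (P2[used] / P0[used] - (P1[used] / P0[used])^2))
  if (obs <= 0) {
    v <- 0; attr(v, "degenerate") <- TRUE
    return(v)
  }
  1 / obs
}

#' Delta-method variance under the r-state symmetric model
#'
#' Closed-form variance of the ML distance obtained by propagating the
#' binomial variance of the mismatch proportion through the distance
#' transform:
#' `beta * ((1-beta) e^{2d/beta} + (2 beta - 1) e^{d/beta} - beta) / n`.
#' For r-state symmetric models it equals the inverse Fisher information.
#'
#' @param r alphabet size.
#' @param d distance(s) `>= 0`; vectorised.
#' @param n alignment length.
#' @return Variance(s); 0 at `d = 0`, strictly increasing in `d`.
#' @export
nr_delta_variance <- function(r, d, n) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(d < 0)) stop("d must be >= 0")
  beta <- (r - 1) / r
  beta * ((1 - beta) * exp(2 * d / beta) +
            (2 * beta - 1) * exp(d / beta) - beta) / n
}

#' Maximum-likelihood pairwise distance estimate
#'
#' Maximises the pairwise log-likelihood over `d >= 0`.  For r-state
#' symmetric models the closed form [nr_distance()] is used; otherwise a
#' safeguarded Newton-Raphson iteration on the score function (with a
#' bisection fallback on a bracketing interval) is run from a p-distance
#' start, converging when the step or the score falls below 1e-9.
#' Estimates that run into `ceiling` are returned at the ceiling with
#' `saturated = TRUE`; the variance is evaluated at the ceiling point.
#'
#' @param model a [substitution_model].
#' @param counts a [site_pair_counts()] object.
#' @param ceiling saturation ceiling in substitutions/site (default 10).
#' @param method `"auto"` (closed form where available, Newton otherwise),
#'   or force `"closed-form"` / `"newton"`.
#' @return An object of class `distance_estimate`: list with `d_hat`,
#'   `variance`, `n`, `saturated`, `method` (`"closed-form"` or
#'   `"newton"`) and `degenerate`.
#' @export
estimate_distance_ml <- function(model, counts, ceiling = 10,
                                 method = c("auto", "closed-form",
                                            "newton")) {
  stopifnot(inherits(model, "substitution_model"),
            inherits(counts, "site_pair_counts"))
  method <- match.arg(method)
  if (ceiling <= 0) stop("configuration error: ceiling must be > 0")
  n <- counts$n
  if (method == "closed-form" && is.na(model$beta))
    stop("no closed form exists for this model")
  if (method != "newton" && !is.na(model$beta)) {
    d <- nr_distance(model$r, counts$I, n)
    sat <- !is.finite(d) || d >= ceiling
    d <- if (sat) ceiling else d
    return(distance_estimate(d, model, n, sat, "closed-form"))
  }
  # Newton-Raphson on the score, started from the p-distance mapped
  # through the symmetric-model transform
  pdist <- counts$I / n
  beta <- (model$r - 1) / model$r
  d0 <- if (pdist / beta >= 1) ceiling else -beta * log(1 - pdist / beta)
  d <- min(max(d0, 1e-6), ceiling)
  if (counts$I == 0) return(distance_estimate(0, model, n, FALSE, "newton"))
  sc <- function(d) score_and_curvature(model, counts, d)
  s_ceil <- sc(ceiling)
  if (s_ceil$score >= 0)  # still increasing at the ceiling
    return(distance_estimate(ceiling, model, n, TRUE, "newton"))
  lo <- 1e-9; hi <- ceiling
  for (it in seq_len(200L)) {
    s <- sc(d)
    if (abs(s$score) < 1e-9) break
    if (s$score > 0) lo <- max(lo, d) else hi <- min(hi, d)
    step <- if (s$curv < 0) s$score / s$curv else NA_real_
    d_new <- d - step
    if (!is.finite(d_new) || d_new <= lo || d_new >= hi)
      d_new <- (lo + hi) / 2
    if (abs(d_new - d) < 1e-9) { d <- d_new; break }
    d <- d_new
  }
  distance_estimate(d, model, n, FALSE, "newton")
}

# First and second derivative of the log-likelihood in d
score_and_curvature <- function(model, counts, d) {
  P0 <- model_qk_expm(model, d, 0L)  # pi cancels in the log-derivatives
  P1 <- model_qk_expm(model, d, 1L)
  P2 <- model_qk_expm(model, d, 2L)
  used <- counts$F > 0
  w <- counts$F[used]
  g1 <- P1[used] / P0[used]
  list(score = sum(w * g1),
       curv = sum(w * (P2[used] / P0[used] - g1^2)))
}

distance_estimate <- function(d_hat, model, n, saturated, method) {
  v <- if (d_hat > 0) ml_variance(model, d_hat, n) else 0
  structure(list(d_hat = d_hat, variance = as.numeric(v), n = n,
                 saturated = saturated, method = method,
                 degenerate = isTRUE(attr(v, "degenerate")) || d_hat <= 0),
            class = "distance_estimate")
}

#' @export
print.distance_estimate <- function(x, ...) {
  cat(sprintf("ML distance: %.6g (variance %.6g, n = %d%s, %s)\n",
              x$d_hat, x$variance, x$n,
              if (x$saturated) ", saturated" else "", x$method))
  invisible(x)
}
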