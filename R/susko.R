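#' Quartet alignment columns
#'
#' Gap-free MSA columns for four taxa `(i, j, k, l)`, the input to the
#' sample-average covariance estimator.  Columns containing a character
#' outside the model alphabet in any of the four rows are dropped
#' (the expectation underlying the estimator is over complete quartets).
#'
#' @param columns n x 4 character matrix (rows = alignment columns).
#' @param model a [substitution_model] supplying the alphabet.
#' @return An object of class `quartet_columns`: list with `columns`
#'   (n x 4 integer matrix of state indices), `n`, `alphabet`,
#'   `n_dropped`.
#' @export
quartet_columns <- function(columns, model) {
  stopifnot(inherits(model, "substitution_model"))
  columns <- as.matrix(columns)
  if (ncol(columns) != 4L) stop("columns must have exactly 4 taxa")
  idx <- matrix(match(columns, model$alphabet), nrow(columns), 4L)
  keep <- rowSums(is.na(idx)) == 0L
  if (!any(keep)) stop("no quartet-complete columns in the model alphabet")
  structure(list(columns = idx[keep, , drop = FALSE], n = sum(keep),
                 alphabet = model$alphabet, n_dropped = sum(!keep)),
            class = "quartet_columns")
}

#' Score of an aligned character pair
#'
#' The derivative of the log pair probability with respect to the
#' distance, evaluated for the ordered pair `(u, v)` at distance `d`:
#' `[Q exp(Q d)]_{uv} / [exp(Q d)]_{uv}` (the equilibrium frequency
#' cancels).  Averaged over the pair distribution at the true distance the
#' score has mean zero.
#'
#' @param model a [substitution_model].
#' @param u,v characters from the model alphabet (vectorised, recycled).
#' @param d distance `> 0`.
#' @return Score value(s); infinite where the pair probability vanishes.
#' @export
pair_score <- function(model, u, v, d) {
  stopifnot(inherits(model, "substitution_model"))
  if (d <= 0) stop("d must be > 0")
  S <- score_lookup(model, d)
  iu <- match(u, model$alphabet); iv <- match(v, model$alphabet)
  if (anyNA(iu) || anyNA(iv)) stop("character outside the model alphabet")
  S[cbind(iu, iv)]
}

# r x r matrix of scores [Q e^{Qd}] / [e^{Qd}]
score_lookup <- function(model, d) {
  P0 <- model_qk_expm(model, d, 0L)
  P1 <- model_qk_expm(model, d, 1L)
  out <- P1 / P0
  out[P0 <= 0] <- ifelse(P1[P0 <= 0] >= 0, Inf, -Inf)
  out
}

#' Sample-average (Susko) covariance of two pairwise distances
#'
#' Linear-time covariance estimator for two distance estimates derived
#' from the same MSA columns:
#' `n * v_ij * v_kl * mean over columns of score_ij * score_kl`, where
#' `score_ij` is the log pair-probability derivative ([pair_score()]) for
#' the pair `(i, j)` evaluated at the plug-in estimate `d_ij_hat`, and
#' likewise for `(k, l)`.  The sample average is unbiased and may be
#' negative.  Columns with no character variation across all four taxa
#' at every site (degenerate input) are flagged.
#'
#' @param model a [substitution_model].
#' @param cols a [quartet_columns()] object with taxa in order
#'   `(i, j, k, l)`.
#' @param d_ij_hat,d_kl_hat the two estimated distances (`> 0`).
#' @param v_ij,v_kl their variance estimates.
#' @return The covariance estimate (numeric); attribute
#'   `degenerate = TRUE` when the columns carry no score variation.
#' @export
susko_covariance <- function(model, cols, d_ij_hat, d_kl_hat, v_ij, v_kl) {
  stopifnot(inherits(model, "substitution_model"),
            inherits(cols, "quartet_columns"))
  if (!identical(cols$alphabet, model$alphabet))
    stop("input error: alphabet mismatch between columns and model")
  if (d_ij_hat <= 0 || d_kl_hat <= 0)
    stop("d must be > 0 for score evaluation")
  X <- cols$columns
  s_ij <- score_lookup(model, d_ij_hat)[X[, c(1L, 2L), drop = FALSE]]
  s_kl <- score_lookup(model, d_kl_hat)[X[, c(3L, 4L), drop = FALSE]]
  out <- cols$n * v_ij * v_kl * mean(s_ij * s_kl)
  if (all(X == X[, 1L])) attr(out, "degenerate") <- TRUE
  out
}
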