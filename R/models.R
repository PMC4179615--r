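#' Substitution models
#'
#' A `substitution_model` bundles an instantaneous rate matrix `Q`, the
#' equilibrium (root) frequencies `pi` and an ordered alphabet.  All models
#' are calibrated so that one unit of evolutionary distance corresponds to
#' one expected substitution per site, i.e. `-sum(pi * diag(Q)) == 1`.
#'
#' @param Q numeric r x r rate matrix; rows must sum to zero and
#'   off-diagonal entries must be non-negative.
#' @param pi numeric length-r equilibrium frequency vector (positive,
#'   summing to one and stationary under `Q`).
#' @param alphabet character vector of state labels, in order.
#' @param name free-text model label.
#' @param calibrate if `TRUE` (default) rescale `Q` to one expected
#'   substitution per unit distance.
#'
#' @return An object of class `substitution_model`: a list with elements
#'   `r`, `alphabet`, `Q`, `pi`, `name`, `beta` (`(r-1)/r` for r-state
#'   symmetric models, `NA` otherwise) and a cached spectral decomposition
#'   used to evaluate matrix exponentials.
#' @seealso [make_nr_model()], [read_paml_model()], [transition_probability()]
#' @export
substitution_model <- function(Q, pi, alphabet = NULL, name = "custom",
                               calibrate = TRUE) {
  Q <- as.matrix(Q)
  r <- nrow(Q)
  if (r < 2L || ncol(Q) != r)
    stop("invalid alphabet: Q must be square with at least 2 states")
  if (is.null(alphabet)) alphabet <- default_alphabet(r)
  if (length(alphabet) != r)
    stop("alphabet length does not match the dimension of Q")
  pi <- as.numeric(pi)
  if (length(pi) != r || any(pi <= 0))
    stop("pi must be a positive vector of length ", r)
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  pi <- pi / sum(pi)
  if (max(abs(rowSums(Q))) > 1e-8 * max(abs(Q)))
    stop("rows of Q must sum to 0")
  offd <- Q; diag(offd) <- 0
  if (any(offd < -1e-12)) stop("off-diagonal entries of Q must be >= 0")
  if (max(abs(as.numeric(pi %*% Q))) > 1e-6 * max(abs(Q)))
    stop("pi is not stationary under Q")
  if (calibrate) {
    mu <- -sum(pi * diag(Q))
    if (mu <= 0) stop("Q has no substitution flux; cannot calibrate")
    Q <- Q / mu
  }
  dimnames(Q) <- list(alphabet, alphabet)
  m <- structure(
    list(r = r, alphabet = alphabet, Q = Q, pi = pi, name = name,
         beta = NA_real_, decomp = NULL),
    class = "substitution_model")
  m$beta <- detect_nr_beta(m)
  m$decomp <- model_decomposition(m)
  m
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("Substitution model:", x$name, "\n")
  cat("  states:", x$r, "(", paste(x$alphabet, collapse = ""), ")\n")
  if (!is.na(x$beta))
    cat("  r-state symmetric, beta =", format(x$beta), "\n")
  cat("  calibration: -sum(pi * diag(Q)) =",
      format(-sum(x$pi * diag(x$Q))), "\n")
  invisible(x)
}

default_alphabet <- function(r) {
  if (r == 4L) c("A", "C", "G", "T")
  else if (r == 20L) PAML_AA_ORDER
  else if (r <= 26L) LETTERS[seq_len(r)]
  else as.character(seq_len(r))
}

# PAML's canonical amino-acid ordering
PAML_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Is the model r-state symmetric (uniform pi, equal off-diagonal rates)?
# Returns beta = (r-1)/r if so, NA otherwise.
detect_nr_beta <- function(model, tol = 1e-12) {
  r <- model$r
  offd <- model$Q[row(model$Q) != col(model$Q)]
  if (max(abs(model$pi - 1 / r)) < tol &&
      diff(range(offd)) < tol * max(1, max(abs(offd))))
    (r - 1) / r
  else NA_real_
}

#' r-state symmetric (N_r) model
#'
#' The r-state generalisation of the Jukes-Cantor model: uniform root
#' frequencies and a single exchange rate between every pair of distinct
#' states.  After calibration to one expected substitution per unit
#' distance the probability of observing a mismatch at distance `d` is
#' `beta * (1 - exp(-d / beta))` with `beta = (r - 1) / r`.
#'
#' @param r alphabet size, an integer >= 2 (`r = 4` is Jukes-Cantor).
#' @return A [substitution_model] with `beta = (r - 1) / r`.
#' @examples
#' m <- make_nr_model(4)
#' m$beta  # 3/4
#' @export
make_nr_model <- function(r) {
  r <- as.integer(r)
  if (is.na(r) || r < 2L) stop("invalid alphabet: r must be an integer >= 2")
  Q <- matrix(1 / (r - 1), r, r)
  diag(Q) <- -1
  substitution_model(Q, rep(1 / r, r), default_alphabet(r),
                     name = sprintf("N%d (%d-state symmetric)", r, r))
}

# --- matrix exponential ----------------------------------------------------

# Spectral decomposition of Q.  For reversible models the symmetrised
# matrix diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric and an orthogonal
# eigendecomposition gives a numerically stable exponential; otherwise a
# general eigendecomposition is attempted, and scaling-and-squaring is the
# last resort (decomp = NULL).
model_decomposition <- function(model) {
  Q <- model$Q; pi <- model$pi; r <- model$r
  flux <- pi * Q
  if (max(abs(flux - t(flux))) < 1e-10 * max(abs(flux))) {
    s <- sqrt(pi)
    B <- (Q * s) / rep(s, each = r)  # diag(s) Q diag(1/s), column-recycled
    B <- (B + t(B)) / 2
    e <- eigen(B, symmetric = TRUE)
    U <- e$vectors / s               # diag(1/s) V
    Uinv <- t(e$vectors * s)         # t(V) diag(s)
    return(list(type = "reversible", lambda = e$values, U = U, Uinv = Uinv))
  }
  e <- tryCatch(eigen(Q), error = function(err) NULL)
  if (!is.null(e) && abs(det(e$vectors)) > 1e-8) {
    return(list(type = "general", lambda = e$values, U = e$vectors,
                Uinv = solve(e$vectors)))
  }
  NULL
}

# e^{Qd} (k = 0) or Q^k e^{Qd} (k = 1, 2) through the cached decomposition
model_qk_expm <- function(model, d, k = 0L) {
  if (d == 0) {
    # exact limit: spectral reconstruction leaves O(eps) residue that
    # would turn impossible pairs into tiny positive probabilities
    P <- switch(k + 1L, diag(model$r), model$Q, model$Q %*% model$Q)
    dimnames(P) <- list(model$alphabet, model$alphabet)
    return(P)
  }
  dec <- model$decomp
  if (is.null(dec)) {
    P <- expm_ss(model$Q * d)
  } else {
    P <- dec$U %*% (exp(dec$lambda * d) * dec$Uinv)
    if (is.complex(P)) P <- Re(P)
  }
  if (k > 0L) {
    Qk <- model$Q
    if (k == 2L) Qk <- Qk %*% model$Q
    P <- Qk %*% P
  }
  dimnames(P) <- list(model$alphabet, model$alphabet)
  P
}

# Scaling-and-squaring matrix exponential (Pade order 6); fallback for
# models without a usable eigendecomposition.
expm_ss <- function(A) {
  n <- nrow(A)
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps) / 0.5)))
  As <- A / 2^s
  c <- c(1, 1 / 2, 5 / 44, 1 / 66, 1 / 792, 1 / 15840, 1 / 665280)
  I <- diag(n)
  A2 <- As %*% As
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  U <- As %*% (c[2] * I + c[4] * A2 + c[6] * A4)
  V <- c[1] * I + c[3] * A2 + c[5] * A4 + c[7] * A6
  P <- solve(V - U, V + U)
  for (i in seq_len(s)) P <- P %*% P
  P
}

# --- pair probabilities ----------------------------------------------------

#' Joint pair probabilities and their distance derivatives
#'
#' Entry `(u, v)` of the returned matrix is `pi_u [Q^k exp(Q d)]_{uv}`:
#' for `k = 0` the joint probability of observing the ordered character
#' pair `(u, v)` in two sequences separated by distance `d`; for
#' `k = 1, 2` its first and second derivative with respect to `d`.
#'
#' @param model a [substitution_model].
#' @param d evolutionary distance, `>= 0` (expected substitutions/site).
#' @param k derivative order, one of 0, 1, 2.
#' @return An r x r numeric matrix with the model alphabet as dimnames.
#'   For `k = 0` the entries are non-negative and sum to one.
#' @export
transition_probability <- function(model, d, k = 0L) {
  stopifnot(inherits(model, "substitution_model"))
  if (length(d) != 1L || is.na(d) || d < 0) stop("d must be a single value >= 0")
  if (!(k %in% 0:2)) stop("unsupported derivative order: k must be 0, 1 or 2")
  model$pi * model_qk_expm(model, d, as.integer(k))
}

#' Mismatch probability of the r-state symmetric model
#'
#' Probability that two homologous characters differ after evolving apart
#' by distance `d` under the r-state symmetric model:
#' `beta * (1 - exp(-d / beta))`, `beta = (r - 1) / r`.  Increases from 0
#' at `d = 0` towards the saturation level `beta`.
#'
#' @param r alphabet size (>= 2).
#' @param d distance(s), `>= 0`; vectorised.
#' @return Mismatch probabilities in `[0, beta)`.
#' @export
nr_mutation_probability <- function(r, d) {
  if (r < 2) stop("invalid alphabet: r must be >= 2")
  if (any(d < 0)) stop("d must be >= 0")
  beta <- (r - 1) / r
  beta * (1 - exp(-d / beta))
}

# --- PAML-format model files ----------------------------------------------

#' Read a substitution model from a PAML-format rate file
#'
#' The file dialect is the one used for empirical amino-acid models: the
#' strictly lower triangle of the symmetric exchangeability matrix given
#' row by row (rows 2..r, whitespace separated, line breaks free), followed
#' by the r equilibrium frequencies.  Anything after these
#' `r(r-1)/2 + r` numbers is ignored, and `#`-comments are stripped.
#' The rate matrix is assembled as `Q = S %*% diag(pi)` with the diagonal
#' set so rows sum to zero, then calibrated to one expected substitution
#' per unit distance.
#'
#' @param path file path.
#' @param r alphabet size the file encodes (default 20, amino acids in
#'   PAML's canonical ARNDCQEGHILKMFPSTWYV order).
#' @param name model label; defaults to the file name.
#' @return A [substitution_model].
#' @seealso [write_paml_model()]
#' @export
read_paml_model <- function(path, r = 20L, name = NULL) {
  if (!file.exists(path)) stop("cannot read PAML model file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- unlist(strsplit(paste(lines, collapse = " "), "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  ntri <- r * (r - 1L) / 2L
  need <- ntri + r
  vals <- vals[!is.na(vals)]
  if (length(vals) < need)
    stop("PAML format error: expected ", need, " numbers (", ntri,
         " exchangeabilities + ", r, " frequencies), found ", length(vals))
  tri <- vals[seq_len(ntri)]
  pi <- vals[ntri + seq_len(r)]
  if (abs(sum(pi) - 1) > 1e-4)
    stop("PAML format error: frequencies sum to ", format(sum(pi)),
         ", expected 1")
  pi <- pi / sum(pi)
  S <- matrix(0, r, r)
  S[upper.tri(S)] <- 0
  idx <- 1L
  for (i in 2L:r) {
    S[i, seq_len(i - 1L)] <- tri[idx:(idx + i - 2L)]
    idx <- idx + i - 1L
  }
  S <- S + t(S)
  if (any(S[row(S) != col(S)] < 0))
    stop("PAML format error: negative exchangeability")
  Q <- S * rep(pi, each = r)  # S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (is.null(name)) name <- basename(path)
  substitution_model(Q, pi, default_alphabet(r), name = name)
}

#' Write a substitution model as a PAML-format rate file
#'
#' Inverse of [read_paml_model()]: the exchangeabilities
#' `S_uv = Q_uv / pi_v` are written as a lower triangle followed by the
#' frequency line.  `read_paml_model(write_paml_model(m, f))` recovers
#' `Q` and `pi` up to calibration (which is re-applied on read).
#'
#' @param model a [substitution_model].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_paml_model <- function(model, path) {
  stopifnot(inherits(model, "substitution_model"))
  r <- model$r
  S <- model$Q / rep(model$pi, each = r)  # Q %*% diag(1/pi)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in 2L:r)
    writeLines(paste(formatC(S[i, seq_len(i - 1L)], format = "g",
                             digits = 17), collapse = " "), con)
  writeLines("", con)
  writeLines(paste(formatC(model$pi, format = "g", digits = 17),
                   collapse = " "), con)
  invisible(path)
}
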