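#' Quartet with branch lengths
#'
#' Ground-truth object for simulation: four leaves `(i, j, k, l)`, five
#' branch lengths (four terminal branches plus the middle branch
#' `delta_m`, all in expected substitutions per site) and the assignment
#' of leaves to the two sides of the middle edge.  With the default
#' `sides = c(1, 3)` the leaves `i` and `k` flank one side and `j`, `l`
#' the other, so the target pair of paths `i..j` and `k..l` both traverse
#' the middle branch (the dependence configuration) and
#' `d_ij = delta_i + delta_m + delta_j`.
#'
#' @param delta numeric length 5: terminal branch lengths for the four
#'   leaves followed by the middle branch length (names `i,j,k,l,m` are
#'   attached).
#' @param labels four leaf labels.
#' @param sides integer vector of the two leaf positions on the first
#'   side of the middle edge.
#' @return An object of class `quartet`.
#' @export
quartet <- function(delta, labels = c("i", "j", "k", "l"), sides = c(1L, 3L)) {
  delta <- as.numeric(delta)
  if (length(delta) != 5L) stop("delta must hold 5 branch lengths")
  if (any(delta < 0)) stop("branch lengths must be >= 0")
  if (length(labels) != 4L) stop("labels must name four leaves")
  sides <- sort(as.integer(sides))
  if (length(sides) != 2L || any(!sides %in% 1:4))
    stop("sides must pick two of the four leaf positions")
  names(delta) <- c("i", "j", "k", "l", "m")
  structure(list(labels = labels, delta = delta, sides = sides),
            class = "quartet")
}

#' @export
print.quartet <- function(x, ...) {
  s1 <- x$labels[x$sides]; s2 <- x$labels[-x$sides]
  cat(sprintf("Quartet ((%s),(%s)): delta = %s, delta_m = %g\n",
              paste(s1, collapse = ","), paste(s2, collapse = ","),
              paste(format(x$delta[1:4]), collapse = " "), x$delta["m"]))
  invisible(x)
}

#' True leaf-to-leaf path lengths of a quartet
#'
#' Additive distances: leaves on the same side of the middle edge are
#' separated by the sum of their terminal branches; leaves on opposite
#' sides additionally traverse the middle branch.
#'
#' @param q a [quartet()].
#' @return Named numeric of length 6 (role names `ij`, `ik`, ..., `kl`).
#' @export
quartet_true_distances <- function(q) {
  stopifnot(inherits(q, "quartet"))
  same <- function(a, b) (a %in% q$sides) == (b %in% q$sides)
  pairs <- list(ij = c(1, 2), ik = c(1, 3), il = c(1, 4),
                jk = c(2, 3), jl = c(2, 4), kl = c(3, 4))
  vapply(pairs, function(p) {
    d <- q$delta[p[1]] + q$delta[p[2]]
    if (!same(p[1], p[2])) d <- d + q$delta["m"]
    unname(d)
  }, numeric(1))
}

# True shared path length between the paths of two role pairs
quartet_shared_length <- function(q, case = c("dependence", "triplet",
                                              "independence")) {
  case <- match.arg(case)
  switch(case,
         dependence = unname(q$delta["m"]),
         triplet = unname(q$delta["j"] + q$delta["m"]),
         independence = 0)
}

#' Sample a random quartet
#'
#' Terminal branch lengths are drawn uniformly from `delta_terminal` and
#' the middle branch from `delta_middle`; all five are then multiplied by
#' a common expansion/contraction factor drawn uniformly from `scale`
#' (default U(0.5, 2)) to explore more extreme regions of branch-length
#' space while preserving the relative structure.
#'
#' @param delta_terminal range (min, max) for the four terminal branches;
#'   default `c(0.02, 0.8)`.
#' @param delta_middle range for the middle branch; default `c(0.01, 0.5)`.
#' @param scale range of the common dilation factor; default `c(0.5, 2)`.
#' @param labels leaf labels.
#' @param seed optional integer; when given, the draw is a pure function
#'   of the seed.
#' @return A [quartet()] in the dependence layout (`sides = c(1, 3)`).
#' @export
sample_quartet <- function(delta_terminal = c(0.02, 0.8),
                           delta_middle = c(0.01, 0.5),
                           scale = c(0.5, 2),
                           labels = c("i", "j", "k", "l"), seed = NULL) {
  check_range <- function(x, nm) {
    if (length(x) != 2L || any(x <= 0) || x[2] < x[1])
      stop("configuration error: ", nm, " must be a positive (min, max) range")
  }
  check_range(delta_terminal, "delta_terminal")
  check_range(delta_middle, "delta_middle")
  check_range(scale, "scale")
  if (!is.null(seed)) set.seed(seed)
  f <- stats::runif(1, scale[1], scale[2])
  quartet(f * c(stats::runif(4, delta_terminal[1], delta_terminal[2]),
                stats::runif(1, delta_middle[1], delta_middle[2])),
          labels = labels)
}

# Propagate a vector of state indices along a branch of length d
propagate_states <- function(model, states, d) {
  P <- model_qk_expm(model, d, 0L)
  out <- integer(length(states))
  for (u in seq_len(model$r)) {
    idx <- which(states == u)
    if (length(idx))
      out[idx] <- sample.int(model$r, length(idx), replace = TRUE,
                             prob = P[u, ])
  }
  out
}

#' Simulate sequence evolution along a quartet
#'
#' Draws root states from the equilibrium frequencies at one end of the
#' middle edge and propagates them independently along every branch with
#' the transition matrix `exp(Q * delta)`.  Sites are i.i.d.; the site
#' index is the true alignment.
#'
#' @param model a [substitution_model].
#' @param q a [quartet()].
#' @param length number of sites.
#' @param seed optional integer seed.
#' @return An `length x 4` character matrix of aligned gapless sequences,
#'   columns named by the quartet labels (order `i, j, k, l`).
#' @export
evolve_quartet <- function(model, q, length, seed = NULL) {
  stopifnot(inherits(model, "substitution_model"), inherits(q, "quartet"))
  if (length < 1) stop("length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  left <- sample.int(model$r, length, replace = TRUE, prob = model$pi)
  right <- propagate_states(model, left, q$delta["m"])
  out <- matrix(0L, length, 4L)
  for (pos in 1:4) {
    anc <- if (pos %in% q$sides) left else right
    out[, pos] <- propagate_states(model, anc, q$delta[pos])
  }
  matrix(model$alphabet[out], length, 4L,
         dimnames = list(NULL, q$labels))
}

#' Exact joint leaf-pattern probabilities of a quartet
#'
#' Enumerates the probability of every `r^4` pattern of leaf states by
#' summing over the states of the two internal nodes: the middle-edge
#' joint distribution times the four terminal-branch conditionals.  This
#' is the brute-force oracle used to validate both the simulator and the
#' closed-form covariance expressions.
#'
#' @param model a [substitution_model].
#' @param q a [quartet()].
#' @return A 4-dimensional array (dimensions = leaves `i, j, k, l`, each
#'   indexed by the model alphabet) summing to one.
#' @export
joint_pattern_probability <- function(model, q) {
  stopifnot(inherits(model, "substitution_model"), inherits(q, "quartet"))
  r <- model$r
  Tm <- model$pi * model_qk_expm(model, q$delta["m"], 0L)  # joint internal
  Pb <- lapply(1:4, function(pos) model_qk_expm(model, q$delta[pos], 0L))
  ls <- q$sides; rs <- setdiff(1:4, q$sides)
  # L2[u, (x2-1)*r + x1] = P_ls1[u, x1] * P_ls2[u, x2]
  pair_block <- function(Pa, Pb2) {
    M <- matrix(0, r, r * r)
    for (x2 in seq_len(r))
      M[, (x2 - 1L) * r + seq_len(r)] <- Pa * Pb2[, x2]
    M
  }
  L2 <- pair_block(Pb[[ls[1]]], Pb[[ls[2]]])
  R2 <- pair_block(Pb[[rs[1]]], Pb[[rs[2]]])
  out <- t(L2) %*% Tm %*% R2          # ((x_ls1, x_ls2), (x_rs1, x_rs2))
  arr <- array(out, rep(r, 4L))       # dims: ls1, ls2, rs1, rs2
  perm <- order(c(ls, rs))            # back to leaf order i, j, k, l
  arr <- aperm(arr, perm)
  dimnames(arr) <- rep(list(model$alphabet), 4L)
  arr
}

#' Indel model with Zipfian gap lengths
#'
#' Per-site, per-sequence gap initiation with probability `gap_rate`; the
#' gap length is drawn from a Zipf (power-law) distribution with exponent
#' `zipf_exponent`, truncated at `max_gap`.
#'
#' @param gap_rate gap-initiation probability per site, in `[0, 1)`.
#' @param zipf_exponent power-law exponent (`> 1`).
#' @param max_gap truncation length (`>= 1`).
#' @return An object of class `indel_model`.
#' @export
indel_model <- function(gap_rate = 0.01, zipf_exponent = 1.821,
                        max_gap = 50L) {
  if (gap_rate < 0 || gap_rate >= 1) stop("gap_rate must be in [0, 1)")
  if (zipf_exponent <= 1) stop("zipf_exponent must be > 1")
  if (max_gap < 1) stop("max_gap must be >= 1")
  structure(list(gap_rate = gap_rate, zipf_exponent = zipf_exponent,
                 max_gap = as.integer(max_gap)),
            class = "indel_model")
}

#' Truncated Zipf gap lengths
#'
#' Samples from the probability mass function proportional to
#' `k^(-s)` on `1..max_gap`.
#'
#' @param n number of draws.
#' @param s exponent (`> 1`).
#' @param max_gap truncation.
#' @return Integer vector of gap lengths.
#' @export
rzipf <- function(n, s, max_gap) {
  k <- seq_len(max_gap)
  sample(k, n, replace = TRUE, prob = k^(-s))
}

#' Introduce gaps of Zipfian length into a true alignment
#'
#' For each sequence independently, every site initiates a deletion with
#' probability `gap_rate`; the deleted stretch (Zipf-distributed length,
#' truncated at `max_gap` and at the sequence end) is replaced by `-`.
#' The returned matrix keeps the original columns, i.e. it is the gapped
#' true alignment; [ungap_sequences()] strips the gaps to obtain the
#' unaligned sequences for re-alignment.
#'
#' @param sequences n x m character matrix (columns = sequences), e.g.
#'   from [evolve_quartet()].
#' @param im an [indel_model()].
#' @param seed optional integer seed.
#' @return Character matrix of the same shape with `-` for deleted sites.
#' @export
apply_indels <- function(sequences, im, seed = NULL) {
  stopifnot(inherits(im, "indel_model"))
  sequences <- as.matrix(sequences)
  if (!is.null(seed)) set.seed(seed)
  if (im$gap_rate == 0) return(sequences)
  n <- nrow(sequences)
  for (s in seq_len(ncol(sequences))) {
    starts <- which(stats::runif(n) < im$gap_rate)
    if (!length(starts)) next
    lens <- rzipf(length(starts), im$zipf_exponent, im$max_gap)
    for (g in seq_along(starts)) {
      span <- starts[g]:min(starts[g] + lens[g] - 1L, n)
      sequences[span, s] <- "-"
    }
  }
  sequences
}

#' @rdname apply_indels
#' @export
ungap_sequences <- function(sequences) {
  sequences <- as.matrix(sequences)
  lapply(stats::setNames(seq_len(ncol(sequences)), colnames(sequences)),
         function(s) sequences[sequences[, s] != "-", s])
}

#' Log-odds scoring matrix from a substitution model
#'
#' Scores in half-bit units: `2 * log2` of the ratio of the joint pair
#' probability at the reference distance to the product of the
#' equilibrium frequencies.
#'
#' @param model a [substitution_model].
#' @param d_ref reference distance at which the log-odds are taken
#'   (default 1 substitution/site).
#' @return An r x r numeric scoring matrix with alphabet dimnames.
#' @export
model_score_matrix <- function(model, d_ref = 1.0) {
  P <- transition_probability(model, d_ref, 0L)
  2 * log2(P / outer(model$pi, model$pi))
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, as
#' implemented by [Biostrings::pairwiseAlignment()]; a gap of length `L`
#' costs `gap_open + L * gap_extend`.  The traceback is deterministic.
#'
#' @param seq_a,seq_b ungapped sequences (strings or character vectors).
#' @param scoring substitution scoring matrix (e.g.
#'   [model_score_matrix()]); required.
#' @param gap_open,gap_extend affine gap penalties (positive costs;
#'   defaults 10 and 1, in the same units as `scoring`).
#' @return List with `a`, `b` (aligned character vectors including `-`)
#'   and `score`.
#' @export
align_pair <- function(seq_a, seq_b, scoring, gap_open = 10, gap_extend = 1) {
  a <- paste(split_chars(seq_a), collapse = "")
  b <- paste(split_chars(seq_b), collapse = "")
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    substitutionMatrix = scoring, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  list(a = strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]],
       b = strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]],
       score = as.numeric(Biostrings::score(aln)))
}

# --- Newick I/O ------------------------------------------------------------

#' Read and write quartets with branch lengths in Newick format
#'
#' `read_quartet_newick()` accepts any Newick tree with exactly four tips
#' (rooted or unrooted); after unrooting, the single internal edge gives
#' the middle branch length and the side assignment.
#' `write_quartet_newick()` emits the unrooted form
#' `((L1:d,L2:d):dm,R1:d,R2:d);`.
#'
#' @param path file path; for `read_quartet_newick` a Newick string is
#'   also accepted via `text`.
#' @param text optional Newick string instead of a file.
#' @param q a [quartet()].
#' @return A [quartet()] (reader) or `path` invisibly (writer).
#' @export
read_quartet_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr) || length(tr$tip.label) != 4L)
    stop("expected a Newick tree with exactly 4 tips")
  tr <- ape::unroot(tr)
  ntip <- 4L
  internal <- which(tr$edge[, 2L] > ntip)
  if (length(internal) != 1L)
    stop("tree does not reduce to a single internal edge")
  dm <- tr$edge.length[internal]
  inner_node <- tr$edge[internal, 2L]
  side1 <- tr$edge[tr$edge[, 1L] == inner_node & tr$edge[, 2L] <= ntip, 2L]
  side2 <- setdiff(seq_len(ntip), side1)
  tip_len <- numeric(ntip)
  term <- tr$edge[, 2L] <= ntip
  tip_len[tr$edge[term, 2L]] <- tr$edge.length[term]
  ord <- c(side1[1L], side2[1L], side1[2L], side2[2L])  # i, j, k, l
  quartet(c(tip_len[ord], dm), labels = tr$tip.label[ord], sides = c(1L, 3L))
}

#' @rdname read_quartet_newick
#' @export
write_quartet_newick <- function(q, path) {
  stopifnot(inherits(q, "quartet"))
  s1 <- q$sides; s2 <- setdiff(1:4, q$sides)
  txt <- sprintf("((%s:%.10g,%s:%.10g):%.10g,%s:%.10g,%s:%.10g);",
                 q$labels[s1[1]], q$delta[s1[1]],
                 q$labels[s1[2]], q$delta[s1[2]], q$delta["m"],
                 q$labels[s2[1]], q$delta[s2[1]],
                 q$labels[s2[2]], q$delta[s2[2]])
  writeLines(txt, path)
  invisible(path)
}
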