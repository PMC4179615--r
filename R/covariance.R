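#' Quartet distance bundle
#'
#' The six pairwise ML distance estimates among four taxa `(i, j, k, l)`,
#' their variances and supporting column counts.  This is the input to
#' topology selection and shared-path estimation; the covariance target
#' pair is always `(d_ij, d_kl)` in this labelling.
#'
#' @param labels character vector of four taxon identifiers `(i, j, k, l)`.
#' @param d named numeric of length 6 with names
#'   `c("ij","ik","il","jk","jl","kl")` (role names, not taxon names);
#'   unnamed vectors are taken in that order.
#' @param v the six variances, same naming.
#' @param n_pair the six supporting column counts, same naming; a single
#'   number is recycled.
#' @return An object of class `quartet_distances`.
#' @export
quartet_distances <- function(labels, d, v, n_pair) {
  if (length(labels) != 4L) stop("labels must name four taxa")
  d <- canon_pairs(d, "d"); v <- canon_pairs(v, "v")
  if (length(n_pair) == 1L) n_pair <- rep(n_pair, 6L)
  n_pair <- canon_pairs(n_pair, "n_pair")
  if (any(d < 0)) stop("distances must be >= 0")
  if (any(v < 0)) stop("variances must be >= 0")
  structure(list(labels = labels, d = d, v = v, n_pair = n_pair),
            class = "quartet_distances")
}

PAIR_ROLES <- c("ij", "ik", "il", "jk", "jl", "kl")

canon_pairs <- function(x, what) {
  x <- unlist(x)
  if (length(x) != 6L) stop(what, " must have 6 entries, one per taxon pair")
  if (!is.null(names(x)) && all(nzchar(names(x)))) {
    if (!setequal(names(x), PAIR_ROLES))
      stop(what, " names must be ", paste(PAIR_ROLES, collapse = ", "))
    x <- x[PAIR_ROLES]
  } else names(x) <- PAIR_ROLES
  x
}

#' Quartet topology selection by weighted least squares
#'
#' Computes the weighted sum-of-squares statistic `S(T)` for the three
#' unrooted quartet topologies
#' `T1 = ((i,k),(j,l))`, `T2 = ((i,l),(j,k))`, `T3 = ((i,j),(k,l))` and
#' returns the minimiser.  Each statistic is the squared four-point
#' residual of the two cross-pair distance sums, weighted by the summed
#' variances of the four distances involved, so `S(T) = 0` characterises
#' an exact additive fit.  Ties that involve `T3` resolve to `T3`
#' (conservative: a zero covariance rather than a fabricated positive
#' one); a `T1`/`T2` tie resolves to `T1`.
#'
#' `T1` and `T2` are the dependence topologies for the target pair
#' `(d_ij, d_kl)`; `T3` is the independence topology.
#'
#' @param q a [quartet_distances()] object; all six variances must be `> 0`.
#' @return An object of class `topology_fit`: list with `topology`
#'   (`"T1"`, `"T2"` or `"T3"`), `scores` (named length-3) and `tied`.
#' @export
select_topology <- function(q) {
  stopifnot(inherits(q, "quartet_distances"))
  if (any(q$v <= 0)) stop("weight error: all variances must be > 0")
  s <- topology_scores(q$d["ij"], q$d["ik"], q$d["il"],
                       q$d["jk"], q$d["jl"], q$d["kl"],
                       q$v["ij"], q$v["ik"], q$v["il"],
                       q$v["jk"], q$v["jl"], q$v["kl"])
  scores <- c(T1 = unname(s$s1), T2 = unname(s$s2), T3 = unname(s$s3))
  tol <- 1e-12 * max(1, max(scores))
  cand <- which(scores <= min(scores) + tol)
  topology <- if (3L %in% cand) "T3" else names(scores)[cand[1L]]
  structure(list(topology = topology, scores = scores,
                 tied = length(cand) > 1L),
            class = "topology_fit")
}

# The three WLS statistics with squared four-point residuals (vectorised)
topology_scores <- function(dij, dik, dil, djk, djl, dkl,
                            vij, vik, vil, vjk, vjl, vkl) {
  list(s1 = (dij + dkl - dil - djk)^2 / (vij + vkl + vil + vjk),
       s2 = (dij + dkl - dik - djl)^2 / (vij + vkl + vik + vjl),
       s3 = (dik + djl - dil - djk)^2 / (vik + vjl + vil + vjk))
}

#' @export
print.topology_fit <- function(x, ...) {
  cat("Selected topology:", x$topology,
      if (x$tied) "(tied)" else "", "\n")
  print(x$scores)
  invisible(x)
}

#' Weighted least-squares estimate of the shared path length
#'
#' For a dependence topology (`T1` or `T2`) estimates the length of the
#' path segment shared by the leaf-to-leaf paths `i..j` and `k..l` (twice
#' the middle-branch length enters the estimating equation).  The
#' unconstrained WLS solution can be negative; both the raw value and its
#' clamp at zero are returned, and a negative raw value means the
#' covariance is estimated as zero.
#'
#' @param q a [quartet_distances()] object.
#' @param fit a `topology_fit` from [select_topology()]; must be `T1` or
#'   `T2` (under `T3` the distances are independent and no shared path
#'   exists).
#' @return List with `raw` (unconstrained WLS value) and `delta_m`
#'   (`max(raw, 0)`).
#' @export
estimate_shared_path <- function(q, fit) {
  stopifnot(inherits(q, "quartet_distances"), inherits(fit, "topology_fit"))
  if (fit$topology == "T3")
    stop("contract violation: no shared path exists under topology T3")
  raw <- shared_path_raw(fit$topology,
                         q$d["ij"], q$d["ik"], q$d["il"],
                         q$d["jk"], q$d["jl"], q$d["kl"],
                         q$v["ij"], q$v["ik"], q$v["il"],
                         q$v["jk"], q$v["jl"], q$v["kl"])
  list(raw = unname(raw), delta_m = max(unname(raw), 0))
}

# Unconstrained WLS shared-path estimate (vectorised over inputs).
# topology is "T1" or "T2" (scalar).
shared_path_raw <- function(topology, dij, dik, dil, djk, djl, dkl,
                            vij, vik, vil, vjk, vjl, vkl) {
  if (topology == "T1") {
    ((dij + dkl) * (vil + vjk) + (dil + djk) * (vij + vkl)) /
      (vij + vkl + vil + vjk) / 2 - (dik + djl) / 2
  } else {
    ((dij + dkl) * (vik + vjl) + (dik + djl) * (vij + vkl)) /
      (vij + vkl + vik + vjl) / 2 - (dil + djk) / 2
  }
}

#' Shared path length for two distances sharing a taxon
#'
#' When the two distance estimates share a taxon (`d_ij` and `d_jk`), the
#' quartet degenerates and the shared path length follows from the
#' three-point formula `(d_ij + d_jk - d_ik) / 2`, clamped at zero.
#'
#' @param d_ij,d_jk the two distances sharing taxon `j`.
#' @param d_ik the distance between the outer taxa.
#' @return The clamped shared path length (vectorised).
#' @export
triplet_shared_path <- function(d_ij, d_jk, d_ik) {
  if (any(c(d_ij, d_jk, d_ik) < 0)) stop("distances must be >= 0")
  pmax((d_ij + d_jk - d_ik) / 2, 0)
}

#' Covariance of two distances under the r-state symmetric model
#'
#' Closed-form covariance of two ML distance estimates whose underlying
#' paths share a segment of length `delta_m`: it equals the delta-method
#' variance [nr_delta_variance()] of an ML distance estimate at true
#' distance `delta_m`.
#'
#' @param r alphabet size.
#' @param delta_m shared path length(s) `>= 0`; vectorised.
#' @param n alignment length.
#' @return Covariance value(s); 0 at `delta_m = 0`.
#' @export
nr_covariance <- function(r, delta_m, n) {
  nr_delta_variance(r, delta_m, n)
}

#' Covariance of two distances under a general Markov model
#'
#' Evaluates the covariance of two ML distance estimates with shared path
#' length `delta_m` as the inverse Fisher information at `delta_m`:
#' `-(1/n) / E[d^2/dd^2 log p(X, d)]` at `d = delta_m`, with the
#' expectation assembled from the pair probabilities and their first two
#' derivatives.  Below `eps` the information diverges and the covariance
#' is 0 by contract.  When `table` is supplied the per-site information is
#' interpolated from the precomputed grid (linearly in log-log
#' coordinates) instead of being evaluated directly; values outside the
#' grid raise a range error.
#'
#' @param model a [substitution_model].
#' @param delta_m shared path length `>= 0`.
#' @param n alignment length.
#' @param table optional [build_info_table()] lookup table.
#' @param eps short-circuit threshold (default 1e-8).
#' @return The covariance value.
#' @export
general_covariance <- function(model, delta_m, n, table = NULL, eps = 1e-8) {
  if (delta_m < 0) stop("delta_m must be >= 0")
  if (delta_m < eps) return(0)
  info <- if (is.null(table)) info_per_site(model, delta_m)
          else info_table_lookup(table, delta_m)
  1 / (n * info)
}

#' Precomputed per-site information table
#'
#' Discretises the distance range and stores the per-site expected
#' negative second derivative of the log pair probability (the per-site
#' Fisher information) at each grid point.  [general_covariance()] can
#' then be evaluated by interpolation in constant time per query.
#'
#' @param model a [substitution_model].
#' @param delta_min,delta_max grid range, `0 < delta_min < delta_max`.
#' @param step grid step (default 0.001).
#' @return An object of class `info_table`: list with `model_id`, `grid`,
#'   `values`.
#' @export
build_info_table <- function(model, delta_min = 0.001, delta_max = 5.0,
                             step = 0.001) {
  stopifnot(inherits(model, "substitution_model"))
  if (!(delta_min > 0 && delta_min < delta_max))
    stop("configuration error: need 0 < delta_min < delta_max")
  if (step <= 0 || step > (delta_max - delta_min))
    stop("configuration error: step must be in (0, delta_max - delta_min]")
  grid <- seq(delta_min, delta_max, by = step)
  values <- vapply(grid, function(d) info_per_site(model, d), numeric(1))
  structure(list(model_id = model$name, grid = grid, values = values),
            class = "info_table")
}

# Interpolation is linear in log-log coordinates: the per-site
# information behaves like 1/delta near the origin, where linear
# interpolation on the raw scale loses several digits; log(info) is
# nearly linear in log(delta) over the whole grid.
info_table_lookup <- function(table, delta_m) {
  stopifnot(inherits(table, "info_table"))
  if (delta_m < table$grid[1L] || delta_m > table$grid[length(table$grid)])
    stop("range error: delta_m = ", format(delta_m),
         " outside the table grid [", format(table$grid[1L]), ", ",
         format(table$grid[length(table$grid)]), "]")
  exp(stats::approx(log(table$grid), log(table$values),
                    xout = log(delta_m), rule = 1)$y)
}

#' Write / read an information table as TSV
#'
#' Two-column tab-separated serialisation (`delta`, `neg_expected_info`)
#' with the model identifier in a `#` header line.
#'
#' @param table an [build_info_table()] object.
#' @param path file path.
#' @return `path` (writer) or an `info_table` (reader).
#' @export
write_info_table <- function(table, path) {
  stopifnot(inherits(table, "info_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# info_table model=", table$model_id), con)
  writeLines("delta\tneg_expected_info", con)
  writeLines(sprintf("%.17g\t%.17g", table$grid, table$values), con)
  invisible(path)
}

#' @rdname write_info_table
#' @export
read_info_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^#", lines)
  model_id <- sub("^# info_table model=", "", lines[hdr][1L])
  df <- utils::read.delim(text = lines[!hdr], header = TRUE)
  structure(list(model_id = model_id, grid = df$delta,
                 values = df$neg_expected_info),
            class = "info_table")
}

#' Branch-covariance of two pairwise distance estimates
#'
#' The full covariance pipeline for a quartet: select the topology by WLS
#' ([select_topology()]); if `T3` is selected the two distances are
#' topologically independent and the covariance is zero; otherwise
#' estimate the shared path length ([estimate_shared_path()]); a negative
#' raw estimate again yields zero; otherwise evaluate the covariance as
#' the inverse Fisher information at the estimated shared path length
#' ([general_covariance()]).  The target pair is `(d_ij, d_kl)` in the
#' quartet's role labelling.
#'
#' @param model a [substitution_model].
#' @param q a [quartet_distances()] object.
#' @param table optional [build_info_table()] lookup table.
#' @param n_effective how to combine the two supporting column counts when
#'   they differ: `"geomean"` (default, geometric mean rounded) or
#'   `"min"`.
#' @return An object of class `covariance_estimate`: list with `cov`,
#'   `delta_m_hat`, `topology` (the `topology_fit`), `n_effective` and
#'   `zero_reason` (`"none"`, `"independent-topology"` or
#'   `"negative-delta"`).
#' @export
branch_covariance <- function(model, q, table = NULL,
                              n_effective = c("geomean", "min")) {
  stopifnot(inherits(model, "substitution_model"),
            inherits(q, "quartet_distances"))
  n_effective <- match.arg(n_effective)
  fit <- select_topology(q)
  n_eff <- combine_n(q$n_pair["ij"], q$n_pair["kl"], n_effective)
  if (fit$topology == "T3")
    return(covariance_estimate(0, NA_real_, fit, n_eff,
                               "independent-topology"))
  sp <- estimate_shared_path(q, fit)
  if (sp$raw < 0)
    return(covariance_estimate(0, 0, fit, n_eff, "negative-delta"))
  cov <- general_covariance(model, sp$delta_m, n_eff, table = table)
  covariance_estimate(cov, sp$delta_m, fit, n_eff, "none")
}

combine_n <- function(n1, n2, how) {
  unname(if (how == "geomean") round(sqrt(n1 * n2)) else pmin(n1, n2))
}

covariance_estimate <- function(cov, delta_m_hat, fit, n_eff, zero_reason) {
  structure(list(cov = cov, delta_m_hat = unname(delta_m_hat),
                 topology = fit, n_effective = n_eff,
                 zero_reason = zero_reason),
            class = "covariance_estimate")
}

#' @export
print.covariance_estimate <- function(x, ...) {
  cat(sprintf("Branch-covariance: %.6g (topology %s, delta_m_hat %s, n_eff %d%s)\n",
              x$cov, x$topology$topology,
              if (is.na(x$delta_m_hat)) "-" else format(x$delta_m_hat),
              x$n_effective,
              if (x$zero_reason != "none") paste0(", zero: ", x$zero_reason)
              else ""))
  invisible(x)
}

#' Covariance records for every pair of pairwise distances
#'
#' Applies the covariance machinery to all pairs of taxon-pairs in a
#' distance table over `m` taxa.  Pairs of pairs sharing no taxon go
#' through the quartet pipeline ([branch_covariance()]); pairs sharing one
#' taxon through the three-point shared path ([triplet_shared_path()]);
#' identical pairs contribute their input variance (the diagonal).
#'
#' @param model a [substitution_model].
#' @param distances data frame with columns `taxon_a`, `taxon_b`, `d_hat`,
#'   `variance`, `n` covering all `m(m-1)/2` pairs.
#' @param table optional [build_info_table()] lookup table.
#' @param n_effective passed to [branch_covariance()].
#' @return List with `records` (data frame: `pair_a`, `pair_b`,
#'   `topology`, `delta_m_hat`, `cov`, `zero_reason`; includes the
#'   diagonal) and `matrix` (the symmetric covariance matrix of the
#'   distance estimates, rows/columns named `"a:b"`).
#' @export
covariance_matrix <- function(model, distances, table = NULL,
                              n_effective = "geomean") {
  need <- c("taxon_a", "taxon_b", "d_hat", "variance", "n")
  if (!all(need %in% names(distances)))
    stop("incomplete input: distances needs columns ",
         paste(need, collapse = ", "))
  taxa <- sort(unique(c(distances$taxon_a, distances$taxon_b)))
  m <- length(taxa)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = ":")
  lut <- distances
  rownames(lut) <- key(lut$taxon_a, lut$taxon_b)
  allpairs <- t(utils::combn(taxa, 2L))
  keys <- key(allpairs[, 1L], allpairs[, 2L])
  if (!all(keys %in% rownames(lut)))
    stop("incomplete input: missing pair(s) ",
         paste(setdiff(keys, rownames(lut)), collapse = ", "))
  get <- function(a, b) lut[key(a, b), ]
  np <- nrow(allpairs)
  C <- matrix(0, np, np, dimnames = list(keys, keys))
  rec <- vector("list", np * (np + 1L) / 2L)
  ri <- 0L
  for (p in seq_len(np)) {
    for (s in p:np) {
      A <- allpairs[p, ]; B <- allpairs[s, ]
      shared <- intersect(A, B)
      if (p == s) {
        cv <- get(A[1L], A[2L])$variance
        row <- list(topology = "diagonal", delta_m_hat = NA_real_,
                    cov = cv, zero_reason = "none")
      } else if (length(shared) == 1L) {
        j <- shared
        i <- setdiff(A, j); l <- setdiff(B, j)
        dm <- triplet_shared_path(get(i, j)$d_hat, get(j, l)$d_hat,
                                  get(i, l)$d_hat)
        n_eff <- combine_n(get(i, j)$n, get(j, l)$n, n_effective)
        cv <- general_covariance(model, dm, n_eff, table = table)
        row <- list(topology = "triplet", delta_m_hat = dm, cov = cv,
                    zero_reason = if (cv == 0) "negative-delta" else "none")
      } else {
        # roles: (i, j) = pair A, (k, l) = pair B
        i <- A[1L]; j <- A[2L]; k <- B[1L]; l <- B[2L]
        dd <- c(ij = get(i, j)$d_hat, ik = get(i, k)$d_hat,
                il = get(i, l)$d_hat, jk = get(j, k)$d_hat,
                jl = get(j, l)$d_hat, kl = get(k, l)$d_hat)
        vv <- c(ij = get(i, j)$variance, ik = get(i, k)$variance,
                il = get(i, l)$variance, jk = get(j, k)$variance,
                jl = get(j, l)$variance, kl = get(k, l)$variance)
        nn <- c(ij = get(i, j)$n, ik = get(i, k)$n, il = get(i, l)$n,
                jk = get(j, k)$n, jl = get(j, l)$n, kl = get(k, l)$n)
        est <- branch_covariance(model, quartet_distances(c(i, j, k, l),
                                                          dd, vv, nn),
                                 table = table, n_effective = n_effective)
        row <- list(topology = est$topology$topology,
                    delta_m_hat = est$delta_m_hat, cov = est$cov,
                    zero_reason = est$zero_reason)
      }
      C[p, s] <- C[s, p] <- row$cov
      ri <- ri + 1L
      rec[[ri]] <- data.frame(pair_a = keys[p], pair_b = keys[s],
                              topology = row$topology,
                              delta_m_hat = row$delta_m_hat,
                              cov = row$cov, zero_reason = row$zero_reason,
                              stringsAsFactors = FALSE)
    }
  }
  list(records = do.call(rbind, rec), matrix = C)
}
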