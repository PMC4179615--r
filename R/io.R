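#' Read an aligned FASTA file
#'
#' Reads a (pairwise or multiple) sequence alignment.  Sequences are
#' returned upper-cased; gaps and ambiguity characters are retained and
#' excluded later, at pair-counting time.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequence strings.
#' @export
read_alignment_fasta <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read FASTA file ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("I/O error reading ", path, ": ",
                         conditionMessage(e)))
  if (length(set) == 0L) stop("I/O error: ", path, " holds no sequences")
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequence strings, or a character
#'   matrix (columns = sequences) as produced by [evolve_quartet()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(seqs, path) {
  if (is.matrix(seqs)) {
    nm <- colnames(seqs)
    seqs <- apply(seqs, 2L, paste, collapse = "")
    names(seqs) <- nm
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' All-against-all pairwise ML distances of an alignment
#'
#' Estimates the ML distance, its variance and the supporting gap-free
#' column count for every pair of sequences in an alignment.
#'
#' @param model a [substitution_model].
#' @param seqs named character vector of aligned sequences (equal
#'   length), e.g. from [read_alignment_fasta()].
#' @param ceiling saturation ceiling (substitutions/site).
#' @param weights variance estimator reported alongside the distances
#'   (and hence feeding any downstream WLS): `"ml"` for the
#'   inverse-expected-information variance (default) or `"sample"` for
#'   the observed-information [sample_average_variance()].
#' @return Data frame with columns `taxon_a`, `taxon_b`, `d_hat`,
#'   `variance`, `n`, `saturated`.
#' @export
pairwise_distance_table <- function(model, seqs, ceiling = 10,
                                    weights = c("ml", "sample")) {
  stopifnot(inherits(model, "substitution_model"))
  weights <- match.arg(weights)
  if (length(seqs) < 2L) stop("need at least two sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  pairs <- utils::combn(names(seqs), 2L)
  rows <- apply(pairs, 2L, function(p) {
    cnt <- count_site_pairs(seqs[[p[1L]]], seqs[[p[2L]]], model)
    e <- estimate_distance_ml(model, cnt, ceiling = ceiling)
    v <- if (weights == "sample" && e$d_hat > 0)
      as.numeric(sample_average_variance(model, cnt, e$d_hat))
    else e$variance
    data.frame(taxon_a = p[1L], taxon_b = p[2L], d_hat = e$d_hat,
               variance = v, n = e$n, saturated = e$saturated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Shared TSV writer: `#`-prefixed provenance header, then a tab-separated
# table with '.' decimals and 10 significant digits.
write_tsv_report <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance table as TSV
#'
#' Tab-separated `(taxon_a, taxon_b, d_hat, variance, n, saturated)`
#' records with a `#` provenance header.
#'
#' @param df distance table from [pairwise_distance_table()].
#' @param path output path.
#' @param header extra header lines (each prefixed with `# `).
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(df, path, header = character()) {
  write_tsv_report(df, path, header)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a PHYLIP square distance matrix
#'
#' Standard PHYLIP format for downstream distance-based tree tools:
#' taxon count on the first line, then one row per taxon (name padded to
#' 10 characters, distances separated by spaces).
#'
#' @param df distance table from [pairwise_distance_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_distances <- function(df, path) {
  taxa <- sort(unique(c(df$taxon_a, df$taxon_b)))
  m <- length(taxa)
  D <- matrix(0, m, m, dimnames = list(taxa, taxa))
  for (row in seq_len(nrow(df)))
    D[df$taxon_a[row], df$taxon_b[row]] <-
      D[df$taxon_b[row], df$taxon_a[row]] <- df$d_hat[row]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", m), con)
  for (t in taxa)
    writeLines(paste0(formatC(t, width = -10),
                      paste(formatC(D[t, ], format = "f", digits = 6),
                            collapse = " ")), con)
  invisible(path)
}
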