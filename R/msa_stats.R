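# Alignment diversity statistics: pairwise identity, the effective sequence
# number (Neff), the minimum diverse-sequence estimate, coverage and per-site
# depth.

# Full N x N pairwise identity matrix over match columns. The identity
# denominator is the number of mutually non-gapped match columns, so terminal
# gaps do not dilute the estimate; 0 when two rows share no non-gap columns.
identity_matrix <- function(x) {
  C <- match_char_matrix(x)
  G <- C == "-"
  n <- nrow(C)
  S <- matrix(0, n, n, dimnames = list(x$id, x$id))
  for (m in seq_len(n)) {
    eq <- C == matrix(C[m, ], n, ncol(C), byrow = TRUE)
    both <- !G & matrix(!G[m, ], n, ncol(C), byrow = TRUE)
    denom <- rowSums(both)
    matches <- rowSums(eq & both)
    S[m, ] <- ifelse(denom > 0, matches / denom, 0)
  }
  S
}

#' Sequence identity between two MSA rows
#'
#' Fraction of identical residues over the match columns where both rows are
#' non-gap. Symmetric; 0 when the rows have no overlapping non-gap columns.
#' Lowercase insertions never contribute.
#'
#' @param x an [msa] object.
#' @param m,n row indices (1-based; row 1 is the query).
#' @return Identity in \[0, 1\].
#' @export
seq_identity <- function(x, m, n) {
  stopifnot(is_msa(x), m >= 1, m <= x$N, n >= 1, n <= x$N)
  C <- match_char_matrix(x)
  a <- C[m, ]; b <- C[n, ]
  both <- a != "-" & b != "-"
  if (!any(both)) return(0)
  sum(a[both] == b[both]) / sum(both)
}

#' Number of effective sequences (Neff) of an MSA
#'
#' Diversity-weighted, length-normalized sequence count:
#' \deqn{Neff = \frac{1}{\sqrt{L}} \sum_{n=1}^{N}
#'   \frac{1}{1 + \sum_{m \ne n} I[S_{m,n} \ge 0.8]}}
#' where \eqn{S_{m,n}} is the pairwise sequence identity and \eqn{I[]} the
#' Iverson bracket. All rows, including the query, participate. When every
#' pair has identity below the threshold, Neff equals \eqn{N/\sqrt{L}}; when
#' all rows are identical it equals \eqn{1/\sqrt{L}} regardless of N.
#'
#' @param x an [msa] object.
#' @param identity_threshold redundancy threshold applied as
#'   `identity >= threshold` (default 0.8).
#' @return Neff (dimensionless), in \eqn{(0, N/\sqrt{L}]}.
#' @export
neff <- function(x, identity_threshold = 0.8) {
  stopifnot(is_msa(x))
  S <- identity_matrix(x)
  redundant <- rowSums(S >= identity_threshold) - (diag(S) >= identity_threshold)
  sum(1 / (1 + redundant)) / sqrt(x$L)
}

#' Minimum number of diverse sequences for a target Neff
#'
#' Inverts the diverse-MSA limit of the Neff definition: an alignment of
#' pairwise-diverse sequences reaches `neff_cut` once it holds
#' \eqn{N_{min} = Neff_{cut} \times \sqrt{L}} sequences. For a 100-residue
#' protein the cutoffs \eqn{2^0} and \eqn{2^4} give 10 and 160 sequences.
#'
#' @param neff_cut Neff cutoff (>= 0).
#' @param L query length in residues (>= 1).
#' @return Estimated minimal number of diverse sequences.
#' @export
#' @examples
#' min_diverse_sequences(2^0, 100)
#' min_diverse_sequences(2^4, 100)
min_diverse_sequences <- function(neff_cut, L) {
  stopifnot(is.numeric(neff_cut), neff_cut >= 0, is.numeric(L), L >= 1)
  neff_cut * sqrt(L)
}

#' Alignment coverage of the query
#'
#' Mean, over the homologs (query excluded), of the fraction of query match
#' columns each homolog aligns (non-gap).
#'
#' @param x an [msa] object with at least one homolog.
#' @return Coverage in \[0, 1\].
#' @export
msa_coverage <- function(x) {
  stopifnot(is_msa(x))
  if (x$N < 2L) {
    undefined_error("coverage is undefined for an MSA without homologs")
  }
  C <- match_char_matrix(x)
  mean(rowMeans(C[-1, , drop = FALSE] != "-"))
}

#' Per-site alignment depth
#'
#' For each query match column, the number of homologs (query excluded) with
#' a non-gap residue at that column.
#'
#' @param x an [msa] object.
#' @return Integer vector of length `L` with entries in \[0, N-1\].
#' @export
per_site_depth <- function(x) {
  stopifnot(is_msa(x))
  if (x$N < 2L) return(integer(x$L))
  C <- match_char_matrix(x)
  as.integer(colSums(C[-1, , drop = FALSE] != "-"))
}

#' Summary statistics of an MSA
#'
#' @param x an [msa] object.
#' @param identity_threshold passed to [neff()].
#' @return An object of class `msa_stats`: `neff`, `coverage` (NA when there
#'   are no homologs), `n_sequences`, `L`, `per_site_depth`, `mean_identity`
#'   (mean off-diagonal pairwise identity; NA when N = 1).
#' @export
msa_stats <- function(x, identity_threshold = 0.8) {
  stopifnot(is_msa(x))
  S <- identity_matrix(x)
  redundant <- rowSums(S >= identity_threshold) -
    (diag(S) >= identity_threshold)
  nf <- sum(1 / (1 + redundant)) / sqrt(x$L)
  mean_id <- if (x$N >= 2L) mean(S[upper.tri(S)]) else NA_real_
  cov <- if (x$N >= 2L) msa_coverage(x) else NA_real_
  structure(
    list(neff = nf, coverage = cov, n_sequences = x$N, L = x$L,
         per_site_depth = per_site_depth(x), mean_identity = mean_id),
    class = "msa_stats")
}

#' @export
print.msa_stats <- function(x, ...) {
  cat(sprintf("MSA statistics: N = %d, L = %d\n", x$n_sequences, x$L))
  cat(sprintf("  Neff          = %.4f\n", x$neff))
  cat(sprintf("  coverage      = %s\n",
              if (is.na(x$coverage)) "NA" else sprintf("%.4f", x$coverage)))
  cat(sprintf("  mean identity = %s\n",
              if (is.na(x$mean_identity)) "NA"
              else sprintf("%.4f", x$mean_identity)))
  cat(sprintf("  median depth  = %s\n",
              format(stats::median(x$per_site_depth))))
  invisible(x)
}
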