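# Column-pair mutual information over a repeat-unit alignment.
#
# Physically interacting positions coevolve; in TPR units the strongest
# intra-unit covariation links positions 7 and 23, which face each other
# across the hairpin. MI is the simplest reproducible estimator of that
# signal and is computed here in nats with a small uniform pseudocount.

#' Mutual information between all column pairs of an alignment
#'
#' For columns i and j, MI(i,j) = sum over residue pairs of
#' p(a,b) * ln( p(a,b) / (p(a) p(b)) ), with the joint frequencies smoothed
#' by `pseudocount / 400` per cell (marginals, being row/column sums of the
#' smoothed joint, receive `pseudocount / 20`). Rows carrying a gap or
#' non-standard letter in either column are dropped for that pair (pairwise
#' deletion). The diagonal (column entropy under the same smoothing) is
#' reported but excluded from ranking by [top_nonlocal_pair()].
#'
#' @param msa Named character vector of aligned sequences (>= 2 rows, equal
#'   lengths).
#' @param pseudocount Total pseudocount mass per pair table (default 1).
#' @param apc Apply average-product correction to the off-diagonal values
#'   (default `FALSE`).
#' @return An object of class `tpr_mi`: list with `width`, `values`
#'   (symmetric width x width matrix, nats), `pseudocount`, `n_sequences`.
#' @export
mutual_information <- function(msa, pseudocount = 1, apc = FALSE) {
  if (length(msa) < 2L) {
    tpr_abort("mutual information needs at least two sequences",
              "tpr_insufficient_data_error")
  }
  m <- msa_to_matrix(msa)
  codes <- matrix(match(m, aa_alphabet()), nrow = nrow(m))  # NA for gaps/X
  w <- ncol(codes)
  values <- matrix(0, w, w)
  for (i in seq_len(w)) {
    for (j in i:w) {
      ok <- !is.na(codes[, i]) & !is.na(codes[, j])
      n <- sum(ok)
      if (n == 0L) { values[i, j] <- values[j, i] <- 0; next }
      joint <- matrix(pseudocount / 400, 20L, 20L)
      tab <- tabulate(codes[ok, i] + 20L * (codes[ok, j] - 1L), nbins = 400L)
      joint <- joint + matrix(tab, 20L, 20L)
      joint <- joint / sum(joint)
      pa <- rowSums(joint); pb <- colSums(joint)
      ratio <- joint / outer(pa, pb)
      mi <- sum(joint[joint > 0] * log(ratio[joint > 0]))
      values[i, j] <- values[j, i] <- max(mi, 0)
    }
  }
  if (apc) {
    off <- values
    diag(off) <- NA
    rm_ <- rowMeans(off, na.rm = TRUE)
    om <- mean(off, na.rm = TRUE)
    corr <- outer(rm_, rm_) / om
    keep_diag <- diag(values)
    values <- values - corr
    diag(values) <- keep_diag
  }
  structure(
    list(width = w, values = values, pseudocount = pseudocount,
         n_sequences = length(msa), apc = apc),
    class = "tpr_mi"
  )
}

#' @export
print.tpr_mi <- function(x, ...) {
  cat(sprintf("<tpr_mi> %d columns, %d sequences, pseudocount %.3g%s\n",
              x$width, x$n_sequences, x$pseudocount,
              if (x$apc) ", APC-corrected" else ""))
  invisible(x)
}

#' Highest-MI column pair at a minimum sequence separation
#'
#' Scans all pairs with `|i - j| >= min_separation` (operationalising
#' "non-local"; neighbouring positions covary trivially through secondary
#' structure) and returns the maximum. Ties resolve to the lexicographically
#' smallest pair.
#'
#' @param mi A `tpr_mi` object.
#' @param min_separation Minimum |i - j| (default 5).
#' @return List with elements `i`, `j` (i < j) and `value` (nats).
#' @export
top_nonlocal_pair <- function(mi, min_separation = 5L) {
  stopifnot(inherits(mi, "tpr_mi"))
  w <- mi$width
  if (w <= min_separation) {
    tpr_abort("alignment width must exceed min_separation", "tpr_value_error")
  }
  best <- list(i = NA_integer_, j = NA_integer_, value = -Inf)
  for (i in seq_len(w - min_separation)) {
    for (j in seq.int(i + min_separation, w)) {
      v <- mi$values[i, j]
      if (v > best$value) best <- list(i = i, j = j, value = v)
    }
  }
  best
}
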