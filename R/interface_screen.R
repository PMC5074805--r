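# Hydrophobicity screening of repeat-interface positions.
#
# In the TPR fold, unit positions 3, 7, 10, 21 and 28 are buried between
# stacked repeats. A candidate hairpin is compatible with repeat stacking
# when enough of these positions carry small/medium hydrophobic side chains
# (Ala, Ile, Leu, Met, Phe, Val; Trp is excluded because its side chain is
# too large for the inter-repeat interface).

#' Define interface positions and the hydrophobic residue set
#'
#' @param positions 1-based indices within the 34-mer unit (default
#'   `c(3, 7, 10, 21, 28)`).
#' @param hydrophobic_set Residue letters counted as hydrophobic (default
#'   A, I, L, M, F, V; Trp is rejected).
#' @return An object of class `tpr_interface_definition`.
#' @export
interface_definition <- function(positions = c(3L, 7L, 10L, 21L, 28L),
                                 hydrophobic_set = c("A", "I", "L", "M", "F", "V")) {
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > 34L)) {
    tpr_abort("interface positions must lie within 1..34", "tpr_value_error")
  }
  hydrophobic_set <- toupper(hydrophobic_set)
  if ("W" %in% hydrophobic_set) {
    tpr_abort("Trp is excluded from the interface hydrophobic set",
              "tpr_value_error")
  }
  structure(list(positions = positions, hydrophobic_set = hydrophobic_set),
            class = "tpr_interface_definition")
}

#' Count hydrophobic residues at the interface positions of a 34-mer
#'
#' @param fragment A 34-residue string.
#' @param definition An [interface_definition()].
#' @param fragment_id Identifier carried into the result.
#' @return An object of class `tpr_screen_result`: list with `fragment_id`,
#'   `fragment`, `hydrophobic_count` and `hydrophobic_positions` (data.frame
#'   of index and residue).
#' @export
#' @examples
#' hydrophobic_interface_count("IKTLSKKAVLLAQEGKAEEAIKIMRKAVSLIDKA")
hydrophobic_interface_count <- function(fragment,
                                        definition = interface_definition(),
                                        fragment_id = "fragment") {
  fragment <- toupper(fragment)
  if (nchar(fragment) != 34L) {
    tpr_abort("fragment must be exactly 34 residues", "tpr_shape_error")
  }
  letters34 <- strsplit(fragment, "")[[1]]
  nonstd <- setdiff(unique(letters34), aa_alphabet())
  if (length(nonstd) > 0L) {
    warning("non-standard letters counted as non-hydrophobic: ",
            paste(nonstd, collapse = ", "), call. = FALSE)
  }
  at <- letters34[definition$positions]
  hydro <- at %in% definition$hydrophobic_set
  structure(
    list(fragment_id = fragment_id, fragment = fragment,
         hydrophobic_count = sum(hydro),
         hydrophobic_positions = data.frame(
           index = definition$positions[hydro], residue = at[hydro],
           stringsAsFactors = FALSE)),
    class = "tpr_screen_result"
  )
}

#' @export
print.tpr_screen_result <- function(x, ...) {
  pos <- paste(sprintf("(%d,%s)", x$hydrophobic_positions$index,
                       x$hydrophobic_positions$residue), collapse = " ")
  cat(sprintf("<tpr_screen_result> %s: %d/%d hydrophobic %s\n",
              x$fragment_id, x$hydrophobic_count, 5L, pos))
  invisible(x)
}

#' Screen a family alignment for stacking-compatible hairpin fragments
#'
#' Locates the 34 alignment columns covering `reference_fragment` in the
#' (gapped) reference row, extracts those columns from every row, discards
#' rows containing any gap in the window, and returns the fragments with at
#' least `min_count` hydrophobic interface residues. Lower-case letters
#' (insert states in Pfam-style alignments) are uppercased; both `-` and `.`
#' count as gaps.
#'
#' @param alignment Named character vector of aligned rows (equal lengths).
#' @param reference_id Name of the reference row.
#' @param reference_fragment The 34-mer whose columns define the window; must
#'   occur exactly once in the ungapped reference row.
#' @param definition An [interface_definition()].
#' @param min_count Minimum hydrophobic interface count (default 3).
#' @return A data.frame with columns `fragment_id`, `fragment`,
#'   `hydrophobic_count` and `hydrophobic_positions` (comma-separated
#'   "index:residue"), sorted by count (descending) then id.
#' @export
screen_family <- function(alignment, reference_id, reference_fragment,
                          definition = interface_definition(),
                          min_count = 3L) {
  if (!reference_id %in% names(alignment)) {
    tpr_abort(sprintf("reference row '%s' not found in alignment",
                      reference_id), "tpr_reference_error")
  }
  rows <- toupper(alignment)
  m <- msa_to_matrix(rows)
  is_gap <- m == "-" | m == "."
  ref <- m[match(reference_id, names(alignment)), ]
  ref_res_cols <- which(!is_gap[match(reference_id, names(alignment)), ])
  ref_ungapped <- paste(ref[ref_res_cols], collapse = "")
  reference_fragment <- toupper(reference_fragment)
  if (nchar(reference_fragment) != 34L) {
    tpr_abort("reference_fragment must be 34 residues", "tpr_shape_error")
  }
  starts <- gregexpr(reference_fragment, ref_ungapped, fixed = TRUE)[[1]]
  if (length(starts) != 1L || starts[1] == -1L) {
    tpr_abort("reference fragment absent or ambiguous in the reference row",
              "tpr_reference_error")
  }
  window_cols <- ref_res_cols[starts[1]:(starts[1] + 33L)]
  frag_m <- m[, window_cols, drop = FALSE]
  gap_free <- !apply(is_gap[, window_cols, drop = FALSE], 1L, any)
  ids <- names(alignment)[gap_free]
  frags <- apply(frag_m[gap_free, , drop = FALSE], 1L, paste, collapse = "")
  res <- lapply(seq_along(ids), function(i) {
    r <- hydrophobic_interface_count(frags[i], definition, fragment_id = ids[i])
    data.frame(
      fragment_id = r$fragment_id, fragment = r$fragment,
      hydrophobic_count = r$hydrophobic_count,
      hydrophobic_positions = paste(
        sprintf("%d:%s", r$hydrophobic_positions$index,
                r$hydrophobic_positions$residue), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[out$hydrophobic_count >= min_count, , drop = FALSE]
  out <- out[order(-out$hydrophobic_count, out$fragment_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
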