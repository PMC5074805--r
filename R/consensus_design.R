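# Rule-based consensus design: amplify a 34-residue helical hairpin into a
# three-repeat TPR construct.
#
# The design grammar mirrors how the published constructs were assembled
# from the Thermus aquaticus RPS20 hairpin (RPS20-hhta): an Asn-Ser
# N-terminal cap, three copies of the (mutated) 34-mer unit with the last
# four residues of all but the final repeat replaced by the TPR consensus
# inter-repeat loop DPNN, the native IDKA tail on the final repeat, and the
# natural RPS20 C-terminal helix as stop helix (or a two-residue stub for
# stop-helix-free constructs). Candidate point mutations are restricted to
# eight sites chosen to restore TPR signature residues, improve interface
# hydrophobicity, preserve the coevolving 7-23 pair, and neutralise surface
# charge; at most five mutations are allowed per repeat so the hairpin keeps
# its RPS20 character.

#' The RPS20-hhta parent hairpin sequence
#'
#' The 34-residue helical hairpin of ribosomal protein S20 from
#' *Thermus aquaticus*, the parent unit of all designed constructs.
#'
#' @return A 34-character string.
#' @export
rps20hhta_unit <- function() "IKTLSKKAVLLAQEGKAEEAIKIMRKAVSLIDKA"

#' TPR signature residues
#'
#' The eight strongly conserved positions of the TPR consensus.
#'
#' @return Named character vector (names are unit positions).
#' @export
tpr_signature_residues <- function() {
  c(`4` = "W", `7` = "L", `8` = "G", `11` = "Y",
    `20` = "A", `24` = "Y", `27` = "A", `32` = "P")
}

#' Parse and validate a set of point mutations
#'
#' @param mutations Character vector in one-letter notation, e.g. `"K7L"`.
#' @param applies_to_repeats Repeat indices (subset of 1:3) the mutations
#'   apply to. The surface-exposure exemption for V9N (position 9 packs
#'   against the stop helix in the last repeat, so V9 is kept there) is
#'   encoded as the default `1:2` when the spec consists of V9N alone.
#' @return An object of class `tpr_mutation_spec`: data.frame columns `pos`,
#'   `from`, `to` plus attribute `applies_to_repeats`.
#' @export
mutation_spec <- function(mutations, applies_to_repeats = NULL) {
  m <- regmatches(mutations,
                  regexec("^([A-Z])([0-9]+)([A-Z])$", toupper(mutations)))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    tpr_abort(paste("malformed mutation code:",
                    paste(mutations[bad], collapse = ", ")),
              "tpr_value_error")
  }
  df <- data.frame(
    pos = as.integer(vapply(m, `[`, character(1), 3L)),
    from = vapply(m, `[`, character(1), 2L),
    to = vapply(m, `[`, character(1), 4L),
    stringsAsFactors = FALSE
  )
  if (any(df$pos < 1L | df$pos > 34L)) {
    tpr_abort("mutation positions must lie within 1..34", "tpr_value_error")
  }
  if (is.null(applies_to_repeats)) {
    applies_to_repeats <-
      if (nrow(df) == 1L && df$pos == 9L && df$from == "V" && df$to == "N")
        1:2 else 1:3
  }
  structure(df, class = c("tpr_mutation_spec", "data.frame"),
            applies_to_repeats = as.integer(applies_to_repeats))
}

#' Build a list of per-repeat mutation specs from codes
#'
#' Convenience wrapper producing one [mutation_spec()] per code, with
#' per-mutation repeat applicability given in `applies` (default: V9N in
#' repeats 1-2 only, everything else in all repeats).
#'
#' @param codes Character vector of mutation codes.
#' @param applies Named list mapping codes to repeat-index vectors.
#' @return List of `tpr_mutation_spec` objects.
#' @export
as_mutation_specs <- function(codes, applies = list()) {
  lapply(codes, function(cd) {
    mutation_spec(cd, applies_to_repeats = applies[[cd]])
  })
}

#' Apply a mutation spec to a repeat unit
#'
#' Substitutions are applied only when `repeat_index` is in the spec's
#' `applies_to_repeats`; each declared from-residue is checked against the
#' unit.
#'
#' @param unit A 34-residue string.
#' @param spec A `tpr_mutation_spec`.
#' @param repeat_index Repeat index (1-based).
#' @return The (possibly unchanged) mutated 34-mer.
#' @export
apply_mutations <- function(unit, spec, repeat_index) {
  stopifnot(inherits(spec, "tpr_mutation_spec"))
  if (nchar(unit) != 34L) {
    tpr_abort("repeat unit must be 34 residues", "tpr_shape_error")
  }
  if (!repeat_index %in% attr(spec, "applies_to_repeats")) return(unit)
  chars <- strsplit(unit, "")[[1]]
  for (k in seq_len(nrow(spec))) {
    if (chars[spec$pos[k]] != spec$from[k]) {
      tpr_abort(sprintf(
        "mutation %s%d%s: unit has %s at position %d",
        spec$from[k], spec$pos[k], spec$to[k], chars[spec$pos[k]],
        spec$pos[k]), "tpr_mutation_error")
    }
    chars[spec$pos[k]] <- spec$to[k]
  }
  paste(chars, collapse = "")
}

#' Assembly grammar for designed TPR constructs
#'
#' @param n_cap N-terminal cap preceding the first repeat (default `"NS"`,
#'   an Asn-Ser helix cap).
#' @param n_repeats Number of repeat units (default 3, the most common TPR
#'   form).
#' @param inter_repeat_loop Four-residue consensus loop replacing unit
#'   positions 31-34 in all but the last repeat (default `"DPNN"`).
#' @param stop_helix C-terminal stop helix covering the hydrophobic face of
#'   the last repeat (default: the natural RPS20 C-terminal helix).
#' @param truncated_stop Stub used instead of the stop helix for
#'   stop-helix-free constructs (default `"AK"`).
#' @return An object of class `tpr_design_grammar`.
#' @export
design_grammar <- function(n_cap = "NS", n_repeats = 3L,
                           inter_repeat_loop = "DPNN",
                           stop_helix = "AKGSTLHKNAAARRKSRLMRKVQKL",
                           truncated_stop = "AK") {
  if (nchar(inter_repeat_loop) != 4L) {
    tpr_abort("inter_repeat_loop must be 4 residues", "tpr_value_error")
  }
  if (n_repeats < 1L) tpr_abort("n_repeats must be >= 1", "tpr_value_error")
  structure(
    list(n_cap = toupper(n_cap), n_repeats = as.integer(n_repeats),
         inter_repeat_loop = toupper(inter_repeat_loop),
         stop_helix = toupper(stop_helix),
         truncated_stop = toupper(truncated_stop)),
    class = "tpr_design_grammar"
  )
}

#' Assemble a designed TPR construct
#'
#' Builds `n_cap + [unit/DPNN] x (n_repeats - 1) + [unit, native tail] +
#' stop segment`, applying every mutation spec to each repeat according to
#' its repeat applicability. At most five point mutations may hit any one
#' repeat.
#'
#' @param parent_unit 34-residue parent hairpin (default [rps20hhta_unit()]).
#' @param specs List of `tpr_mutation_spec` objects (or a character vector of
#'   mutation codes, converted via [as_mutation_specs()]).
#' @param grammar A [design_grammar()].
#' @param name Construct name.
#' @param use_truncated_stop Use `grammar$truncated_stop` instead of the full
#'   stop helix (default `FALSE`).
#' @return An object of class `tpr_construct`: list with `name`, `sequence`,
#'   `repeats` (assembled repeat strings including loop/tail),
#'   `per_repeat_mutations` (integer count per repeat), `net_charge` and
#'   `grammar`.
#' @export
#' @examples
#' m4n <- assemble_construct(
#'   specs = as_mutation_specs(c("K6N", "K7L", "V9N", "I23Y")), name = "M4N")
#' m4n$sequence
assemble_construct <- function(parent_unit = rps20hhta_unit(), specs = list(),
                               grammar = design_grammar(), name = "design",
                               use_truncated_stop = FALSE) {
  if (nchar(parent_unit) != 34L) {
    tpr_abort("parent unit must be 34 residues", "tpr_shape_error")
  }
  if (is.character(specs)) specs <- as_mutation_specs(specs)
  n_rep <- grammar$n_repeats
  units <- character(n_rep)
  n_mut <- integer(n_rep)
  for (i in seq_len(n_rep)) {
    u <- parent_unit
    for (sp in specs) u <- apply_mutations(u, sp, i)
    n_mut[i] <- sum(strsplit(u, "")[[1]] != strsplit(parent_unit, "")[[1]])
    if (n_mut[i] > 5L) {
      tpr_abort(sprintf(
        "repeat %d carries %d mutations; at most five are allowed per repeat",
        i, n_mut[i]), "tpr_design_constraint_error")
    }
    units[i] <- u
  }
  reps <- vapply(seq_len(n_rep), function(i) {
    if (i < n_rep) {
      paste0(substr(units[i], 1L, 30L), grammar$inter_repeat_loop)
    } else units[i]
  }, character(1))
  stop_seg <- if (use_truncated_stop) grammar$truncated_stop else
    grammar$stop_helix
  sequence <- paste0(grammar$n_cap, paste(reps, collapse = ""), stop_seg)
  structure(
    list(name = name, sequence = sequence, repeats = reps,
         per_repeat_mutations = n_mut, net_charge = net_charge(sequence),
         grammar = grammar, parent_unit = parent_unit, specs = specs,
         use_truncated_stop = use_truncated_stop),
    class = "tpr_construct"
  )
}

#' @export
print.tpr_construct <- function(x, ...) {
  cat(sprintf("<tpr_construct> %s (%d aa, net charge %+d)\n%s\n",
              x$name, nchar(x$sequence), x$net_charge, x$sequence))
  invisible(x)
}

#' Decompose a construct back into its grammar segments
#'
#' Inverse of [assemble_construct()]: splits the sequence into cap, repeat
#' units and stop segment by length arithmetic and verifies the split is
#' exact.
#'
#' @param construct A `tpr_construct` (or its sequence plus `grammar` and
#'   `use_truncated_stop`).
#' @param grammar Grammar used at assembly (taken from the construct when
#'   available).
#' @param use_truncated_stop Whether the truncated stop was used.
#' @return List with `n_cap`, `repeats` (character vector) and `stop_segment`.
#' @export
decompose_construct <- function(construct, grammar = NULL,
                                use_truncated_stop = NULL) {
  if (inherits(construct, "tpr_construct")) {
    grammar <- construct$grammar
    use_truncated_stop <- construct$use_truncated_stop
    sequence <- construct$sequence
  } else sequence <- construct
  stop_seg <- if (isTRUE(use_truncated_stop)) grammar$truncated_stop else
    grammar$stop_helix
  expected <- nchar(grammar$n_cap) + 34L * grammar$n_repeats + nchar(stop_seg)
  if (nchar(sequence) != expected) {
    tpr_abort(sprintf("sequence length %d does not match grammar (%d)",
                      nchar(sequence), expected), "tpr_shape_error")
  }
  off <- nchar(grammar$n_cap)
  reps <- vapply(seq_len(grammar$n_repeats), function(i) {
    substr(sequence, off + 34L * (i - 1L) + 1L, off + 34L * i)
  }, character(1))
  tail_seg <- substr(sequence, off + 34L * grammar$n_repeats + 1L,
                     nchar(sequence))
  if (substr(sequence, 1L, off) != grammar$n_cap || tail_seg != stop_seg) {
    tpr_abort("sequence does not decompose under the grammar",
              "tpr_shape_error")
  }
  list(n_cap = grammar$n_cap, repeats = reps, stop_segment = tail_seg)
}

#' Net charge of a protein sequence
#'
#' Counted as (#Lys + #Arg) - (#Asp + #Glu); His is counted neutral (its
#' near-neutral pKa leaves it largely uncharged at physiological pH, and the
#' charge-reduction rule targets only Lys/Arg versus Asp/Glu).
#'
#' @param sequence Amino-acid string.
#' @return Integer net charge.
#' @export
net_charge <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  as.integer(sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E")))
}

# ---------------------------------------------------------------------------
# Published constructs

#' Mutation specs of the published constructs
#'
#' The seven constructs assembled from RPS20-hhta: M0 (no mutations), M2,
#' M4E, M4N, M4RD, M5 and M4NdC (M4N without the stop helix). V9N applies to
#' repeats 1-2 only; M5 applies L4W to repeats 2-3 only.
#'
#' @return Named list; each element has `codes`, `applies` and
#'   `use_truncated_stop`.
#' @export
published_construct_specs <- function() {
  list(
    M0   = list(codes = character(0), applies = list(),
                use_truncated_stop = FALSE),
    M2   = list(codes = c("K7L", "I23Y"), applies = list(),
                use_truncated_stop = FALSE),
    M4E  = list(codes = c("K2E", "K7L", "V9N", "I23Y"),
                applies = list(V9N = 1:2), use_truncated_stop = FALSE),
    M4N  = list(codes = c("K6N", "K7L", "V9N", "I23Y"),
                applies = list(V9N = 1:2), use_truncated_stop = FALSE),
    M4RD = list(codes = c("K2E", "K7R", "V9N", "I23D"),
                applies = list(V9N = 1:2), use_truncated_stop = FALSE),
    M5   = list(codes = c("K2E", "L4W", "K7L", "V9N", "I23Y"),
                applies = list(L4W = 2:3, V9N = 1:2),
                use_truncated_stop = FALSE),
    M4NdC = list(codes = c("K6N", "K7L", "V9N", "I23Y"),
                 applies = list(V9N = 1:2), use_truncated_stop = TRUE)
  )
}

#' Assemble all published constructs
#'
#' @param grammar A [design_grammar()].
#' @return Named list of `tpr_construct` objects.
#' @export
published_constructs <- function(grammar = design_grammar()) {
  specs <- published_construct_specs()
  out <- lapply(names(specs), function(nm) {
    s <- specs[[nm]]
    assemble_construct(
      specs = as_mutation_specs(s$codes, s$applies),
      grammar = grammar, name = nm,
      use_truncated_stop = s$use_truncated_stop)
  })
  names(out) <- names(specs)
  out
}

# ---------------------------------------------------------------------------
# Candidate report

.candidate_sites <- c("K2E", "L4W", "K6N", "K7L", "K7R", "V9N",
                      "K22E", "I23D", "I23Y", "R25Q", "R25E")

# Admissible joint states of the coevolving 7-23 pair. The rule set encodes
# exactly the tested combinations: L7 pairs with Y23, R7 with D23, D23 may
# also stand alone (Lys and Arg side chains are physicochemically close), and
# leaving both positions native is always admissible.
.coupling_ok <- function(to7, to23) {
  (is.na(to7) && is.na(to23)) ||
    (identical(to7, "L") && identical(to23, "Y")) ||
    (identical(to7, "R") && identical(to23, "D")) ||
    (is.na(to7) && identical(to23, "D"))
}

#' Rule-based report over candidate mutation sets
#'
#' Each candidate is a set of mutation codes drawn from the eight candidate
#' sites (K2E, L4W, K6N, K7L/R, V9N, K22E, I23D/Y, R25Q/E). Candidates
#' violating the 7-23 coupling rule or the five-mutations-per-repeat limit
#' are rejected with a reason. Accepted candidates are scored by the
#' interface hydrophobic count and signature-residue agreement of the middle
#' repeat unit (where every non-exempt mutation applies) and by the net
#' charge of the assembled construct, then ranked by signature agreement,
#' hydrophobic count and |net charge|.
#'
#' @param parent_unit 34-residue parent hairpin.
#' @param candidate_specs Named list; each element either a character vector
#'   of codes or a list with `codes` and optional `applies` (as in
#'   [published_construct_specs()]).
#' @param grammar A [design_grammar()].
#' @return A data.frame with columns `candidate`, `accepted`, `reason`,
#'   `n_mutations`, `hydrophobic_count`, `net_charge`, `signature_matches`.
#' @export
design_report <- function(parent_unit = rps20hhta_unit(), candidate_specs,
                          grammar = design_grammar()) {
  if (is.null(names(candidate_specs))) {
    names(candidate_specs) <- sprintf("candidate%02d",
                                      seq_along(candidate_specs))
  }
  sig <- tpr_signature_residues()
  rows <- lapply(names(candidate_specs), function(nm) {
    cand <- candidate_specs[[nm]]
    if (is.character(cand)) cand <- list(codes = cand, applies = list())
    codes <- toupper(cand$codes)
    row <- data.frame(candidate = nm, accepted = FALSE, reason = "",
                      n_mutations = length(codes),
                      hydrophobic_count = NA_integer_,
                      net_charge = NA_integer_,
                      signature_matches = NA_integer_,
                      stringsAsFactors = FALSE)
    unknown <- setdiff(codes, .candidate_sites)
    if (length(unknown) > 0L) {
      tpr_abort(paste("unknown candidate site:",
                      paste(unknown, collapse = ", ")),
                "tpr_candidate_site_error")
    }
    pos <- as.integer(gsub("[A-Z]", "", codes))
    if (anyDuplicated(pos)) {
      row$reason <- "conflicting mutations at one site"
      return(row)
    }
    to7 <- if (7L %in% pos) substr(codes[pos == 7L], nchar(codes[pos == 7L]),
                                   nchar(codes[pos == 7L])) else NA_character_
    to23 <- if (23L %in% pos) substr(codes[pos == 23L],
                                     nchar(codes[pos == 23L]),
                                     nchar(codes[pos == 23L])) else
      NA_character_
    if (!.coupling_ok(to7, to23)) {
      row$reason <- "violates 7-23 coupling rule"
      return(row)
    }
    specs <- as_mutation_specs(codes, applies = cand$applies)
    constr <- tryCatch(
      assemble_construct(parent_unit, specs, grammar, name = nm),
      tpr_design_constraint_error = function(e) NULL)
    if (is.null(constr)) {
      row$reason <- "more than five mutations per repeat"
      return(row)
    }
    mid <- Reduce(function(u, sp) apply_mutations(u, sp, 2L), specs,
                  parent_unit)
    mid_chars <- strsplit(mid, "")[[1]]
    row$accepted <- TRUE
    row$reason <- "ok"
    row$hydrophobic_count <- hydrophobic_interface_count(
      mid, fragment_id = nm)$hydrophobic_count
    row$net_charge <- constr$net_charge
    row$signature_matches <-
      sum(mid_chars[as.integer(names(sig))] == unname(sig))
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$accepted, -xtfrm(out$signature_matches),
                   -xtfrm(out$hydrophobic_count), abs(out$net_charge),
                   out$candidate), , drop = FALSE]
  rownames(out) <- NULL
  out
}
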