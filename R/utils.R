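# Shared constants and small helpers.

#' The 20 standard amino acids
#'
#' One-letter codes in alphabetical order. This fixed ordering defines the
#' column layout of profile matrices and the integer encoding used internally.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Background amino-acid frequencies
#'
#' Robinson & Robinson (1991) average composition of globular proteins, a
#' standard stand-in for the composition of a large sequence database such as
#' the PDB SEQRES corpus. Frequencies sum to 1 exactly.
#'
#' @return Named numeric vector over [aa_alphabet()].
#' @export
aa_background <- function() {
  f <- c(A = 0.0780, C = 0.0192, D = 0.0536, E = 0.0629, F = 0.0386,
         G = 0.0738, H = 0.0226, I = 0.0514, K = 0.0574, L = 0.0901,
         M = 0.0225, N = 0.0448, P = 0.0520, Q = 0.0426, R = 0.0512,
         S = 0.0712, T = 0.0584, V = 0.0644, W = 0.0132, Y = 0.0321)
  f[aa_alphabet()]
}

# Integer codes 1..20 for the standard alphabet, 0 for anything else.
# Lookup table indexed by utf8 codepoint keeps encoding allocation-free.
.aa_code_table <- local({
  tab <- integer(127L)
  tab[utf8ToInt(paste(aa_alphabet(), collapse = ""))] <-
    seq_along(aa_alphabet())
  tab
})

# Encode an amino-acid string to integer codes (0 = non-standard letter).
encode_aa <- function(sequence, warn_unknown = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  cp <- utf8ToInt(toupper(sequence))
  bad <- cp < 1L | cp > 127L
  cp[bad] <- 1L
  codes <- .aa_code_table[cp]
  codes[bad] <- 0L
  if (warn_unknown && any(codes == 0L)) {
    warning("non-standard residue letter(s) treated as background (score 0): ",
            paste(unique(strsplit(toupper(sequence), "")[[1]][codes == 0L]),
                  collapse = ", "),
            call. = FALSE)
  }
  codes
}

decode_aa <- function(codes) {
  letters20 <- aa_alphabet()
  paste(ifelse(codes > 0L, letters20[pmax(codes, 1L)], "X"), collapse = "")
}

# Classed error helper so callers can distinguish failure modes.
tpr_abort <- function(message, class) {
  stop(structure(
    class = c(class, "tpr_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Derive a stream-specific random seed
#'
#' All randomness in the package flows from one integer seed; repeated
#' subtasks (bootstrap replicates, FDR repetitions, Monte-Carlo draws)
#' use seeds derived by this fixed counter scheme, keeping every result
#' reproducible while decorrelating the streams. Values stay below 2^31.
#'
#' @param seed Integer master seed.
#' @param counter Integer subtask index (>= 0).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483629) * 48271 + as.double(counter) * 9973
  as.integer(s %% 2147483629) + 1L
}

# Split a character MSA (named vector of equal-length strings) into a
# character matrix of single letters, rows = sequences.
msa_to_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  w <- unique(nchar(msa))
  if (length(w) != 1L) {
    tpr_abort("alignment rows have unequal lengths", "tpr_shape_error")
  }
  m <- matrix(unlist(strsplit(toupper(msa), ""), use.names = FALSE),
              nrow = length(msa), ncol = w, byrow = TRUE)
  rownames(m) <- names(msa)
  m
}
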