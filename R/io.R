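# Readers and writers for the standard formats the pipeline touches:
# (aligned) FASTA and Stockholm alignments, PDB/mmCIF Calpha traces, hit and
# screen tables as TSV.

#' Read a (multi-)FASTA file
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @return Named character vector; names are the first whitespace-delimited
#'   token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    tpr_abort(paste("file not found:", path), "tpr_io_error")
  }
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read an alignment in aligned-FASTA or Stockholm format
#'
#' Stockholm files (detected by the `# STOCKHOLM` header) are parsed
#' minimally: `#` annotation and `//` terminator lines are skipped and
#' per-sequence lines concatenated. Gap characters `-` and `.` are kept;
#' lower-case insert states are preserved for the caller to normalise.
#'
#' @param path Alignment file.
#' @return Named character vector of aligned rows.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    tpr_abort(paste("file not found:", path), "tpr_io_error")
  }
  first <- readLines(path, n = 1L)
  if (!grepl("^# STOCKHOLM", first)) return(read_fasta(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                   nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  ids <- vapply(parts, `[`, character(1), 1L)
  seqs <- vapply(parts, `[`, character(1), 2L)
  out <- vapply(unique(ids), function(id) {
    paste(seqs[ids == id], collapse = "")
  }, character(1))
  out
}

#' Write a hit table as TSV
#'
#' Columns: seq_id, start, end, window, score_bits, p_value, singleton_flag.
#'
#' @param hits Hit data.frame from [scan_db()].
#' @param path Output file.
#' @param singleton_gap Gap used to flag singletons (default 10).
#' @export
write_hits_tsv <- function(hits, path, singleton_gap = 10L) {
  singles <- extract_singletons(hits, gap = singleton_gap)
  key <- paste(hits$seq_id, hits$start)
  out <- data.frame(
    seq_id = hits$seq_id, start = hits$start, end = hits$end,
    window = hits$window, score_bits = hits$score, p_value = hits$p_value,
    singleton_flag = key %in% paste(singles$seq_id, singles$start),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a 34-residue Calpha hairpin from a PDB or mmCIF file
#'
#' Uses the first model, Calpha atoms only, keyed by author residue number;
#' alternate locations resolve to the first (highest-occupancy in
#' PDB convention) record per residue.
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param chain Chain identifier.
#' @param resno_start First author residue number of the 34-residue window
#'   (default: first residue of the chain).
#' @param helixB_len Helix B length for the segmentation (14 or 18).
#' @return A `tpr_hairpin`.
#' @export
read_hairpin_structure <- function(path, chain = "A", resno_start = NULL,
                                   helixB_len = 14L) {
  if (!file.exists(path)) {
    tpr_abort(paste("file not found:", path), "tpr_io_error")
  }
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, elety = "CA", chain = chain)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  at <- at[!duplicated(at$resno), , drop = FALSE]     # first altloc wins
  if (is.null(resno_start)) resno_start <- min(at$resno)
  want <- resno_start:(resno_start + 33L)
  at <- at[match(want, at$resno), , drop = FALSE]
  if (anyNA(at$resno)) {
    tpr_abort("chain does not cover 34 consecutive residues from resno_start",
              "tpr_shape_error")
  }
  hairpin_structure(as.matrix(at[, c("x", "y", "z")]),
                    label = sprintf("%s_%s_%d", basename(path), chain,
                                    resno_start),
                    helixB_len = helixB_len)
}

#' Write a hairpin as a single-chain Calpha PDB file
#'
#' @param hairpin A `tpr_hairpin`.
#' @param path Output PDB file.
#' @export
write_hairpin_pdb <- function(hairpin, path) {
  n <- nrow(hairpin$coords)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(hairpin$coords)),
    resno = seq_len(n), resid = rep("ALA", n), elety = rep("CA", n),
    chain = rep("A", n)
  )
  invisible(path)
}
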