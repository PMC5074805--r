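# Ground-truth fixture generators. Every generator is a pure function of
# its arguments and seed, so fixtures are bit-reproducible and ship as code
# rather than data.

#' Simulated null sequence database
#'
#' Sequences of i.i.d. residues drawn from a given amino-acid composition,
#' with lengths resampled with replacement from an empirical pool. This
#' emulates a composition- and length-matched random counterpart of a real
#' database, the null model under which scan hits are false positives.
#'
#' @param n Number of sequences (0 gives an empty database).
#' @param composition Amino-acid frequencies over [aa_alphabet()].
#' @param length_pool Non-empty integer vector resampled for lengths.
#' @param seed Integer seed.
#' @param prefix Name prefix for records.
#' @return Named character vector of sequences.
#' @export
make_null_db <- function(n, composition = aa_background(),
                         length_pool = default_length_pool(), seed = 1L,
                         prefix = "null") {
  if (n == 0L) return(setNames(character(0), character(0)))
  if (length(length_pool) == 0L) {
    tpr_abort("length_pool must be non-empty", "tpr_config_error")
  }
  set.seed(seed)
  lens <- length_pool[sample.int(length(length_pool), n, replace = TRUE)]
  codes <- sample(aa_alphabet(), sum(lens), replace = TRUE,
                  prob = composition)
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  seqs <- vapply(seq_len(n), function(i) {
    paste(codes[starts[i]:ends[i]], collapse = "")
  }, character(1))
  names(seqs) <- sprintf("%s%05d", prefix, seq_len(n))
  seqs
}

#' Plant 34-mer units into host sequences
#'
#' Overwrites 34-residue windows of a database with the given unit sequences
#' and returns the modified database together with a truth table for
#' recall/FDR bookkeeping. Positions are either drawn at random (one unit
#' per randomly chosen host of sufficient length) or given explicitly;
#' overlapping placements within one sequence are a placement error.
#'
#' @param db Named character vector (host sequences).
#' @param units Character vector of 34-mers, one per planting.
#' @param positions `NULL` for random placement, or a data.frame with
#'   columns `seq_id` and `start` (1-based), one row per unit.
#' @param seed Integer seed (random placement).
#' @return List with `db` (modified sequences) and `truth` (data.frame
#'   `seq_id`, `start`, `unit`).
#' @export
plant_hairpins <- function(db, units, positions = NULL, seed = 1L) {
  if (any(nchar(units) != 34L)) {
    tpr_abort("all planted units must be 34 residues", "tpr_shape_error")
  }
  if (is.null(positions)) {
    set.seed(seed)
    eligible <- names(db)[nchar(db) >= 34L]
    if (length(eligible) < length(units)) {
      tpr_abort("not enough host sequences of length >= 34",
                "tpr_placement_error")
    }
    hosts <- sample(eligible, length(units))
    starts <- vapply(hosts, function(h) {
      sample.int(nchar(db[[h]]) - 33L, 1L)
    }, integer(1))
    positions <- data.frame(seq_id = hosts, start = starts,
                            stringsAsFactors = FALSE)
  }
  if (nrow(positions) != length(units)) {
    tpr_abort("positions must have one row per unit", "tpr_shape_error")
  }
  occupied <- split(seq_len(nrow(positions)), positions$seq_id)
  for (idx in occupied) {
    if (length(idx) < 2L) next
    s <- sort(positions$start[idx])
    if (any(diff(s) < 34L)) {
      tpr_abort("planted units overlap within one sequence",
                "tpr_placement_error")
    }
  }
  for (k in seq_len(nrow(positions))) {
    id <- positions$seq_id[k]; s <- positions$start[k]
    if (!id %in% names(db) || s < 1L || s + 33L > nchar(db[[id]])) {
      tpr_abort(sprintf("invalid placement %s:%d", id, s),
                "tpr_placement_error")
    }
    substr(db[[id]], s, s + 33L) <- units[k]
  }
  list(db = db,
       truth = data.frame(seq_id = positions$seq_id,
                          start = positions$start, unit = units,
                          stringsAsFactors = FALSE))
}

#' Idealised helical-hairpin Calpha coordinates
#'
#' Builds an antiparallel two-helix Calpha trace from canonical alpha-helix
#' geometry (1.5 A rise and 100 degrees twist per residue on a 2.3 A helix
#' radius), a 3-residue connecting loop, and a C-terminal extension bringing
#' the total to 34 residues (the 4-residue inter-repeat loop of a TPR unit
#' when helix B has 14 residues). Helix B runs antiparallel to helix A at a
#' 9.5 A axial offset, tilted by `180 - packing_angle` degrees. Optional
#' Gaussian coordinate noise emulates structural heterogeneity.
#'
#' @param helixA_len,loop_len,helixB_len Segment lengths (13/3/14 for a TPR
#'   unit, 13/3/18 for an RPS20-like hairpin); the total including the
#'   C-terminal extension must be 34.
#' @param packing_angle Inter-helix packing angle in degrees (default 165,
#'   near-antiparallel).
#' @param noise_sd Gaussian coordinate noise per axis in Angstrom.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param label Structure label.
#' @return A `tpr_hairpin`.
#' @export
ideal_hairpin_coords <- function(helixA_len = 13L, loop_len = 3L,
                                 helixB_len = 14L, packing_angle = 165,
                                 noise_sd = 0, seed = 1L,
                                 label = "ideal_hairpin") {
  if (helixA_len < 1L || loop_len < 1L || helixB_len < 1L) {
    tpr_abort("segment lengths must be positive", "tpr_value_error")
  }
  used <- helixA_len + loop_len + helixB_len
  if (used > 34L) {
    tpr_abort("segments exceed the 34-residue unit", "tpr_shape_error")
  }
  n_tail <- 34L - used
  rise <- 1.5; twist <- 100 * pi / 180; radius <- 2.3
  helix_pts <- function(n) {
    i <- seq_len(n) - 1L
    cbind(radius * cos(twist * i), radius * sin(twist * i), rise * i)
  }
  A <- helix_pts(helixA_len)
  # Helix B: generated along +z, then flipped antiparallel with a tilt of
  # (180 - packing_angle) about y and offset laterally by 9.5 A.
  B0 <- helix_pts(helixB_len)
  tilt <- (180 - packing_angle) * pi / 180
  flip <- rbind(c(cos(pi + tilt), 0, sin(pi + tilt)),
                c(0, 1, 0),
                c(-sin(pi + tilt), 0, cos(pi + tilt)))
  B <- B0 %*% t(flip)
  top_z <- rise * (helixA_len - 1L) + 2.0
  B <- sweep(B, 2L, c(9.5, 0, top_z) - B[1L, ], `+`)
  # Loop: linear interpolation between helix ends.
  la <- A[helixA_len, ]; lb <- B[1L, ]
  tseq <- seq_len(loop_len) / (loop_len + 1L)
  L <- t(vapply(tseq, function(t) la + t * (lb - la), numeric(3)))
  coords <- rbind(A, L, B)
  if (n_tail > 0L) {
    dirv <- coords[nrow(coords), ] - coords[nrow(coords) - 1L, ]
    dirv <- dirv / sqrt(sum(dirv^2))
    tail_pts <- t(vapply(seq_len(n_tail), function(k) {
      coords[nrow(coords), ] + 3.6 * k * dirv
    }, numeric(3)))
    coords <- rbind(coords, tail_pts)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    coords <- coords + matrix(rnorm(length(coords), sd = noise_sd),
                              ncol = 3L)
  }
  suppressWarnings(
    hairpin_structure(coords, label = label,
                      helixB_len = if (helixB_len == 18L) 18L else 14L)
  )
}

#' Synthetic repeat-unit alignment around a consensus
#'
#' Rows are independent copies of the consensus with i.i.d. substitutions at
#' the given per-position rate (replacement drawn from the composition,
#' excluding the consensus residue). Used to build scanning profiles with a
#' known consensus.
#'
#' @param consensus Consensus string (e.g. a 34-mer unit).
#' @param n_rows Number of rows.
#' @param mutation_rate Per-position substitution probability.
#' @param composition Replacement-residue frequencies.
#' @param seed Integer seed.
#' @return Named character vector (an ungapped MSA).
#' @export
make_unit_msa <- function(consensus, n_rows = 50L, mutation_rate = 0.2,
                          composition = aa_background(), seed = 1L) {
  set.seed(seed)
  w <- nchar(consensus)
  cons <- strsplit(toupper(consensus), "")[[1]]
  rows <- vapply(seq_len(n_rows), function(i) {
    chars <- cons
    hit <- runif(w) < mutation_rate
    if (any(hit)) {
      chars[hit] <- vapply(which(hit), function(p) {
        repeat {
          a <- sample(aa_alphabet(), 1L, prob = composition)
          if (a != cons[p]) return(a)
        }
      }, character(1))
    }
    paste(chars, collapse = "")
  }, character(1))
  setNames(rows, sprintf("unit%03d", seq_len(n_rows)))
}

#' Alignment with one planted covarying column pair
#'
#' Background columns are i.i.d. uniform over the 20 residues. At the
#' designated pair, the first column is uniform and the second copies it
#' through a fixed bijective recoding with probability `coupling`, otherwise
#' it is drawn independently. The population mutual information of the pair
#' is available in closed form via [covarying_pair_mi()].
#'
#' @param n_rows Number of sequences.
#' @param width Alignment width (default 34).
#' @param pair Length-2 integer vector of covarying columns (default
#'   `c(7, 23)`).
#' @param coupling Copy probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Named character vector of aligned rows.
#' @export
make_covarying_msa <- function(n_rows, width = 34L, pair = c(7L, 23L),
                               coupling = 0.8, seed = 1L) {
  if (coupling < 0 || coupling > 1) {
    tpr_abort("coupling must lie in [0, 1]", "tpr_config_error")
  }
  pair <- as.integer(pair)
  if (any(pair < 1L | pair > width) || pair[1L] == pair[2L]) {
    tpr_abort("pair indices must be distinct columns within the alignment",
              "tpr_config_error")
  }
  set.seed(seed)
  alpha <- aa_alphabet()
  m <- matrix(sample(alpha, n_rows * width, replace = TRUE),
              nrow = n_rows, ncol = width)
  a <- sample.int(20L, n_rows, replace = TRUE)
  copy <- runif(n_rows) < coupling
  b <- ifelse(copy, a %% 20L + 1L,            # fixed shift-by-one bijection
              sample.int(20L, n_rows, replace = TRUE))
  m[, pair[1L]] <- alpha[a]
  m[, pair[2L]] <- alpha[b]
  setNames(apply(m, 1L, paste, collapse = ""),
           sprintf("seq%05d", seq_len(n_rows)))
}

#' Closed-form mutual information of the planted covarying pair
#'
#' For the joint model of [make_covarying_msa()] with copy probability `c`
#' over a `K`-letter alphabet: the joint distribution is
#' `c/K` on the bijection graph plus `(1-c)/K^2` everywhere.
#'
#' @param coupling Copy probability.
#' @param K Alphabet size (default 20).
#' @return Mutual information in nats.
#' @export
covarying_pair_mi <- function(coupling, K = 20L) {
  p1 <- coupling / K + (1 - coupling) / K^2    # on-bijection cells (K of them)
  p0 <- (1 - coupling) / K^2                   # remaining K(K-1) cells
  v <- 0
  if (p1 > 0) v <- v + K * p1 * log(p1 * K^2)
  if (p0 > 0) v <- v + K * (K - 1L) * p0 * log(p0 * K^2)
  v
}

#' Synthetic chemical denaturation curve
#'
#' Forward two-state LEM signal plus Gaussian noise. Warns when the grid
#' does not cover the transition region `Cm +/- 2/m`.
#'
#' @param dG,m Unfolding free energy (kcal/mol) and m-value (kcal/mol/M);
#'   `m > 0`.
#' @param y_F,y_U Baseline intercepts.
#' @param m_F,m_U Baseline slopes.
#' @param x Denaturant grid (M).
#' @param noise_sd Gaussian noise SD (signal units).
#' @param seed Integer seed.
#' @param temperature_K Temperature (K).
#' @return A `tpr_unfolding_curve` (mode `"chemical"`).
#' @export
make_unfolding_curve <- function(dG = 5, m = 1.5, y_F = -30, y_U = -5,
                                 m_F = 0, m_U = 0,
                                 x = seq(0, 8, length.out = 25),
                                 noise_sd = 0, seed = 1L,
                                 temperature_K = 296.15) {
  if (m <= 0) tpr_abort("m must be positive", "tpr_value_error")
  cm <- dG / m
  if (min(x) > cm - 2 / m || max(x) < cm + 2 / m) {
    warning(sprintf("grid does not cover the transition (Cm = %.2f M)", cm),
            call. = FALSE)
  }
  y <- two_state_signal(x, y_F, m_F, y_U, m_U, dG, m, temperature_K)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(x), sd = noise_sd)
  }
  unfolding_curve(x, y, mode = "chemical")
}

#' Synthetic thermal melt curve
#'
#' Boltzmann sigmoid with linear baselines plus Gaussian noise.
#'
#' @param Tm Inflection temperature (degrees C).
#' @param k Transition width (degrees C).
#' @param y_F,y_U Baseline intercepts; `m_F`, `m_U` slopes.
#' @param x Temperature grid (degrees C).
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return A `tpr_unfolding_curve` (mode `"thermal"`).
#' @export
make_melt_curve <- function(Tm = 77, k = 2.5, y_F = -30, y_U = -8,
                            m_F = 0.02, m_U = 0.05,
                            x = seq(20, 95, by = 1), noise_sd = 0,
                            seed = 1L) {
  y <- melt_signal(x, y_F, m_F, y_U, m_U, Tm, k)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(x), sd = noise_sd)
  }
  unfolding_curve(x, y, mode = "thermal")
}
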