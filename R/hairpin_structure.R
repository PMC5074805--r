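# Calpha geometry of 34-residue helical hairpins: least-squares
# superposition, iterative average-unit construction, RMSD filtering and
# structural transfer of interface positions.

#' Construct a helical-hairpin Calpha structure
#'
#' A hairpin is an ordered set of 34 Calpha coordinates segmented as
#' helix A (positions 1-13), loop (14-16) and helix B (17 onward; 14
#' residues for a canonical TPR unit followed by the inter-repeat loop, 18
#' for the RPS20 hairpin). Consecutive Calpha-Calpha distances inside the
#' helical segments are validated against the physically plausible
#' 2.9-4.1 A band (warning only, so noisy synthetic structures remain
#' usable).
#'
#' @param coords Numeric 34 x 3 matrix of Calpha coordinates in Angstrom.
#' @param label Structure label.
#' @param helixB_len Length of helix B (14 or 18).
#' @return An object of class `tpr_hairpin`.
#' @export
hairpin_structure <- function(coords, label = "hairpin", helixB_len = 14L) {
  coords <- as.matrix(coords)
  if (nrow(coords) != 34L || ncol(coords) != 3L) {
    tpr_abort("a hairpin needs exactly 34 Calpha coordinates (34 x 3 matrix)",
              "tpr_shape_error")
  }
  if (!helixB_len %in% c(14L, 18L)) {
    tpr_abort("helixB_len must be 14 (TPR unit) or 18 (RPS20 hairpin)",
              "tpr_value_error")
  }
  seg <- list(helixA = 1:13, loop = 14:16, helixB = 17:(16L + helixB_len))
  for (h in c("helixA", "helixB")) {
    idx <- seg[[h]]
    d <- sqrt(rowSums((coords[idx[-1], , drop = FALSE] -
                       coords[idx[-length(idx)], , drop = FALSE])^2))
    if (any(d < 2.9 | d > 4.1)) {
      warning(sprintf("%s: consecutive Calpha distances in %s outside 2.9-4.1 A",
                      label, h), call. = FALSE)
    }
  }
  structure(list(label = label, coords = unname(coords), segmentation = seg),
            class = "tpr_hairpin")
}

#' @export
print.tpr_hairpin <- function(x, ...) {
  cat(sprintf("<tpr_hairpin> %s: 34 Calpha, helix B length %d\n",
              x$label, length(x$segmentation$helixB)))
  invisible(x)
}

coords_of <- function(x) {
  if (inherits(x, "tpr_hairpin")) x$coords else as.matrix(x)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' corresponded coordinate sets. Reflections are excluded by flipping the
#' sign of the smallest singular direction when needed, so
#' `det(rotation) == +1` always holds.
#'
#' @param mobile,reference Numeric n x 3 matrices (or `tpr_hairpin` objects)
#'   with n >= 3 corresponded points.
#' @return An object of class `tpr_superposition` with fields `rotation`
#'   (3 x 3, applied to centred row vectors), `translation` (length 3) and
#'   `rmsd` (Angstrom). `y = x %*% rotation + translation` maps mobile onto
#'   the reference frame.
#' @export
kabsch_superpose <- function(mobile, reference) {
  X <- coords_of(mobile); Y <- coords_of(reference)
  if (nrow(X) != nrow(Y) || ncol(X) != 3L || ncol(Y) != 3L) {
    tpr_abort("coordinate sets must be equal-length n x 3 matrices",
              "tpr_shape_error")
  }
  if (nrow(X) < 3L) {
    tpr_abort("superposition needs at least 3 points", "tpr_value_error")
  }
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  H <- crossprod(Xc, Yc)                       # 3x3
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  S <- diag(c(1, 1, d))
  R <- sv$u %*% S %*% t(sv$v)                  # row convention: Xc %*% R ~ Yc
  rmsd <- sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
  structure(
    list(rotation = R, translation = as.numeric(cy - cx %*% R), rmsd = rmsd),
    class = "tpr_superposition"
  )
}

#' @export
print.tpr_superposition <- function(x, ...) {
  cat(sprintf("<tpr_superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sup A `tpr_superposition`.
#' @param coords n x 3 matrix or `tpr_hairpin` (coordinates in the mobile
#'   frame).
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, coords) {
  X <- coords_of(coords)
  sweep(X %*% sup$rotation, 2L, sup$translation, `+`)
}

#' Calpha RMSD after optimal superposition
#'
#' @param a,b Coordinate matrices or `tpr_hairpin` objects.
#' @return RMSD in Angstrom.
#' @export
superposed_rmsd <- function(a, b) kabsch_superpose(a, b)$rmsd

#' Average repeat-unit structure by iterative superposition
#'
#' Because all hairpins share the 34-position correspondence, a full multiple
#' structure alignment is unnecessary: each member is superposed onto the
#' current mean (initialised to the first member), the coordinate-wise mean
#' is recomputed, and the procedure repeats until the mean moves less than
#' `tol` (plain coordinate RMS between successive means) or `max_iter` is
#' reached.
#'
#' @param hairpins List of at least two `tpr_hairpin` objects (or 34 x 3
#'   matrices).
#' @param tol Convergence tolerance in Angstrom (default 1e-6).
#' @param max_iter Maximum iterations (default 100).
#' @return A `tpr_hairpin` holding the converged mean (label "average"); the
#'   per-member RMSDs to the mean are attached as attribute `member_rmsd`.
#'   Non-convergence raises a `tpr_convergence_error` carrying the last mean
#'   in its `data` field.
#' @export
average_unit <- function(hairpins, tol = 1e-6, max_iter = 100L) {
  if (length(hairpins) < 2L) {
    tpr_abort("averaging needs at least two hairpins", "tpr_value_error")
  }
  mats <- lapply(hairpins, coords_of)
  helixB_len <- if (inherits(hairpins[[1]], "tpr_hairpin")) {
    length(hairpins[[1]]$segmentation$helixB)
  } else 14L
  ref <- mats[[1]]
  for (it in seq_len(max_iter)) {
    fitted <- lapply(mats, function(m) {
      apply_superposition(kabsch_superpose(m, ref), m)
    })
    new_mean <- Reduce(`+`, fitted) / length(fitted)
    delta <- sqrt(mean((new_mean - ref)^2))
    ref <- new_mean
    if (delta < tol) {
      member_rmsd <- vapply(mats, function(m) superposed_rmsd(m, ref),
                            numeric(1))
      # the mean is a derived object; members were validated on input
      out <- suppressWarnings(
        hairpin_structure(ref, label = "average", helixB_len = helixB_len))
      attr(out, "member_rmsd") <- member_rmsd
      attr(out, "iterations") <- it
      return(out)
    }
  }
  cond <- structure(
    class = c("tpr_convergence_error", "tpr_error", "error", "condition"),
    list(message = sprintf("average_unit did not converge in %d iterations",
                           max_iter),
         call = sys.call(-1), data = ref)
  )
  stop(cond)
}

#' Partition candidate hairpins by RMSD to the average unit
#'
#' Candidates whose superposed Calpha RMSD to the average structure exceeds
#' the cutoff are discarded as non-hairpin-like.
#'
#' @param candidates List of `tpr_hairpin` objects or 34 x 3 matrices.
#' @param average Reference `tpr_hairpin` (typically from [average_unit()]).
#' @param cutoff RMSD cutoff in Angstrom (default 2.0).
#' @return A list with elements `pass` and `fail` (sublists of `candidates`)
#'   and `report`, a data.frame of labels, RMSDs and pass flags.
#' @export
rmsd_filter <- function(candidates, average, cutoff = 2.0) {
  if (cutoff <= 0) tpr_abort("cutoff must be positive", "tpr_value_error")
  rmsds <- vapply(candidates, function(h) superposed_rmsd(h, average),
                  numeric(1))
  labels <- vapply(seq_along(candidates), function(i) {
    h <- candidates[[i]]
    if (inherits(h, "tpr_hairpin")) h$label else sprintf("candidate%03d", i)
  }, character(1))
  ok <- rmsds <= cutoff
  list(pass = candidates[ok], fail = candidates[!ok],
       report = data.frame(label = labels, rmsd = rmsds, pass = ok,
                           stringsAsFactors = FALSE))
}

#' Transfer interface positions between hairpins by structure alignment
#'
#' The reference hairpin is superposed onto the query; each reference
#' position then maps to the query position with the nearest Calpha (ties
#' resolved to the lower index). With the shared 34-residue numbering of the
#' TPR unit and the RPS20 hairpin the mapping is the identity, so the
#' canonical interface positions 3, 7, 10, 21 and 28 carry over unchanged.
#'
#' @param query,reference `tpr_hairpin` objects (34 residues each).
#' @param reference_positions 1-based indices to transfer (default
#'   `c(3, 7, 10, 21, 28)`).
#' @param warn_distance Emit a mapping-quality warning when a mapped pair is
#'   farther apart than this many Angstrom (default 5).
#' @return Integer vector of query positions, one per reference position.
#' @export
map_interface_positions <- function(query, reference,
                                    reference_positions = c(3L, 7L, 10L, 21L, 28L),
                                    warn_distance = 5) {
  qc <- coords_of(query); rc <- coords_of(reference)
  if (nrow(qc) != 34L || nrow(rc) != 34L) {
    tpr_abort("both structures must be 34-residue hairpins", "tpr_shape_error")
  }
  sup <- kabsch_superpose(rc, qc)
  rt <- apply_superposition(sup, rc)
  vapply(reference_positions, function(p) {
    d2 <- rowSums(sweep(qc, 2L, rt[p, ])^2)
    j <- which.min(d2)                 # which.min returns the lowest index on ties
    if (sqrt(d2[j]) > warn_distance) {
      warning(sprintf(
        "reference position %d maps at %.1f A (> %.1f A): low-confidence mapping",
        p, sqrt(d2[j]), warn_distance), call. = FALSE)
    }
    as.integer(j)
  }, integer(1))
}
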