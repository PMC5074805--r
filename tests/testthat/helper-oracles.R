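# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: superposition via quaternions instead of SVD,
# profile scores via per-position string lookups, distances via ape's
# cophenetic path lengths.

# Horn's quaternion method for optimal rigid superposition RMSD.
quaternion_rmsd <- function(mobile, reference) {
  X <- sweep(mobile, 2L, colMeans(mobile))
  Y <- sweep(reference, 2L, colMeans(reference))
  M <- crossprod(X, Y)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz
  ), 4L, 4L, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- sum(X^2) + sum(Y^2) - 2 * lambda
  sqrt(max(e2, 0) / nrow(mobile))
}

# Random proper rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3L))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

rigid_copy <- function(coords, rotation = random_rotation(),
                       translation = rnorm(3, sd = 20)) {
  sweep(coords %*% rotation, 2L, translation, `+`)
}

# Brute-force window score: explicit per-position lookups on letters.
brute_window_score <- function(profile, sequence, start) {
  letters34 <- strsplit(substr(sequence, start, start + profile$width - 1L),
                        "")[[1]]
  s <- 0
  for (k in seq_len(profile$width)) {
    a <- letters34[k]
    if (a %in% aa_alphabet()) s <- s + unname(profile$log_odds[k, a])
  }
  s
}

# Brute-force smoothed log-odds for one column from raw letter counts.
brute_column_log_odds <- function(column_letters, n_rows, pseudocount,
                                  background) {
  vapply(aa_alphabet(), function(a) {
    cnt <- sum(column_letters == a)
    log2((cnt + pseudocount * background[[a]]) /
           ((n_rows + pseudocount) * background[[a]]))
  }, numeric(1))
}

# Forward distance oracle: random additive distances from a random tree.
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(n) runif(n, 0.05, 1))
  d <- ape::cophenetic.phylo(tree)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tree, d = d)
}

expect_same_topology <- function(t1, t2) {
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
}

# The seven published construct sequences exactly as printed (cap + three
# repeat rows + stop segment), frozen here independently of the assembler.
printed_constructs <- function() {
  stop_helix <- "AKGSTLHKNAAARRKSRLMRKVQKL"
  c(
    M0 = paste0("NS",
                "IKTLSKKAVLLAQEGKAEEAIKIMRKAVSLDPNN",
                "IKTLSKKAVLLAQEGKAEEAIKIMRKAVSLDPNN",
                "IKTLSKKAVLLAQEGKAEEAIKIMRKAVSLIDKA", stop_helix),
    M2 = paste0("NS",
                "IKTLSKLAVLLAQEGKAEEAIKYMRKAVSLDPNN",
                "IKTLSKLAVLLAQEGKAEEAIKYMRKAVSLDPNN",
                "IKTLSKLAVLLAQEGKAEEAIKYMRKAVSLIDKA", stop_helix),
    M4E = paste0("NS",
                 "IETLSKLANLLAQEGKAEEAIKYMRKAVSLDPNN",
                 "IETLSKLANLLAQEGKAEEAIKYMRKAVSLDPNN",
                 "IETLSKLAVLLAQEGKAEEAIKYMRKAVSLIDKA", stop_helix),
    M4N = paste0("NS",
                 "IKTLSNLANLLAQEGKAEEAIKYMRKAVSLDPNN",
                 "IKTLSNLANLLAQEGKAEEAIKYMRKAVSLDPNN",
                 "IKTLSNLAVLLAQEGKAEEAIKYMRKAVSLIDKA", stop_helix),
    M4RD = paste0("NS",
                  "IETLSKRANLLAQEGKAEEAIKDMRKAVSLDPNN",
                  "IETLSKRANLLAQEGKAEEAIKDMRKAVSLDPNN",
                  "IETLSKRAVLLAQEGKAEEAIKDMRKAVSLIDKA", stop_helix),
    M5 = paste0("NS",
                "IETLSKLANLLAQEGKAEEAIKYMRKAVSLDPNN",
                "IETWSKLANLLAQEGKAEEAIKYMRKAVSLDPNN",
                "IETWSKLAVLLAQEGKAEEAIKYMRKAVSLIDKA", stop_helix),
    M4NdC = paste0("NS",
                   "IKTLSNLANLLAQEGKAEEAIKYMRKAVSLDPNN",
                   "IKTLSNLANLLAQEGKAEEAIKYMRKAVSLDPNN",
                   "IKTLSNLAVLLAQEGKAEEAIKYMRKAVSLIDKA", "AK")
  )
}
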