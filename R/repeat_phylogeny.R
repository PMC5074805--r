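# Neighbor-joining phylogenies of fixed-length repeat units.
#
# Because every TPR unit is 34 residues long, unit alignments are indel-free
# and the p-distance (fraction of differing positions) is well defined
# without further alignment. Trees from recently amplified arrays are
# star-like with short internal edges; anciently diverged repeats give long
# internal edges with strong bootstrap support.

#' Pairwise p-distance matrix of 34-residue repeat units
#'
#' @param units Named character vector of 34-mers (>= 3).
#' @return Symmetric numeric matrix with zero diagonal, entries in `[0, 1]`
#'   (Hamming distance / 34), dimnames from `names(units)`.
#' @export
p_distance_matrix <- function(units) {
  if (length(units) < 3L) {
    tpr_abort("at least three units are required", "tpr_value_error")
  }
  if (any(nchar(units) != 34L)) {
    tpr_abort("all repeat units must be 34 residues", "tpr_shape_error")
  }
  if (is.null(names(units))) names(units) <- sprintf("unit%02d",
                                                     seq_along(units))
  m <- msa_to_matrix(units)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(units), names(units)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ]) / 34
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}), which reproduces additive
#' distance matrices exactly. Negative branch lengths occasionally produced
#' by NJ on non-additive input are clamped to zero, with the negative length
#' transferred to the longest sibling branch at the same node so that path
#' lengths are preserved as closely as possible (standard practice).
#'
#' @param d Symmetric nonnegative distance matrix with zero diagonal
#'   (labels in dimnames), e.g. from [p_distance_matrix()].
#' @return An unrooted `phylo` object (\pkg{ape}).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-12)) {
    tpr_abort("distance matrix must be symmetric", "tpr_input_error")
  }
  if (any(diag(d) != 0) || any(d < 0)) {
    tpr_abort("distance matrix must be nonnegative with zero diagonal",
              "tpr_input_error")
  }
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_edges(tree)
}

# Zero out negative NJ branch lengths, compensating on the longest sibling
# edge at the same internal node.
clamp_negative_edges <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    len <- tree$edge.length[e]
    node <- tree$edge[e, 1L]
    sibs <- setdiff(which(tree$edge[, 1L] == node | tree$edge[, 2L] == node),
                    e)
    if (length(sibs) > 0L) {
      s <- sibs[which.max(tree$edge.length[sibs])]
      tree$edge.length[s] <- max(tree$edge.length[s] + len, 0)
    }
    tree$edge.length[e] <- 0
  }
  tree
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples the 34 alignment columns with replacement `n_replicates` times,
#' rebuilds the NJ tree per replicate, and maps internal-edge bipartition
#' frequencies (percent) onto the full-data tree as node labels. Bipartitions
#' subtended by a zero-length internal edge are uninformative and reported as
#' 0.
#'
#' @param units Named character vector of 34-mers.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer master seed; replicate seeds derive via
#'   [derive_seed()].
#' @return A `phylo` object with `node.label` holding support percentages
#'   (empty for the arbitrary root node) and a numeric attribute `support`.
#' @export
bootstrap_support <- function(units, n_replicates = 1000L, seed = 1L) {
  if (n_replicates < 1L) {
    tpr_abort("n_replicates must be >= 1", "tpr_value_error")
  }
  units <- units[order(names(units))]   # canonical taxon order
  m <- msa_to_matrix(units)
  full <- neighbor_joining(p_distance_matrix(units))
  boot_trees <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, r))
    cols <- sample.int(34L, 34L, replace = TRUE)
    res <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    boot_trees[[r]] <- neighbor_joining(p_distance_matrix(res))
  }
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(full, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_replicates
  # Zero-length internal edges carry no signal: report 0 support.
  internal_nodes <- (length(full$tip.label) + 1L):(length(full$tip.label) +
                                                     full$Nnode)
  for (k in seq_along(internal_nodes)) {
    e <- which(full$edge[, 2L] == internal_nodes[k])
    if (length(e) == 1L && full$edge.length[e] <= 0) support[k] <- 0
  }
  full$node.label <- as.character(round(support, 1))
  full$node.label[1L] <- ""     # basal trifurcation has no bipartition
  attr(full, "support") <- support
  full
}

#' Write a tree in Newick format
#'
#' Bootstrap supports (when present as node labels) are emitted as internal
#' node labels, the dialect produced by Clustal-style bootstrap NJ trees.
#'
#' @param tree A `phylo` object.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
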