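#' Clusters of a rooted tree
#'
#' The cluster of a vertex `v` is the set of leaf labels below `v`; a rooted
#' binary tree on `n` leaves is determined by its `2n - 1` clusters.  Trivial
#' clusters (the `n` singletons and the full taxon set at the root) are
#' included: the costs in this package allow source clusters to map to trivial
#' target clusters.
#'
#' `cluster_matrix()` returns the canonical representation used by all cost
#' computations: a `(2n - 1) x n` 0/1 matrix over a fixed taxon ordering, with
#' one row per vertex.  With this representation, all pairwise symmetric
#' difference sizes between two trees reduce to one matrix product.
#' `tree_clusters()` returns the clusters as a list of character vectors.
#'
#' @param tree An `aff_tree`.
#' @param taxa Character vector fixing the column order; defaults to the
#'   tree's own sorted taxon set.  Trees under comparison must use the same
#'   ordering.
#' @return `cluster_matrix()`: a numeric 0/1 matrix with one row per vertex
#'   (row order = vertex id).  `tree_clusters()`: a list of character vectors,
#'   one per vertex.
#' @examples
#' tr <- read_newick("((A,B),C);")
#' tree_clusters(tr)
#' @export
cluster_matrix <- function(tree, taxa = tree$taxa) {
  if (!setequal(taxa, tree$taxa)) stop("taxon set mismatch")
  n <- tree$n
  C <- matrix(0, tree$nv, n)
  ch <- tree$children
  for (v in postorder(tree)) {
    if (ch[v, 1L] == 0L) {
      C[v, match(tree$label[v], taxa)] <- 1
    } else {
      C[v, ] <- C[ch[v, 1L], ] + C[ch[v, 2L], ]
    }
  }
  colnames(C) <- taxa
  C
}

#' @rdname cluster_matrix
#' @export
tree_clusters <- function(tree) {
  C <- cluster_matrix(tree)
  lapply(seq_len(tree$nv), function(v) tree$taxa[C[v, ] == 1])
}

#' Per-vertex tau and phi profiles
#'
#' For a vertex `v` with cluster size `s` in a tree on `n` leaves,
#' `tau(v) = min(n - s, s - 1)` is the largest CA contribution the cluster of
#' `v` can incur against any target tree (it can always map to a contained
#' singleton or to the root cluster), and `phi(v) = tau(v) / s` is the
#' corresponding bound for the CS cost.  The totals `tau(T)` and `phi(T)` are
#' per-tree upper bounds on the CA and CS costs from `T` to any target;
#' caterpillars maximize tau and balanced 2-caterpillars maximize phi.
#'
#' @param tree An `aff_tree`.
#' @return `tree_profile()`: a tibble with one row per vertex (`vertex`,
#'   `size`, `tau`, `phi`).  `tau_total()` / `phi_total()`: the scalar sums.
#' @examples
#' tau_total(caterpillar_tree(5))  # 4
#' phi_total(two_caterpillar_tree(6))  # 7/3
#' @export
tree_profile <- function(tree) {
  sz <- subtree_sizes(tree)
  tau <- pmin(tree$n - sz, sz - 1L)
  tibble::tibble(vertex = seq_len(tree$nv), size = sz,
                 tau = as.integer(tau), phi = tau / sz)
}

#' @rdname tree_profile
#' @export
tau_total <- function(tree) {
  sz <- subtree_sizes(tree)
  sum(pmin(tree$n - sz, sz - 1L))
}

#' @rdname tree_profile
#' @export
phi_total <- function(tree) {
  sz <- subtree_sizes(tree)
  sum(pmin(tree$n - sz, sz - 1L) / sz)
}
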