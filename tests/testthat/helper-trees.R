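# Shared fixtures and independent oracles for the test suite.

# Random rooted binary tree on n taxa "t1".."tn" via ape.
random_tree <- function(n) {
  as_aff_tree(ape::rtree(n, rooted = TRUE, br = NULL))
}

# Canonical string form of a tree's cluster set, for set comparisons.
cluster_key <- function(tree) {
  sort(vapply(tree_clusters(tree), function(cl) paste(sort(cl), collapse = "|"),
              character(1)))
}

# Vertex id of the leaf with a given label.
leaf_id <- function(tree, label) which(tree$label == label)

# Naive set-arithmetic oracles, independent of the matrix path in the package.
naive_cluster_min <- function(cl, target_clusters) {
  min(vapply(target_clusters,
             function(x) length(setdiff(cl, x)) + length(setdiff(x, cl)),
             numeric(1)))
}

naive_ca <- function(g, s) {
  sc <- tree_clusters(s)
  sum(vapply(tree_clusters(g), naive_cluster_min, numeric(1),
             target_clusters = sc))
}

naive_cs <- function(g, s) {
  sc <- tree_clusters(s)
  gc <- tree_clusters(g)
  sum(vapply(gc, function(cl) naive_cluster_min(cl, sc) / length(cl),
             numeric(1)))
}

naive_rf <- function(g, s) {
  sc <- cluster_key(s)
  sum(!(cluster_key(g) %in% sc))
}

# All sites where a caterpillar-extend is legal in `tree`.
extend_sites <- function(tree) {
  sz <- subtree_sizes(tree)
  Filter(function(v) {
    ch <- tree$children[v, ]
    ch[1] != 0 && sz[ch[1]] >= 2 && sz[ch[2]] >= 2 &&
      is_caterpillar(tree, ch[1]) && is_caterpillar(tree, ch[2])
  }, seq_len(tree$nv))
}
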