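test_that("Newick parsing builds the expected cluster sets and rejects bad input", {
  tr <- read_newick("((A,B),C);")
  expect_s3_class(tr, "aff_tree")
  expect_equal(tr$nv, 5L)
  expect_setequal(cluster_key(tr), c("A", "B", "C", "A|B", "A|B|C"))

  expect_error(read_newick("(A,B,C);"), "non-binary")
  expect_error(read_newick("((A,B),(C,D),E);"), "non-binary")
  expect_error(read_newick("((A,A),C);"), "label collision")

  # branch lengths and internal labels are parsed but ignored
  tr2 <- read_newick("((A:1.2,B:0.1)x:3,C:9)r;")
  expect_setequal(cluster_key(tr2), cluster_key(tr))
})

test_that("write/parse round-trips preserve the cluster set", {
  set.seed(42)
  for (n in c(4, 7, 20, 60)) {
    for (rep in 1:25) {
      tr <- random_tree(n)
      back <- read_newick(write_newick(tr))
      expect_identical(cluster_key(back), cluster_key(tr))
    }
  }
})

test_that("clusters include trivial clusters and count 2n - 1", {
  c4 <- caterpillar_tree(4)
  expect_setequal(cluster_key(c4),
                  c("1", "2", "3", "4", "1|2", "1|2|3", "1|2|3|4"))
  set.seed(7)
  for (n in c(5, 12, 30)) {
    tr <- random_tree(n)
    ck <- cluster_key(tr)
    expect_length(ck, 2 * n - 1)
    sizes <- lengths(strsplit(ck, "|", fixed = TRUE))
    expect_equal(sum(sizes > 1 & sizes < n), n - 2)  # non-trivial count
  }
})

test_that("tau matches hand sums and the caterpillar closed form", {
  expect_equal(tau_total(caterpillar_tree(4)), 2)
  expect_equal(tau_total(caterpillar_tree(5)), 4)
  for (n in 2:128) {
    expect_equal(tau_total(caterpillar_tree(n)), ceiling((n^2 - 2 * n) / 4))
  }
  # per-vertex profile sums to the total; leaves and root contribute 0
  tr <- random_tree(15)
  pr <- tree_profile(tr)
  expect_equal(sum(pr$tau), tau_total(tr))
  expect_true(all(pr$tau[pr$size == 1] == 0))
  expect_equal(pr$tau[tr$root], 0L)
})

test_that("phi matches hand sums", {
  expect_equal(phi_total(two_caterpillar_tree(4)), 1.0)
  expect_equal(phi_total(two_caterpillar_tree(6)), 7 / 3)
  expect_equal(phi_total(caterpillar_tree(2)), 0)
  tr <- random_tree(12)
  pr <- tree_profile(tr)
  expect_equal(sum(pr$phi), phi_total(tr))
})

test_that("caterpillar constructions match their nested-parenthesis patterns", {
  expect_equal(write_newick(caterpillar_tree(3)), "(3,(2,1));")
  expect_equal(write_newick(caterpillar_tree(2)), "(2,1);")
  expect_setequal(setdiff(cluster_key(caterpillar_tree(5)),
                          c("1", "2", "3", "4", "5", "1|2|3|4|5")),
                  c("1|2", "1|2|3", "1|2|3|4"))
  expect_equal(write_newick(reversed_caterpillar_tree(4)), "(1,(2,(4,3)));")
  expect_setequal(setdiff(cluster_key(reversed_caterpillar_tree(4)),
                          c("1", "2", "3", "4", "1|2|3|4")),
                  c("3|4", "2|3|4"))
  expect_identical(cluster_key(reversed_caterpillar_tree(2)),
                   cluster_key(caterpillar_tree(2)))
  expect_error(caterpillar_tree(1), "at least 2")
})

test_that("balanced trees have the prefix-order pair labeling and equal depths", {
  expect_setequal(cluster_key(balanced_tree(4)),
                  c("1", "2", "3", "4", "1|4", "2|3", "1|2|3|4"))
  p8 <- balanced_tree(8)
  # cherries in prefix order are (1,8), (2,7), (3,6), (4,5)
  ch <- p8$children
  sz <- subtree_sizes(p8)
  cherries <- Filter(function(v) ch[v, 1] != 0 && sz[ch[v, 1]] == 1 &&
                       sz[ch[v, 2]] == 1, affinitree:::preorder(p8))
  labs <- lapply(cherries, function(v) sort(as.integer(p8$label[ch[v, ]])))
  expect_equal(labs, list(c(1L, 8L), c(2L, 7L), c(3L, 6L), c(4L, 5L)))
  # all leaves at depth log2(n); every cluster has the form {i..j, n-j+1..n-i+1}
  for (n in c(2, 8, 16)) {
    p <- balanced_tree(n)
    d <- vertex_depths(p)[subtree_sizes(p) == 1]
    expect_true(all(d == log2(n)))
  }
  cm <- cluster_matrix(p8)
  szs <- rowSums(cm)
  for (v in which(szs > 1 & szs < 8)) {
    members <- sort(as.integer(p8$taxa[cm[v, ] == 1]))
    expect_setequal(members, sort(unique(c(members, 8 + 1 - members))))
  }
  expect_error(balanced_tree(6), "power of two")
})

test_that("2-caterpillar constructions split taxa as ceiling/floor halves", {
  d6 <- two_caterpillar_tree(6)
  rc <- d6$children[d6$root, ]
  halves <- lapply(rc, function(v)
    sort(as.integer(stats::na.omit(d6$label[affinitree:::subtree_vertices(d6, v)]))))
  expect_setequal(halves, list(1:3, 4:6))
  expect_true(all(vapply(rc, function(v) is_caterpillar(d6, v), logical(1))))

  d5 <- two_caterpillar_tree(5)
  sz <- subtree_sizes(d5)[d5$children[d5$root, ]]
  expect_setequal(sz, c(3L, 2L))
  expect_setequal(cluster_key(two_caterpillar_tree(4))[
    lengths(strsplit(cluster_key(two_caterpillar_tree(4)), "|", fixed = TRUE)) == 2],
    c("1|2", "3|4"))
  expect_error(two_caterpillar_tree(3), "at least 4")
})

test_that("the crossed 2-caterpillar realizes the CS cost bound from D_n", {
  for (n in 4:12) {
    dn <- two_caterpillar_tree(n)
    db <- crossed_two_caterpillar_tree(n)
    expect_true(is_two_caterpillar(db))
    expect_equal(cs_cost(dn, db), phi_total(dn), tolerance = 1e-12)
  }
  # same-taxa halves (the naive reading) leave the half-root clusters at
  # distance 0 and fall short of phi(D_n)
  d6 <- two_caterpillar_tree(6)
  naive <- affinitree:::join_trees(
    affinitree:::caterpillar_from_labels(c("1", "2", "3")),
    affinitree:::caterpillar_from_labels(c("4", "5", "6")))
  expect_lt(cs_cost(d6, naive), phi_total(d6))
})

test_that("tree enumeration yields (2n-3)!! distinct trees and refuses large n", {
  expect_length(all_trees(3), 3)
  expect_length(all_trees(4), 15)
  tr6 <- all_trees(6)
  expect_length(tr6, 945)
  keys <- vapply(tr6, function(t) paste(cluster_key(t), collapse = ";"),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_error(all_trees(9), "refusing")
})
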