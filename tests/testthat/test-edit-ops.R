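test_that("SPR handles both regraft cases and rejects invalid moves", {
  tr <- read_newick("((A,B),C);")
  out <- spr(tr, leaf_id(tr, "C"), leaf_id(tr, "A"))
  expect_setequal(cluster_key(out), c("A", "B", "C", "A|C", "A|B|C"))

  # regrafting at the root creates a new root above the old one
  tr2 <- read_newick("((A,B),(C,D));")
  out2 <- spr(tr2, leaf_id(tr2, "A"), tr2$root)
  affinitree:::validate_aff_tree(out2)
  expect_setequal(cluster_key(out2), c("A", "B", "C", "D", "C|D", "B|C|D",
                                       "A|B|C|D"))
  expect_equal(out2$label[out2$children[out2$root, ]][2], "A")

  expect_error(spr(tr2, tr2$root, 1L), "cannot prune root")
  v <- tr2$children[tr2$root, 1]
  expect_error(spr(tr2, v, tr2$children[v, 1]), "inside pruned subtree")

  # regrafting onto the sibling edge is the identity
  same <- spr(tr2, leaf_id(tr2, "A"), leaf_id(tr2, "B"))
  expect_identical(cluster_key(same), cluster_key(tr2))
})

test_that("SPR preserves the leaf set and binarity along random walks", {
  set.seed(31)
  tr <- random_tree(25)
  wk <- random_walk(tr, 120, "spr")
  for (tt in wk$trees[c(2, 30, 60, 121)]) {
    affinitree:::validate_aff_tree(tt)
    expect_identical(tt$taxa, tr$taxa)
  }
})

test_that("NNI exchanges the pruned vertex's sibling and uncle, changing one cluster", {
  c4 <- caterpillar_tree(4)
  out <- nni(c4, leaf_id(c4, "1"))
  before <- cluster_key(c4); after <- cluster_key(out)
  expect_setequal(setdiff(before, after), "1|2")
  expect_setequal(setdiff(after, before), "1|3")

  expect_error(nni(c4, c4$root), "root")
  expect_error(nni(c4, c4$children[c4$root, 1]), "root")

  set.seed(5)
  for (rep in 1:40) {
    tr <- random_tree(12)
    sites <- affinitree:::nni_sites(tr)
    v <- sample(sites, 1)
    out <- nni(tr, v)
    affinitree:::validate_aff_tree(out)
    d <- union(setdiff(cluster_key(tr), cluster_key(out)),
               setdiff(cluster_key(out), cluster_key(tr)))
    expect_length(d, 2)  # one cluster replaced by one other
  }

  # applying the inverse NNI restores the original cluster set
  tr <- caterpillar_tree(5)
  ev <- attr(nni(tr, leaf_id(tr, "1")), "event")
  undo <- nni(nni(tr, leaf_id(tr, "1")), ev$v)
  expect_identical(cluster_key(undo), cluster_key(tr))
})

test_that("caterpillar-extend merges caterpillar children and never lowers tau", {
  q <- read_newick("((1,2),(3,4));")
  out <- caterpillar_extend(q, q$root)
  expect_true(is_caterpillar(out))
  expect_gte(tau_total(out), tau_total(q))
  expect_error(caterpillar_extend(caterpillar_tree(5), leaf_id(caterpillar_tree(5), "1")),
               "not allowed")

  set.seed(11)
  for (rep in 1:30) {
    tr <- random_tree(9)
    for (v in extend_sites(tr)) {
      expect_gte(tau_total(caterpillar_extend(tr, v)), tau_total(tr))
    }
  }
})

test_that("maximal extend sequences end in caterpillars", {
  set.seed(3)
  for (rep in 1:15) {
    tr <- random_tree(8)
    guard <- 0
    while (length(s <- extend_sites(tr)) > 0) {
      tr <- caterpillar_extend(tr, s[[1]])
      guard <- guard + 1
      expect_lt(guard, 100)
    }
    expect_true(is_caterpillar(tr))
  }
})

test_that("swap, split and balance enforce their side conditions and raise phi", {
  # balance moves one leaf across the root; repeated, sizes differ by <= 1
  tr <- caterpillar_tree(7)
  guard <- 0
  repeat {
    nxt <- tryCatch(caterpillar_balance(tr), error = function(e) NULL)
    if (is.null(nxt)) break
    expect_gt(phi_total(nxt), phi_total(tr))
    tr <- nxt
    guard <- guard + 1
    expect_lt(guard, 10)
  }
  sz <- subtree_sizes(tr)[tr$children[tr$root, ]]
  expect_lte(abs(diff(sz)), 1)

  expect_error(caterpillar_balance(two_caterpillar_tree(8)), "not allowed")

  # every legal rule application on 5-taxon trees raises phi by > 1/n^2
  for (tr in all_trees(5)) {
    for (a in affinitree:::applicable_rules(tr)) {
      t2 <- affinitree:::apply_rule(tr, a$rule, a$site)
      expect_gt(phi_total(t2) - phi_total(tr), 1 / 25)
    }
  }
})

test_that("rule fixpoints are balanced 2-caterpillars with the diameter phi", {
  f8 <- apply_rules_to_fixpoint(balanced_tree(8))
  expect_true(is_two_caterpillar(f8))
  expect_setequal(subtree_sizes(f8)[f8$children[f8$root, ]], c(4L, 4L))
  expect_equal(phi_total(f8), cs_diameter(8), tolerance = 1e-12)

  d10 <- two_caterpillar_tree(10)
  expect_equal(attr(apply_rules_to_fixpoint(d10), "n_steps"), 0L)

  set.seed(19)
  for (rep in 1:10) {
    f <- apply_rules_to_fixpoint(random_tree(10))
    expect_true(is_two_caterpillar(f))
    expect_equal(phi_total(f), cs_diameter(10), tolerance = 1e-12)
  }
})

test_that("random walks are reproducible and step by single edits", {
  tr <- caterpillar_tree(10)
  expect_length(random_walk(tr, 0, "nni")$trees, 1)
  w1 <- random_walk(tr, 15, "nni", seed = 99)
  w2 <- random_walk(tr, 15, "nni", seed = 99)
  expect_identical(lapply(w1$trees, write_newick), lapply(w2$trees, write_newick))
  s1 <- random_walk(tr, 15, "spr", seed = 99)
  s2 <- random_walk(tr, 15, "spr", seed = 99)
  expect_identical(lapply(s1$trees, write_newick), lapply(s2$trees, write_newick))

  for (i in 1:15) {
    a <- cluster_key(w1$trees[[i]]); b <- cluster_key(w1$trees[[i + 1]])
    expect_length(union(setdiff(a, b), setdiff(b, a)), 2)
  }
})
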