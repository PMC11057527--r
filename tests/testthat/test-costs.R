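test_that("single-cluster affinity scans all target clusters, trivial included", {
  cbar4 <- reversed_caterpillar_tree(4)
  expect_equal(cluster_affinity(c("1", "2"), cbar4), 1L)
  # {1,2,3} is matched by the root cluster under the trivial-cluster relaxation
  expect_equal(cluster_affinity(c("1", "2", "3"), cbar4), 1L)
  expect_equal(cluster_affinity(c("3", "4"), cbar4), 0L)
  expect_error(cluster_affinity(c("1", "zz"), cbar4), "taxon set mismatch")
  expect_error(cluster_affinity(character(0), cbar4), "non-empty")
})

test_that("CA cost matches the constructions and respects the tau bound", {
  c4 <- caterpillar_tree(4)
  expect_equal(ca_cost(c4, c4), 0)
  expect_equal(ca_cost(c4, reversed_caterpillar_tree(4)), 2)
  expect_equal(ca_cost(caterpillar_tree(8), balanced_tree(8)), 12)
  expect_error(ca_cost(c4, caterpillar_tree(5)), "taxon set mismatch")

  set.seed(8)
  for (rep in 1:25) {
    g <- random_tree(14); s <- random_tree(14)
    expect_lte(ca_cost(g, s), tau_total(g))      # per-tree bound
    expect_lte(cs_cost(g, s), phi_total(g))      # CS analogue
    pr <- affinity_profile(g, s)
    expect_true(all(pr$ca <= tree_profile(g)$tau))  # per-cluster bound
    expect_equal(sum(pr$ca), ca_cost(g, s))
    expect_equal(sum(pr$cs), cs_cost(g, s))
    expect_equal(sum(!pr$present), rf_one_sided(g, s))
  }
})

test_that("matrix-path costs agree with the naive set-arithmetic oracle", {
  set.seed(21)
  for (n in c(8, 32, 100)) {
    reps <- if (n == 100) 3 else 20
    for (rep in seq_len(reps)) {
      g <- random_tree(n); s <- random_tree(n)
      expect_equal(ca_cost(g, s), naive_ca(g, s))
      expect_equal(cs_cost(g, s), naive_cs(g, s), tolerance = 1e-12)
      expect_equal(rf_one_sided(g, s), naive_rf(g, s))
    }
  }
})

test_that("symmetric CA averages the directions and vanishes iff clusters agree", {
  c4 <- caterpillar_tree(4)
  expect_equal(ca_symmetric(c4, c4), 0)
  expect_equal(ca_symmetric(c4, reversed_caterpillar_tree(4)), 2)
  set.seed(13)
  for (rep in 1:20) {
    g <- random_tree(10); s <- random_tree(10)
    expect_equal(ca_symmetric(g, s), ca_symmetric(s, g))
    expect_equal(ca_symmetric(g, s), (ca_cost(g, s) + ca_cost(s, g)) / 2)
    if (ca_symmetric(g, s) == 0) {
      expect_identical(cluster_key(g), cluster_key(s))
    }
  }
})

test_that("CS variants normalize per cluster and per cluster count", {
  d4 <- two_caterpillar_tree(4)
  x <- read_newick("((1,3),(2,4));")
  expect_equal(cs_cost(d4, x), 1.0)
  expect_equal(cs_cost(d4, d4), 0)
  expect_equal(cluster_support(c("1", "2"), x), 0.5)
  expect_equal(cs_normalized(d4, x), 1.0 / 7)
  expect_equal(cs_normalized(d4, x, denominator = "nontrivial"), 1.0 / 2)
})

test_that("one-sided RF counts absent clusters, bounded by n - 2", {
  c4 <- caterpillar_tree(4)
  expect_equal(rf_one_sided(c4, c4), 0)
  expect_equal(rf_one_sided(c4, reversed_caterpillar_tree(4)), 2)
  expect_equal(rf_one_sided(read_newick("((1,2),(3,4));"),
                            read_newick("((1,3),(2,4));")), 2)
  set.seed(17)
  for (rep in 1:20) {
    g <- random_tree(9); s <- random_tree(9)
    expect_lte(rf_one_sided(g, s), 7)
  }
})

test_that("separation is symmetric, bounded, and large for the caterpillar-vs-balanced pair", {
  c4 <- caterpillar_tree(4)
  expect_equal(separation(c4, c4), 0)
  set.seed(23)
  for (rep in 1:15) {
    g <- random_tree(11); s <- random_tree(11)
    expect_equal(separation(g, s), separation(s, g))
    expect_lte(separation(g, s), ca_diameter(11))
  }
  # C_64 against P_64: one direction attains tau(C_64) = 992 while the other
  # is capped by tau(P_64) = 64*log2(64) - 2*64 + 2 = 258
  n <- 64
  cn <- caterpillar_tree(n); pn <- balanced_tree(n)
  expect_equal(ca_cost(cn, pn), (n^2 - 2 * n) / 4)
  expect_lte(ca_cost(pn, cn), n * log2(n) - 2 * n + 2)
  expect_gte(separation(cn, pn), (n^2 - 2 * n) / 4 - (n * log2(n) - 2 * n + 2))
})

test_that("diameter formulas and harmonic numbers evaluate exactly", {
  expect_equal(ca_diameter(2), 0L)
  expect_equal(ca_diameter(4), 2L)
  expect_equal(ca_diameter(5), 4L)
  expect_equal(ca_diameter(100), 2450L)
  expect_equal(cs_diameter(4), 1.0)
  expect_equal(cs_diameter(6), 7 / 3)
  expect_equal(cs_diameter(5), 5 / 3)
  expect_equal(harmonic(0), 0)
  expect_equal(harmonic(3), 11 / 6)
  ex <- cs_diameter_exact(6)
  expect_equal(c(ex$num, ex$den), c(7, 3))
  ex5 <- cs_diameter_exact(5)
  expect_equal(c(ex5$num, ex5$den), c(5, 3))
  expect_error(ca_diameter(1), "at least 2")
})

test_that("tree_comparison reports every cost with its normalization", {
  g <- caterpillar_tree(8); s <- reversed_caterpillar_tree(8)
  tc <- tree_comparison(g, s)
  expect_s3_class(tc, "tbl_df")
  expect_equal(tc$value[tc$cost == "ca" & tc$direction == "a->b"], 12)
  expect_equal(tc$normalized[tc$cost == "ca" & tc$direction == "a->b"], 1)
  expect_equal(tc$value[tc$cost == "separation"], 0)
  self <- tree_comparison(g, g)
  expect_true(all(self$value == 0))
})
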