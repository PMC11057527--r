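#' Cluster Affinity, Cluster Support and related tree-comparison costs
#'
#' The asymmetric Cluster Affinity (CA) cost from a source tree `G` to a
#' target tree `S` over the same taxa sums, over every cluster `c` of `G`
#' (trivial clusters included), the minimum symmetric-difference size between
#' `c` and any cluster of `S`:
#' \deqn{d(G,S) = \sum_{c \in C(G)} \min_{x \in C(S)} |c \Delta x|.}
#' The Cluster Support (CS) cost divides each cluster's contribution by the
#' cluster's own size, so every cluster contributes a fractional mismatch in
#' `[0, 1)`:
#' \deqn{d'(G,S) = \sum_{c \in C(G)} \min_{x \in C(S)} |c \Delta x| / |c|.}
#' `ca_symmetric()` is the arithmetic mean of the two CA directions;
#' `rf_one_sided()` counts source clusters absent from the target (the
#' one-sided Robinson-Foulds distance, or false-negative count); and
#' `separation()` is the absolute difference of the two CA directions -- a
#' measure of how asymmetric the comparison is.
#'
#' All of these are costs, not metrics: CA/CS are asymmetric and none of them
#' is claimed to satisfy the triangle inequality.
#'
#' @param source,target,a,b Trees (`aff_tree`, or anything [as_aff_tree()]
#'   accepts) over identical taxon sets.
#' @param cluster A character vector of taxon labels (a non-empty subset of
#'   the target's taxa).
#' @param denominator For `cs_normalized()`: divide the CS total by all
#'   `2n - 1` source clusters (`"all"`, the default, matching the cost's
#'   definition) or only by the `n - 2` non-trivial ones (`"nontrivial"`;
#'   trivial source clusters always contribute 0, so the default dilutes the
#'   average -- both conventions are exposed).
#' @return A single number; `cluster_affinity()` and `rf_one_sided()` are
#'   integers, the CS variants are doubles.
#' @examples
#' ca_cost(caterpillar_tree(4), reversed_caterpillar_tree(4))  # 2 = diameter
#' cs_cost(two_caterpillar_tree(6), crossed_two_caterpillar_tree(6))  # 7/3
#' @export
cluster_affinity <- function(cluster, target) {
  target <- as_aff_tree(target)
  if (length(cluster) == 0L) stop("cluster must be non-empty")
  if (!all(cluster %in% target$taxa)) stop("taxon set mismatch")
  Ct <- cluster_matrix(target)
  ind <- as.numeric(target$taxa %in% cluster)
  d <- length(cluster) + rowSums(Ct) - 2 * as.vector(Ct %*% ind)
  as.integer(min(d))
}

# All pairwise symmetric-difference sizes: D[i, j] = |c_i(source) Δ c_j(target)|.
# Row/column order = vertex ids of source/target.
cost_matrix <- function(source, target) {
  if (!setequal(source$taxa, target$taxa)) stop("taxon set mismatch")
  ord <- source$taxa
  A <- cluster_matrix(source, ord)
  B <- cluster_matrix(target, ord)
  szA <- rowSums(A); szB <- rowSums(B)
  outer(szA, szB, "+") - 2 * tcrossprod(A, B)
}

row_mins <- function(D) D[cbind(seq_len(nrow(D)), max.col(-D, ties.method = "first"))]

#' @rdname cluster_affinity
#' @export
ca_cost <- function(source, target) {
  source <- as_aff_tree(source); target <- as_aff_tree(target)
  sum(row_mins(cost_matrix(source, target)))
}

#' @rdname cluster_affinity
#' @export
ca_symmetric <- function(a, b) {
  a <- as_aff_tree(a); b <- as_aff_tree(b)
  D <- cost_matrix(a, b)
  (sum(row_mins(D)) + sum(row_mins(t(D)))) / 2
}

#' @rdname cluster_affinity
#' @export
cluster_support <- function(cluster, target) {
  cluster_affinity(cluster, target) / length(cluster)
}

#' @rdname cluster_affinity
#' @export
cs_cost <- function(source, target) {
  source <- as_aff_tree(source); target <- as_aff_tree(target)
  sz <- subtree_sizes(source)
  sum(row_mins(cost_matrix(source, target)) / sz)
}

#' @rdname cluster_affinity
#' @export
cs_normalized <- function(source, target, denominator = c("all", "nontrivial")) {
  denominator <- match.arg(denominator)
  source <- as_aff_tree(source)
  den <- if (denominator == "all") source$nv else source$n - 2L
  if (den <= 0L) stop("normalization denominator is not positive")
  cs_cost(source, target) / den
}

#' @rdname cluster_affinity
#' @export
rf_one_sided <- function(source, target) {
  source <- as_aff_tree(source); target <- as_aff_tree(target)
  sum(row_mins(cost_matrix(source, target)) > 0)
}

#' @rdname cluster_affinity
#' @export
separation <- function(a, b) {
  a <- as_aff_tree(a); b <- as_aff_tree(b)
  D <- cost_matrix(a, b)
  abs(sum(row_mins(D)) - sum(row_mins(t(D))))
}

#' Per-cluster cost breakdown
#'
#' Returns the minimum mapping cost of every source cluster against the
#' target's cluster set: the raw symmetric-difference minimum (the cluster's
#' CA contribution), its size-normalized value (the CS contribution), whether
#' the cluster is present in the target, and optionally all minimizing target
#' clusters.
#'
#' @inheritParams cluster_affinity
#' @param argmin If `TRUE`, add a list-column with every minimizing target
#'   cluster (as character vectors, in canonical vertex order).
#' @return A tibble with one row per source vertex: `vertex`, `size`,
#'   `cluster` (list-column), `ca` (integer minimum), `cs` (= `ca / size`),
#'   `present`, and `argmin` if requested.  `sum(ca)` is [ca_cost()],
#'   `sum(cs)` is [cs_cost()], `sum(!present)` is [rf_one_sided()].
#' @export
affinity_profile <- function(source, target, argmin = FALSE) {
  source <- as_aff_tree(source); target <- as_aff_tree(target)
  D <- cost_matrix(source, target)
  m <- row_mins(D)
  sz <- subtree_sizes(source)
  out <- tibble::tibble(
    vertex = seq_len(source$nv), size = sz,
    cluster = tree_clusters(source),
    ca = as.integer(m), cs = m / sz, present = m == 0)
  if (argmin) {
    tc <- tree_clusters(target)
    out$argmin <- lapply(seq_len(source$nv),
                         function(i) tc[which(D[i, ] == m[i])])
  }
  out
}

#' Full comparison report for a pair of trees
#'
#' Computes every cost in the package for a tree pair, in both directions
#' where the cost is asymmetric, together with diameter-normalized values.
#'
#' @inheritParams cluster_affinity
#' @return A tibble with columns `cost` (ca, cs, rf, ca_sym, separation),
#'   `direction` (`"a->b"`, `"b->a"` or `"sym"`), `value`, `diameter` and
#'   `normalized` (`value / diameter`; the CS diameter normalizes the raw CS
#'   total, the RF "diameter" is the non-trivial cluster count `n - 2`).
#' @examples
#' tree_comparison(caterpillar_tree(8), balanced_tree(8))
#' @export
tree_comparison <- function(a, b) {
  a <- as_aff_tree(a); b <- as_aff_tree(b)
  D <- cost_matrix(a, b)
  mab <- row_mins(D); mba <- row_mins(t(D))
  sza <- subtree_sizes(a); szb <- subtree_sizes(b)
  n <- a$n
  ca_ab <- sum(mab); ca_ba <- sum(mba)
  vals <- tibble::tribble(
    ~cost, ~direction, ~value, ~diameter,
    "ca", "a->b", ca_ab, ca_diameter(n),
    "ca", "b->a", ca_ba, ca_diameter(n),
    "ca_sym", "sym", (ca_ab + ca_ba) / 2, ca_diameter(n),
    "cs", "a->b", sum(mab / sza), cs_diameter(n),
    "cs", "b->a", sum(mba / szb), cs_diameter(n),
    "rf", "a->b", sum(mab > 0), n - 2,
    "rf", "b->a", sum(mba > 0), n - 2,
    "separation", "sym", abs(ca_ab - ca_ba), ca_diameter(n))
  vals$normalized <- ifelse(vals$diameter > 0, vals$value / vals$diameter, 0)
  vals
}

#' Exact cost diameters and harmonic numbers
#'
#' The maximum CA cost between two trees on `n` leaves is
#' `ceiling((n^2 - 2n) / 4)`, attained by a caterpillar against its reversed
#' caterpillar.  The maximum CS cost is `n - H(ceiling(n/2)) - H(floor(n/2))`
#' with `H(i)` the i-th harmonic number, attained by the balanced
#' 2-caterpillar D_n against its crossed counterpart.  `cs_diameter_exact()`
#' returns the CS diameter as an exact fraction (numerator/denominator), which
#' is possible while the common denominator stays below 2^53 (roughly
#' `n <= 80`).
#'
#' @param n Number of leaves, `n >= 2`.
#' @param i Harmonic index, `i >= 0`.
#' @return `ca_diameter()`: an integer.  `cs_diameter()`, `harmonic()`:
#'   doubles.  `cs_diameter_exact()`: a list with fields `num`, `den` and
#'   `value`.
#' @examples
#' ca_diameter(100)       # 2450
#' cs_diameter(6)         # 7/3
#' cs_diameter_exact(6)   # 7 / 3
#' @export
ca_diameter <- function(n) {
  if (n < 2) stop("n must be at least 2")
  as.integer(ceiling((n^2 - 2 * n) / 4))
}

#' @rdname ca_diameter
#' @export
cs_diameter <- function(n) {
  if (n < 2) stop("n must be at least 2")
  n - harmonic(ceiling(n / 2)) - harmonic(floor(n / 2))
}

#' @rdname ca_diameter
#' @export
harmonic <- function(i) {
  if (i < 0) stop("i must be non-negative")
  if (i == 0) return(0)
  sum(1 / seq_len(i))
}

#' @rdname ca_diameter
#' @export
cs_diameter_exact <- function(n) {
  if (n < 2) stop("n must be at least 2")
  h <- frac_add(harmonic_fraction(ceiling(n / 2)), harmonic_fraction(floor(n / 2)))
  out <- frac_add(list(num = n, den = 1), list(num = -h$num, den = h$den))
  list(num = out$num, den = out$den, value = out$num / out$den)
}

# -- exact fractions on doubles (integral, gcd-reduced, overflow-checked) ----

frac_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

frac_check <- function(x) {
  if (abs(x) >= 2^53) stop("exact fraction arithmetic overflows past 2^53")
  x
}

frac_add <- function(x, y) {
  g <- frac_gcd(x$den, y$den)
  den <- frac_check(x$den / g * y$den)
  num <- frac_check(x$num * (y$den / g)) + frac_check(y$num * (x$den / g))
  g2 <- frac_gcd(num, den)
  if (g2 > 1) { num <- num / g2; den <- den / g2 }
  list(num = num, den = den)
}

harmonic_fraction <- function(i) {
  out <- list(num = 0, den = 1)
  for (k in seq_len(i)) out <- frac_add(out, list(num = 1, den = k))
  out
}

#' Exhaustive diameter search over all tree pairs
#'
#' Enumerates every ordered pair of rooted binary trees on `n` taxa and
#' returns the maximum CA and CS costs observed, together with the theoretical
#' diameters.  Used to verify the diameter formulas exactly at small `n`
#' (945^2 ordered pairs at n = 6).
#'
#' @param n Number of taxa, `3 <= n <= 6`.
#' @return A list with `max_ca`, `max_cs`, `ca_diameter`, `cs_diameter`,
#'   `n_trees`.
#' @export
max_costs_exhaustive <- function(n) {
  if (n < 3 || n > 6) stop("exhaustive search supported for 3 <= n <= 6")
  trees <- all_trees(n)
  ord <- trees[[1]]$taxa
  mats <- lapply(trees, cluster_matrix, taxa = ord)
  Z <- do.call(rbind, mats)              # all clusters of all trees, stacked
  szZ <- rowSums(Z)
  nv <- 2L * n - 1L
  grp <- rep(seq_along(trees), each = nv) # source tree of each stacked row
  szrep <- szZ
  max_ca <- 0; max_cs <- 0
  for (j in seq_along(trees)) {
    B <- mats[[j]]
    D <- outer(szZ, rowSums(B), "+") - 2 * tcrossprod(Z, B)
    m <- row_mins(D)                     # min cost of every cluster vs tree j
    ca <- rowsum(m, grp)                 # d(T_i, T_j) for all i at once
    cs <- rowsum(m / szrep, grp)
    max_ca <- max(max_ca, ca)
    max_cs <- max(max_cs, cs)
  }
  list(max_ca = as.integer(max_ca), max_cs = max_cs,
       ca_diameter = ca_diameter(n), cs_diameter = cs_diameter(n),
       n_trees = length(trees))
}
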