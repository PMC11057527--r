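#' NNI and SPR edit operations on rooted binary trees
#'
#' `spr(tree, v, w)` prunes the subtree rooted at `v` (deleting the edge to
#' its parent `u` and suppressing `u`) and regrafts it: if `w` is the root, a
#' new root is created above the old one; otherwise the edge above `w` is
#' subdivided and `v` attached there.  `nni(tree, v)` is the SPR that regrafts
#' `v` at the sibling of its parent; it exchanges the sibling of `v` with the
#' sibling of `v`'s parent and is the smallest rooted rearrangement -- exactly
#' one cluster of the tree changes.
#'
#' Vertex ids are stable: all vertices keep their ids, with the suppressed
#' vertex's id reused for the newly created one.  The returned tree carries an
#' `"event"` attribute recording the vertices involved; for NNI this is
#' `list(kind, v, u, s, x)` where `u = parent(v)` is the vertex whose cluster
#' changed (from `c_v + c_s` to `c_v + c_x`), `s` the old sibling of `v` and
#' `x` the old sibling of `u`.  The incremental tracker consumes these events.
#'
#' @param tree An `aff_tree`.
#' @param v Vertex to prune (non-root; for NNI its parent must also be
#'   non-root).
#' @param w Regraft target vertex: not inside the pruned subtree and not the
#'   pruned vertex's parent.
#' @return A new `aff_tree` with an `"event"` attribute.
#' @examples
#' tr <- caterpillar_tree(4)
#' tr2 <- nni(tr, 1)  # leaf "1": cluster {1,2} becomes {1,3}
#' @export
nni <- function(tree, v) {
  if (v == tree$root) stop("NNI undefined: v is the root")
  u <- tree$parent[v]
  if (u == tree$root) stop("NNI undefined: parent of v is the root")
  g <- tree$parent[u]
  s <- sibling_of(tree, v)
  x <- sibling_of(tree, u)
  # swap s (sibling of v) and x (sibling of u)
  tree$children[u, ] <- c(v, x)
  tree$children[g, tree$children[g, ] == x] <- s
  tree$parent[x] <- u
  tree$parent[s] <- g
  attr(tree, "event") <- list(kind = "nni", v = v, u = u, s = s, x = x)
  tree
}

#' @rdname nni
#' @export
spr <- function(tree, v, w) {
  if (v == tree$root) stop("cannot prune root")
  u <- tree$parent[v]
  if (w == v || w %in% subtree_vertices(tree, v))
    stop("invalid regraft: target inside pruned subtree")
  if (w == u) stop("invalid regraft: target is the pruned vertex's parent")
  g <- tree$parent[u]
  s <- sibling_of(tree, v)
  old_root <- tree$root
  if (w == old_root) {
    # prune: s takes u's place; u becomes the new root above the old one
    tree$children[g, tree$children[g, ] == u] <- s
    tree$parent[s] <- g
    tree$children[u, ] <- c(w, v)
    tree$parent[w] <- u; tree$parent[v] <- u
    tree$parent[u] <- 0L
    tree$root <- u
  } else {
    p <- tree$parent[w]
    if (p == u) {
      # regrafting onto the edge above v's sibling restores the same tree
      attr(tree, "event") <- list(kind = "spr", v = v, w = w, noop = TRUE)
      return(tree)
    }
    if (g == 0L) { # u is the root: delete it, s becomes the root
      tree$parent[s] <- 0L
      tree$root <- s
    } else {
      tree$children[g, tree$children[g, ] == u] <- s
      tree$parent[s] <- g
    }
    # reuse u's id as the subdividing vertex above w
    tree$children[p, tree$children[p, ] == w] <- u
    tree$parent[u] <- p
    tree$children[u, ] <- c(w, v)
    tree$parent[w] <- u; tree$parent[v] <- u
  }
  attr(tree, "event") <- list(kind = "spr", v = v, w = w, noop = FALSE)
  tree
}

#' Caterpillar transformations behind the diameter proofs
#'
#' Four constrained edit operations, each defined only under shape and size
#' side conditions, that monotonically drive a tree towards the extremal
#' shapes:
#'
#' * `caterpillar_extend(tree, v)`: `v` has two caterpillar child subtrees
#'   with at least 2 leaves each; an NNI at a leaf child of the smaller one
#'   merges them one step closer to a single caterpillar.  tau never
#'   decreases.
#' * `caterpillar_swap(tree, x)`: with `u = parent(x)` non-root,
#'   `y = sibling(x)`, `v = sibling(u)`, all of `T(v), T(x), T(y)`
#'   caterpillars, `|c_v| < |c_y| <= |c_x|`: an NNI at `x` exchanges `y` and
#'   `v`.
#' * `caterpillar_split(tree, y)`: same configuration but
#'   `|c_y| <= min(|c_v|, |c_x|)` and `|c_y| >= 2`: the leaf child of `y` is
#'   pruned and regrafted as the sibling of `v`.
#' * `caterpillar_balance(tree)`: the root's children are caterpillars with
#'   sizes differing by more than 1; an NNI moves a leaf from the larger to
#'   the smaller side.
#'
#' Every application of swap/split/balance (and extend under Rules 1-2)
#' strictly increases phi, by more than `1/n^2`.
#'
#' @param tree An `aff_tree`.
#' @param v,x,y The operation site (see above).
#' @return A new `aff_tree`.
#' @export
caterpillar_extend <- function(tree, v) {
  ch <- tree$children[v, ]
  if (ch[1L] == 0L) stop("operation not allowed: v is a leaf")
  sz <- subtree_sizes(tree)
  t <- if (sz[ch[1L]] < sz[ch[2L]]) ch[1L] else ch[2L]  # smaller child (tie: first)
  u <- if (t == ch[1L]) ch[2L] else ch[1L]
  if (sz[t] < 2L) stop("operation not allowed: both child subtrees need >= 2 leaves")
  if (!is_caterpillar(tree, u) || !is_caterpillar(tree, t))
    stop("operation not allowed: child subtrees must be caterpillars")
  nni(tree, leaf_child_of(tree, t))
}

#' @rdname caterpillar_extend
#' @export
caterpillar_swap <- function(tree, x) {
  u <- tree$parent[x]
  if (x == tree$root || u == tree$root) stop("operation not allowed")
  y <- sibling_of(tree, x)
  v <- sibling_of(tree, u)
  sz <- subtree_sizes(tree)
  ok <- is_caterpillar(tree, v) && is_caterpillar(tree, x) &&
    is_caterpillar(tree, y) && sz[v] < sz[y] && sz[y] <= sz[x]
  if (!ok) stop("operation not allowed: caterpillar-swap side conditions unmet")
  nni(tree, x)
}

#' @rdname caterpillar_extend
#' @export
caterpillar_split <- function(tree, y) {
  u <- tree$parent[y]
  if (y == tree$root || u == tree$root) stop("operation not allowed")
  x <- sibling_of(tree, y)
  v <- sibling_of(tree, u)
  sz <- subtree_sizes(tree)
  ok <- is_caterpillar(tree, v) && is_caterpillar(tree, x) &&
    is_caterpillar(tree, y) && sz[y] <= sz[v] && sz[y] <= sz[x] && sz[y] >= 2L
  if (!ok) stop("operation not allowed: caterpillar-split side conditions unmet")
  spr(tree, leaf_child_of(tree, y), v)
}

#' @rdname caterpillar_extend
#' @export
caterpillar_balance <- function(tree) {
  ch <- tree$children[tree$root, ]
  sz <- subtree_sizes(tree)
  u <- if (sz[ch[1L]] >= sz[ch[2L]]) ch[1L] else ch[2L]
  v <- if (u == ch[1L]) ch[2L] else ch[1L]
  ok <- is_caterpillar(tree, u) && is_caterpillar(tree, v) && sz[v] < sz[u] - 1L
  if (!ok) stop("operation not allowed: caterpillar-balance side conditions unmet")
  nni(tree, leaf_child_of(tree, u))
}

# ---- rule engine -----------------------------------------------------------

# List the (rule, site) applications legal at `tree`, per the five
# transformation rules.  Rule sites:
#   rule 1: non-root v, |c_v| <= n/2, T(v) not a caterpillar
#           -> one extend at the deepest qualifying vertex inside T(v)
#   rule 2: non-root u with caterpillar children x >= y, |c_y| >= 2,
#           |c_x| < n/2, |c_u| > n/2 -> extend at u
#   rule 3: u non-root, T(v), T(x), T(y) caterpillars, T(u) not,
#           |c_v| < |c_y|, |c_x| >= n/2 -> swap at x
#   rule 4: as rule 3 but |c_y| <= |c_v| -> split at y
#   rule 5: root children caterpillars, sizes differ by > 1 -> balance
applicable_rules <- function(tree) {
  n <- tree$n
  sz <- subtree_sizes(tree)
  dep <- vertex_depths(tree)
  cat_flag <- vapply(seq_len(tree$nv), function(v) is_caterpillar(tree, v),
                     logical(1))
  out <- list()
  add <- function(rule, site) out[[length(out) + 1L]] <<- list(rule = rule, site = site, depth = dep[site])
  for (v in seq_len(tree$nv)) {
    if (v == tree$root) next
    if (sz[v] <= n / 2 && !cat_flag[v]) add(1L, v)
  }
  for (u in seq_len(tree$nv)) {
    if (u == tree$root || tree$parent[u] == 0L) next
    ch <- tree$children[u, ]
    if (ch[1L] == 0L) next
    x <- if (sz[ch[1L]] >= sz[ch[2L]]) ch[1L] else ch[2L]
    y <- if (x == ch[1L]) ch[2L] else ch[1L]
    v <- sibling_of(tree, u)
    if (cat_flag[x] && cat_flag[y] && sz[y] >= 2L &&
        sz[x] < n / 2 && sz[u] > n / 2) add(2L, u)
    if (cat_flag[v] && cat_flag[x] && cat_flag[y] && !cat_flag[u] &&
        sz[x] >= n / 2) {
      if (sz[v] < sz[y]) add(3L, x)
      if (sz[y] <= sz[v] && sz[y] >= 2L) add(4L, y)
    }
  }
  rch <- tree$children[tree$root, ]
  if (cat_flag[rch[1L]] && cat_flag[rch[2L]] &&
      abs(sz[rch[1L]] - sz[rch[2L]]) > 1L) add(5L, tree$root)
  out
}

apply_rule <- function(tree, rule, site) {
  switch(rule,
    { # rule 1: extend at the deepest vertex of T(site) with two caterpillar
      # children of size >= 2
      sz <- subtree_sizes(tree)
      dep <- vertex_depths(tree)
      cand <- Filter(function(w) {
        ch <- tree$children[w, ]
        ch[1L] != 0L && sz[ch[1L]] >= 2L && sz[ch[2L]] >= 2L &&
          is_caterpillar(tree, ch[1L]) && is_caterpillar(tree, ch[2L])
      }, subtree_vertices(tree, site))
      if (!length(cand)) stop("rule 1: no caterpillar-extend site found")
      w <- cand[[which.max(vapply(cand, function(z) dep[z], numeric(1)))]]
      caterpillar_extend(tree, w)
    },
    caterpillar_extend(tree, site),   # rule 2
    caterpillar_swap(tree, site),     # rule 3
    caterpillar_split(tree, site),    # rule 4
    caterpillar_balance(tree))        # rule 5
}

#' Transform a tree into a balanced 2-caterpillar by rule applications
#'
#' Repeatedly applies the lowest-numbered applicable rule (ties broken at the
#' shallowest qualifying vertex, then by vertex id) until no rule applies.
#' A rule applies exactly when the tree is not yet a balanced 2-caterpillar,
#' every application strictly increases phi by more than `1/n^2`, and any
#' maximal sequence therefore terminates -- at a 2-caterpillar whose phi value
#' is the CS diameter regardless of the starting tree.
#'
#' @param tree An `aff_tree` with at least 4 leaves.
#' @return The fixpoint tree, with attribute `"n_steps"` (number of rule
#'   applications performed).
#' @examples
#' ft <- apply_rules_to_fixpoint(balanced_tree(8))
#' is_two_caterpillar(ft)
#' @export
apply_rules_to_fixpoint <- function(tree) {
  tree <- as_aff_tree(tree)
  if (tree$n < 4) stop("n must be at least 4")
  steps <- 0L
  limit <- (2L * tree$n - 1L) * tree$n^2 + 10L
  repeat {
    if (is_two_caterpillar(tree)) break
    apps <- applicable_rules(tree)
    if (!length(apps))
      stop("no rule applies but the tree is not a 2-caterpillar")
    pick <- apps[[order(vapply(apps, `[[`, numeric(1), "rule"),
                        vapply(apps, `[[`, numeric(1), "depth"),
                        vapply(apps, `[[`, numeric(1), "site"))[1L]]]
    tree <- apply_rule(tree, pick$rule, pick$site)
    steps <- steps + 1L
    if (steps > limit) stop("rule sequence exceeded its termination bound")
  }
  attr(tree, "event") <- NULL
  attr(tree, "n_steps") <- steps
  tree
}

# ---- random walks ----------------------------------------------------------

# Vertices where NNI is defined: non-root with non-root parent.
nni_sites <- function(tree) {
  v <- seq_len(tree$nv)
  v[v != tree$root & tree$parent[v] != 0L & tree$parent[v] != tree$root]
}

#' Seeded random NNI / SPR walks
#'
#' Generates a walk `T_0, T_1, ..., T_k` where each tree arises from its
#' predecessor by one uniformly chosen edit.  NNI edits are uniform over all
#' vertices where NNI is defined; SPR edits are uniform over valid
#' prune/regraft pairs `(v, w)` with `w` outside the pruned subtree,
#' excluding the two choices that recreate the same tree (`w = parent(v)`,
#' `w = sibling(v)`).
#'
#' @param tree The start tree.
#' @param k Number of steps (`k >= 0`).
#' @param op `"nni"` or `"spr"`.
#' @param seed Optional integer seed (sets the R RNG).
#' @return A list with `trees` (length `k + 1`, starting at the input tree)
#'   and `events` (length `k`, the `"event"` attribute of each step).
#' @export
random_walk <- function(tree, k, op = c("nni", "spr"), seed = NULL) {
  op <- match.arg(op)
  tree <- as_aff_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  trees <- vector("list", k + 1L)
  events <- vector("list", k)
  trees[[1L]] <- tree
  cur <- tree
  for (i in seq_len(k)) {
    cur <- if (op == "nni") {
      sites <- nni_sites(cur)
      nni(cur, sites[sample.int(length(sites), 1L)])
    } else {
      random_spr(cur)
    }
    ev <- attr(cur, "event")
    ev$step <- i
    events[[i]] <- ev
    trees[[i + 1L]] <- cur
  }
  list(trees = trees, events = events)
}

# Uniform over valid (v, w) pairs: v is drawn with probability proportional
# to its number of valid regraft targets, then w uniformly among them.
# A pruned subtree with s leaves blocks 2s - 1 vertices plus parent & sibling.
random_spr <- function(tree) {
  sz <- subtree_sizes(tree)
  wcount <- tree$nv - 2L * sz - 1L
  wcount[tree$root] <- 0L
  v <- sample.int(tree$nv, 1L, prob = pmax(wcount, 0))
  excl <- c(subtree_vertices(tree, v), tree$parent[v], sibling_of(tree, v))
  w_ok <- setdiff(seq_len(tree$nv), excl)
  w <- w_ok[sample.int(length(w_ok), 1L)]
  spr(tree, v, w)
}
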