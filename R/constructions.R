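#' Extremal tree constructions
#'
#' Builders for the tree families that realize the cost diameters:
#'
#' * `caterpillar_tree(n)` -- the caterpillar `(n,(n-1,...(2,1)...))`: every
#'   internal vertex has a leaf child; it maximizes the per-tree CA bound
#'   tau(T).
#' * `reversed_caterpillar_tree(n)` -- the caterpillar `(1,(2,...(n,n-1)...))`
#'   whose non-trivial clusters are suffix sets; the CA cost from the plain to
#'   the reversed caterpillar attains the CA diameter.
#' * `balanced_tree(n)` -- a perfectly balanced tree on `n = 2^m` leaves whose
#'   i-th cherry, in prefix (preorder) order, carries leaf labels `i` and
#'   `n - i + 1`; every non-trivial cluster has the form
#'   `{i..j, n-j+1..n-i+1}`, which makes the CA cost from the caterpillar
#'   equal to tau(C_n) while tau of the balanced tree itself is only
#'   `n*log2(n) - 2n + 2` -- the gap behind the quadratic separation diameter.
#' * `two_caterpillar_tree(n)` -- D_n: two caterpillars of sizes ceiling(n/2)
#'   (taxa `1..ceiling(n/2)`) and floor(n/2) (the rest) joined at the root;
#'   it maximizes the per-tree CS bound phi(T).
#' * `crossed_two_caterpillar_tree(n)` -- a 2-caterpillar target realizing the
#'   CS diameter from D_n.  Taxa are interleaved in balanced pairs
#'   `1, n, 2, n-1, ...` (echoing the balanced-tree cherry labeling) and the
#'   sequence is cut into two caterpillar halves, deepest cherry first.
#'   Every cluster of this tree then holds at most
#'   `(size + 1) / 2` taxa from any prefix `{1..j}` or suffix
#'   `{n-j+1..n}`, so every cluster of D_n meets it at its full tau value and
#'   the CS cost from D_n equals phi(D_n).  (Crossing the taxa is essential:
#'   with the same taxa in corresponding halves, D_n's half-root clusters
#'   would be present at distance 0.)
#'
#' Leaves are labelled `"1" .. "n"`.
#'
#' @param n Number of leaves (`n >= 2`; `balanced_tree` needs a power of two,
#'   the 2-caterpillars need `n >= 4`).
#' @return An `aff_tree`.
#' @examples
#' write_newick(caterpillar_tree(4))
#' write_newick(crossed_two_caterpillar_tree(4))
#' @export
caterpillar_tree <- function(n) {
  if (n < 2) stop("n must be at least 2")
  caterpillar_from_labels(as.character(n:1))
}

#' @rdname caterpillar_tree
#' @export
reversed_caterpillar_tree <- function(n) {
  if (n < 2) stop("n must be at least 2")
  caterpillar_from_labels(reversed_label_order(as.character(1:n)))
}

# C-bar ordering of an ascending label sequence: top leaf first, deepest
# cherry (h[k], h[k-1]).
reversed_label_order <- function(h) {
  k <- length(h)
  if (k == 2L) c(h[2L], h[1L]) else c(h[seq_len(k - 2L)], h[k], h[k - 1L])
}

# Caterpillar with `labs[1]` the leaf nearest the root and the cherry
# (labs[k-1], labs[k]) deepest.  Built iteratively on the arrays.
caterpillar_from_labels <- function(labs) {
  n <- length(labs)
  stopifnot(n >= 2L)
  nv <- 2L * n - 1L
  parent <- integer(nv); children <- matrix(0L, nv, 2L)
  label <- rep(NA_character_, nv)
  label[1:n] <- labs
  # internal vertices n+1..nv: n+1 is the root (pairs leaf 1 with n+2), etc.
  for (i in seq_len(n - 1L)) {
    v <- n + i
    left <- i                                  # leaf labs[i]
    right <- if (i == n - 1L) n else n + i + 1L
    children[v, ] <- c(left, right)
    parent[left] <- v; parent[right] <- v
  }
  new_aff_tree(n, root = n + 1L, parent = parent, children = children,
               label = label)
}

#' @rdname caterpillar_tree
#' @export
balanced_tree <- function(n) {
  if (n < 2 || bitwAnd(n, n - 1L) != 0L)
    stop("n must be a power of two, n >= 2")
  if (n == 2L) return(caterpillar_from_labels(c("1", "2")))
  env <- new.env()
  env$next_cherry <- 0L
  build <- function(k) {
    if (k == 2L) {
      env$next_cherry <- env$next_cherry + 1L
      i <- env$next_cherry
      return(list(as.character(i), as.character(n - i + 1L)))
    }
    left <- build(k %/% 2L)   # prefix order: left subtree first
    right <- build(k %/% 2L)
    list(left, right)
  }
  tree_from_nested(build(as.integer(n)))
}

#' @rdname caterpillar_tree
#' @export
two_caterpillar_tree <- function(n) {
  if (n < 4) stop("n must be at least 4")
  h <- ceiling(n / 2)
  join_trees(caterpillar_from_labels(as.character(h:1)),
             caterpillar_from_labels(as.character(n:(h + 1L))))
}

#' @rdname caterpillar_tree
#' @export
crossed_two_caterpillar_tree <- function(n) {
  if (n < 4) stop("n must be at least 4")
  q <- n %/% 2L
  s <- as.vector(rbind(seq_len(q), n + 1L - seq_len(q)))  # 1, n, 2, n-1, ...
  if (n %% 2L == 1L) s <- c(s, q + 1L)                    # odd: middle taxon last
  h <- ceiling(n / 2)
  # deepest cherry = earliest pair of each half (labels reversed: root-near first)
  join_trees(caterpillar_from_labels(as.character(rev(s[seq_len(h)]))),
             caterpillar_from_labels(as.character(rev(s[(h + 1L):n]))))
}

# Join two trees under a new root.
join_trees <- function(a, b) {
  na <- a$nv; nb <- b$nv
  nv <- na + nb + 1L
  parent <- integer(nv); children <- matrix(0L, nv, 2L)
  label <- rep(NA_character_, nv)
  parent[seq_len(na)] <- a$parent
  children[seq_len(na), ] <- a$children
  label[seq_len(na)] <- a$label
  off <- na
  pb <- b$parent; pb[pb != 0L] <- pb[pb != 0L] + off
  parent[off + seq_len(nb)] <- pb
  cb <- b$children; cb[cb != 0L] <- cb[cb != 0L] + off
  children[off + seq_len(nb), ] <- cb
  label[off + seq_len(nb)] <- b$label
  root <- nv
  children[root, ] <- c(a$root, b$root + off)
  parent[a$root] <- root; parent[b$root + off] <- root
  new_aff_tree((a$n + b$n), root = root, parent = parent,
               children = children, label = label)
}

# Build an aff_tree from nested lists of leaf labels.
tree_from_nested <- function(x) {
  env <- new.env()
  env$parent <- integer(64); env$children <- matrix(0L, 64, 2L)
  env$label <- rep(NA_character_, 64); env$k <- 0L
  grow <- function(m) {
    if (m > length(env$parent)) {
      sz <- max(2L * length(env$parent), m)
      env$parent <- c(env$parent, integer(sz - length(env$parent)))
      env$label <- c(env$label, rep(NA_character_, sz - length(env$label)))
      ch <- matrix(0L, sz, 2L); ch[seq_len(nrow(env$children)), ] <- env$children
      env$children <- ch
    }
  }
  rec <- function(node) {
    env$k <- env$k + 1L; v <- env$k; grow(v)
    if (is.character(node)) {
      env$label[v] <- node
    } else {
      stopifnot(length(node) == 2L)
      a <- rec(node[[1L]]); b <- rec(node[[2L]])
      env$children[v, ] <- c(a, b)
      env$parent[a] <- v; env$parent[b] <- v
    }
    v
  }
  root <- rec(x)
  nv <- env$k
  n <- (nv + 1L) %/% 2L
  new_aff_tree(n, root = root, parent = env$parent[seq_len(nv)],
               children = env$children[seq_len(nv), , drop = FALSE],
               label = env$label[seq_len(nv)])
}

#' Enumerate all rooted binary trees on a small taxon set
#'
#' Generates every rooted binary tree on taxa `"1" .. "n"` by leaf insertion:
#' the trees on `n` taxa arise from each tree on `n - 1` taxa by attaching the
#' new leaf on any of its `2n - 3` edges (counting the edge above the root).
#' There are `(2n - 3)!!` such trees; the enumeration is refused for `n > 8`
#' (10,395 trees at n = 8).
#'
#' @param n Number of taxa, `2 <= n <= 8`.
#' @return A list of `aff_tree` objects.
#' @examples
#' length(all_trees(4))  # 15
#' @export
all_trees <- function(n) {
  if (n < 2) stop("n must be at least 2")
  if (n > 8) stop("refusing to enumerate trees for n > 8")
  # nested-list representation; insert leaf on every edge incl. above root
  trees <- list(list("1", "2"))
  if (n == 2L) return(lapply(trees, tree_from_nested))
  for (k in 3:n) {
    leaf <- as.character(k)
    out <- list()
    for (t in trees) {
      out <- c(out, insert_everywhere(t, leaf))
    }
    trees <- out
  }
  lapply(trees, tree_from_nested)
}

insert_everywhere <- function(t, leaf) {
  res <- list(list(t, leaf))  # above the root
  if (is.character(t)) return(res)
  for (side in 1:2) {
    for (sub in insert_everywhere(t[[side]], leaf)) {
      t2 <- t; t2[[side]] <- sub
      res <- c(res, list(t2))
    }
  }
  res
}
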