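#' Rooted binary phylogenetic trees
#'
#' `aff_tree` is the tree representation used throughout the package: a rooted
#' binary tree whose leaves are bijectively labelled with a taxon set.  It is a
#' plain list of parallel vectors (parent pointers, a two-column children
#' matrix, leaf labels), which keeps vertex identities stable under the edit
#' operations ([nni()], [spr()]) -- a property the incremental cost tracker
#' relies on.
#'
#' Fields: `n` (leaf count), `nv = 2n - 1` (vertex count), `root` (vertex id),
#' `parent` (integer vector, 0 at the root), `children` (nv x 2 integer matrix,
#' zeros at leaves), `label` (character vector, `NA` at internal vertices) and
#' `taxa` (the sorted taxon set).
#'
#' @param x An object to convert.
#' @param ... Passed on to methods.
#' @return An object of class `aff_tree`.
#' @seealso [read_newick()], [as.phylo.aff_tree()]
#' @export
as_aff_tree <- function(x, ...) UseMethod("as_aff_tree")

#' @export
as_aff_tree.aff_tree <- function(x, ...) x

#' @rdname as_aff_tree
#' @export
as_aff_tree.phylo <- function(x, ...) {
  n <- length(x$tip.label)
  if (n < 2L) stop("tree must have at least 2 leaves")
  if (is.null(x$Nnode) || x$Nnode != n - 1L)
    stop("non-binary tree: a rooted binary tree on ", n,
         " leaves must have ", n - 1L, " internal vertices")
  nv <- 2L * n - 1L
  parent <- integer(nv)
  children <- matrix(0L, nv, 2L)
  cnt <- integer(nv)
  for (i in seq_len(nrow(x$edge))) {
    p <- x$edge[i, 1L]; v <- x$edge[i, 2L]
    parent[v] <- p
    cnt[p] <- cnt[p] + 1L
    if (cnt[p] > 2L) stop("non-binary tree: polytomy at an internal vertex")
    children[p, cnt[p]] <- v
  }
  if (any(cnt[(n + 1L):nv] != 2L)) stop("non-binary tree")
  root <- which(parent[(n + 1L):nv] == 0L) + n
  if (length(root) != 1L) stop("tree must have a single root")
  lab <- c(x$tip.label, rep(NA_character_, n - 1L))
  if (anyDuplicated(x$tip.label)) stop("label collision: duplicate leaf labels")
  if (any(!nzchar(x$tip.label))) stop("empty leaf label")
  new_aff_tree(n = n, root = as.integer(root), parent = parent,
               children = children, label = lab)
}

new_aff_tree <- function(n, root, parent, children, label) {
  structure(
    list(n = as.integer(n), nv = 2L * as.integer(n) - 1L,
         root = as.integer(root), parent = as.integer(parent),
         children = children, label = label,
         taxa = sort(label[!is.na(label)])),
    class = "aff_tree")
}

#' Read and write rooted binary trees in Newick format
#'
#' `read_newick()` accepts a Newick string or a file path and returns an
#' [as_aff_tree()] tree.  The tree must be rooted and strictly binary;
#' polytomies and duplicated leaf labels are rejected.  Branch lengths and
#' internal node labels are parsed but discarded: all costs in this package are
#' topology-only.  `write_newick()` renders a tree back to Newick (topology
#' only), optionally writing it to `file`.
#'
#' @param x A Newick string (containing "(") or the path of a file with one or
#'   more Newick trees.
#' @param tree An `aff_tree`.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return `read_newick()`: an `aff_tree` (or a list of them if the file holds
#'   several trees).  `write_newick()`: the Newick string, invisibly when
#'   written to a file.
#' @examples
#' tr <- read_newick("((A,B),C);")
#' write_newick(tr)
#' @export
read_newick <- function(x) {
  ph <- if (grepl("(", x[1], fixed = TRUE)) ape::read.tree(text = x)
        else ape::read.tree(file = x)
  if (is.null(ph)) stop("could not parse Newick input")
  if (inherits(ph, "multiPhylo")) return(lapply(ph, as_aff_tree))
  as_aff_tree(ph)
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(as.phylo(tree))
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' @importFrom ape as.phylo
#' @export
ape::as.phylo

#' Convert an `aff_tree` to an ape `phylo` object
#'
#' @param x An `aff_tree`.
#' @param ... Unused.
#' @return An object of class `phylo`.
#' @export
as.phylo.aff_tree <- function(x, ...) {
  n <- x$n
  # ape convention: tips 1..n, root n+1, internals in preorder
  newid <- integer(x$nv)
  tip_i <- 0L; int_i <- n
  ord <- preorder(x)
  tip_label <- character(n)
  for (v in ord) {
    if (x$children[v, 1L] == 0L) {
      tip_i <- tip_i + 1L
      newid[v] <- tip_i
      tip_label[tip_i] <- x$label[v]
    } else {
      int_i <- int_i + 1L
      newid[v] <- int_i
    }
  }
  nonroot <- setdiff(seq_len(x$nv), x$root)
  edge <- cbind(newid[x$parent[nonroot]], newid[nonroot])
  storage.mode(edge) <- "integer"
  ph <- list(edge = edge, tip.label = tip_label, Nnode = n - 1L)
  class(ph) <- "phylo"
  attr(ph, "order") <- NULL
  ape::reorder.phylo(ph, "cladewise")
}

# Preorder (root first) vertex sequence, iterative.
preorder <- function(tree) {
  out <- integer(tree$nv)
  stack <- integer(tree$nv)
  stack[1L] <- tree$root
  top <- 1L; k <- 0L
  ch <- tree$children
  while (top > 0L) {
    v <- stack[top]; top <- top - 1L
    k <- k + 1L; out[k] <- v
    if (ch[v, 1L] != 0L) {
      top <- top + 1L; stack[top] <- ch[v, 2L]
      top <- top + 1L; stack[top] <- ch[v, 1L]
    }
  }
  out
}

# Postorder = reversed preorder of mirrored children; children always precede
# parents in rev(preorder).
postorder <- function(tree) rev(preorder(tree))

#' Tree accessors
#'
#' Small helpers on `aff_tree` objects: `n_leaves()` returns the number of
#' leaves, `taxa()` the sorted taxon set, `subtree_sizes()` the number of
#' leaves below every vertex, `vertex_depths()` the edge distance from the
#' root, and `is_caterpillar()` / `is_two_caterpillar()` test the extremal
#' shapes used by the diameter theory (a caterpillar has a leaf child at every
#' internal vertex; a 2-caterpillar has two caterpillar subtrees of near-equal
#' size, differing by at most one leaf, hanging off the root).
#'
#' @param tree An `aff_tree`.
#' @param v A vertex id; defaults to the root.
#' @return See individual descriptions.
#' @export
n_leaves <- function(tree) tree$n

#' @rdname n_leaves
#' @export
taxa <- function(tree) tree$taxa

#' @rdname n_leaves
#' @export
subtree_sizes <- function(tree) {
  sz <- integer(tree$nv)
  ch <- tree$children
  for (v in postorder(tree)) {
    sz[v] <- if (ch[v, 1L] == 0L) 1L else sz[ch[v, 1L]] + sz[ch[v, 2L]]
  }
  sz
}

#' @rdname n_leaves
#' @export
vertex_depths <- function(tree) {
  d <- integer(tree$nv)
  for (v in preorder(tree)) {
    if (v != tree$root) d[v] <- d[tree$parent[v]] + 1L
  }
  d
}

#' @rdname n_leaves
#' @export
is_caterpillar <- function(tree, v = tree$root) {
  sz <- subtree_sizes(tree)
  ch <- tree$children
  stack <- v
  while (length(stack)) {
    w <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (ch[w, 1L] != 0L) {
      if (sz[ch[w, 1L]] > 1L && sz[ch[w, 2L]] > 1L) return(FALSE)
      stack <- c(stack, ch[w, ch[w, ] != 0L & sz[ch[w, ]] > 1L])
    }
  }
  TRUE
}

#' @rdname n_leaves
#' @export
is_two_caterpillar <- function(tree) {
  ch <- tree$children[tree$root, ]
  sz <- subtree_sizes(tree)
  abs(sz[ch[1L]] - sz[ch[2L]]) <= 1L &&
    is_caterpillar(tree, ch[1L]) && is_caterpillar(tree, ch[2L])
}

sibling_of <- function(tree, v) {
  p <- tree$parent[v]
  ch <- tree$children[p, ]
  if (ch[1L] == v) ch[2L] else ch[1L]
}

# Vertex ids of the subtree rooted at v.
subtree_vertices <- function(tree, v) {
  ch <- tree$children
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    w <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    out <- c(out, w)
    if (ch[w, 1L] != 0L) stack <- c(stack, ch[w, 1L], ch[w, 2L])
  }
  out
}

# First leaf child of v (0 if none).
leaf_child_of <- function(tree, v) {
  ch <- tree$children[v, ]
  if (ch[1L] == 0L) return(0L)
  leaves <- ch[tree$children[ch, 1L] == 0L]
  if (length(leaves)) leaves[1L] else 0L
}

#' @export
print.aff_tree <- function(x, ...) {
  cat("<aff_tree> rooted binary tree,", x$n, "leaves\n")
  s <- write_newick(x)
  if (nchar(s) > 70) s <- paste0(substr(s, 1, 67), "...")
  cat(" ", s, "\n")
  invisible(x)
}

# Structural sanity check used by tests.
validate_aff_tree <- function(tree) {
  stopifnot(tree$nv == 2L * tree$n - 1L,
            tree$parent[tree$root] == 0L,
            sum(tree$children[, 1L] == 0L) == tree$n,
            !anyDuplicated(stats::na.omit(tree$label)))
  for (v in seq_len(tree$nv)) {
    ch <- tree$children[v, ]
    if (xor(ch[1L] == 0L, ch[2L] == 0L)) stop("unary vertex ", v)
    for (c in ch[ch != 0L]) {
      if (tree$parent[c] != v) stop("parent/child mismatch at ", v)
    }
  }
  sz <- subtree_sizes(tree)
  stopifnot(sz[tree$root] == tree$n)
  invisible(TRUE)
}
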