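#' Incremental Cluster Affinity under NNI walks
#'
#' Computing `d(c, T)` from scratch is linear in the tree size, but along an
#' NNI walk only one target cluster changes per step: if the NNI prunes `v`
#' (parent `u`, old sibling `s`, parent's old sibling `x`), the cluster at `u`
#' changes from `c_v + c_s` to the disjoint union `c_v + c_x`, whose distance
#' to the source cluster is available in constant time as
#' \deqn{|c \Delta (c_v \cup c_x)| = d_v + d_x - |c|.}
#' Keeping the per-vertex distances `d_w = |c \Delta c_w|` in an updatable
#' min-heap therefore maintains `d(c, T_i)` in O(log n) per NNI after O(n)
#' preprocessing.
#'
#' `affinity_state()` builds that structure for one source cluster;
#' `apply_nni()` consumes the `"event"` produced by [nni()] (events must be
#' applied in order -- the state is versioned and rejects stale events);
#' `state_min()` returns the current `d(c, T_i)` in O(1).
#'
#' @param cluster Character vector of taxon labels (non-empty subset of the
#'   target's taxa).
#' @param target The initial target tree.
#' @param state An `affinity_state`.
#' @param event The `"event"` attribute of a tree produced by [nni()], or such
#'   a tree itself.
#' @return `affinity_state()`: an object of class `affinity_state`.
#'   `apply_nni()`: the updated state (states are mutable environments; the
#'   return value is the same object, invisibly).  `state_min()`: the current
#'   integer minimum.
#' @examples
#' t0 <- caterpillar_tree(4)
#' st <- affinity_state(c("1", "2"), t0)
#' state_min(st)  # 0: {1,2} is a cluster of C_4
#' t1 <- nni(t0, 1)
#' st <- apply_nni(st, t1)
#' state_min(st)  # 1
#' @export
affinity_state <- function(cluster, target) {
  target <- as_aff_tree(target)
  if (length(cluster) == 0L) stop("cluster must be non-empty")
  if (!all(cluster %in% target$taxa)) stop("taxon set mismatch")
  Ct <- cluster_matrix(target)
  ind <- as.numeric(target$taxa %in% cluster)
  d <- length(cluster) + rowSums(Ct) - 2 * as.vector(Ct %*% ind)
  st <- new.env(parent = emptyenv())
  st$csize <- length(cluster)
  st$heap <- heap_new(d)
  st$version <- 0L
  class(st) <- "affinity_state"
  st
}

#' @rdname affinity_state
#' @export
apply_nni <- function(state, event) {
  if (inherits(event, "aff_tree")) event <- attr(event, "event")
  if (is.null(event) || !identical(event$kind, "nni"))
    stop("event must come from an NNI operation")
  if (!is.null(event$step)) {
    if (event$step != state$version + 1L)
      stop("out-of-order update: tree version mismatch")
  }
  d_new <- heap_value(state$heap, event$v) + heap_value(state$heap, event$x) -
    state$csize
  heap_update(state$heap, event$u, d_new)
  state$version <- state$version + 1L
  invisible(state)
}

#' @rdname affinity_state
#' @export
state_min <- function(state) as.integer(heap_min(state$heap))

#' @export
print.affinity_state <- function(x, ...) {
  cat("<affinity_state> |c| =", x$csize, "; current min =", state_min(x),
      "; version", x$version, "\n")
  invisible(x)
}

# ---- indexed binary min-heap ----------------------------------------------
# Supports: build O(n), query-min O(1), update of any entry (increase or
# decrease) O(log n).  `key[i]` is the value of external index i; `heap` holds
# external indices, `pos` the inverse permutation.

heap_new <- function(values) {
  h <- new.env(parent = emptyenv())
  n <- length(values)
  h$key <- as.numeric(values)
  h$heap <- seq_len(n)
  h$pos <- seq_len(n)
  for (i in rev(seq_len(n %/% 2L))) heap_sift_down(h, i)
  h
}

heap_swap <- function(h, a, b) {
  ia <- h$heap[a]; ib <- h$heap[b]
  h$heap[a] <- ib; h$heap[b] <- ia
  h$pos[ia] <- b; h$pos[ib] <- a
}

heap_sift_up <- function(h, i) {
  while (i > 1L) {
    p <- i %/% 2L
    if (h$key[h$heap[i]] < h$key[h$heap[p]]) { heap_swap(h, i, p); i <- p }
    else break
  }
}

heap_sift_down <- function(h, i) {
  n <- length(h$heap)
  repeat {
    l <- 2L * i; r <- l + 1L
    m <- i
    if (l <= n && h$key[h$heap[l]] < h$key[h$heap[m]]) m <- l
    if (r <= n && h$key[h$heap[r]] < h$key[h$heap[m]]) m <- r
    if (m == i) break
    heap_swap(h, i, m)
    i <- m
  }
}

heap_update <- function(h, i, value) {
  old <- h$key[i]
  h$key[i] <- value
  if (value < old) heap_sift_up(h, h$pos[i]) else heap_sift_down(h, h$pos[i])
  invisible(h)
}

heap_value <- function(h, i) h$key[i]

heap_min <- function(h) h$key[h$heap[1L]]

heap_argmin <- function(h) h$heap[1L]

#' Track whole-tree costs along an NNI walk
#'
#' Maintains the CA cost (and the CS and one-sided RF costs, which share the
#' same per-cluster minima) from a fixed source tree `G` to every tree of an
#' NNI walk on the target.  Preprocessing builds the full matrix of distances
#' `d[c, w] = |c \Delta c_w|` between all source clusters and all target
#' vertices (one matrix product, O(n^2) entries); each NNI event then rewrites
#' exactly one column -- the constant-time update applied to every
#' source cluster at once -- and the per-step costs are re-read from row
#' minima.
#'
#' @param source The fixed source tree `G`.
#' @param target The initial target tree `T_0` (same taxa).
#' @param walk A walk as returned by [random_walk()] with `op = "nni"`, or a
#'   bare list of NNI events.
#' @return A tibble with one row per walk position: `step` (0-based), `ca`
#'   (= `ca_cost(G, T_step)`), `cs`, `rf`.
#' @examples
#' g <- caterpillar_tree(6)
#' w <- random_walk(balanced_tree(8), 0, "nni")  # empty walk
#' @export
tracked_tree_cost <- function(source, target, walk) {
  source <- as_aff_tree(source); target <- as_aff_tree(target)
  events <- if (!is.null(walk$events)) walk$events else walk
  D <- cost_matrix(source, target)
  sz <- subtree_sizes(source)
  k <- length(events)
  ca <- numeric(k + 1L); cs <- numeric(k + 1L); rf <- integer(k + 1L)
  read_costs <- function(i) {
    m <- row_mins(D)
    ca[i] <<- sum(m); cs[i] <<- sum(m / sz); rf[i] <<- sum(m > 0)
  }
  read_costs(1L)
  for (i in seq_len(k)) {
    ev <- events[[i]]
    if (!identical(ev$kind, "nni")) stop("tracked walks must consist of NNI events")
    D[, ev$u] <- D[, ev$v] + D[, ev$x] - sz
    read_costs(i + 1L)
  }
  tibble::tibble(step = 0:k, ca = ca, cs = cs, rf = rf)
}
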