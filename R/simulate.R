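#' Simulate a birth-death tree topology with a fixed number of extant taxa
#'
#' Forward simulation of the embedded jump chain of a birth-death process:
#' starting from a single lineage, each event is a speciation of a uniformly
#' chosen extant lineage with probability `birth / (birth + death)` and an
#' extinction of a uniformly chosen extant lineage otherwise.  The process
#' stops as soon as `n` lineages are extant; extinct lineages are then pruned
#' and unary vertices suppressed.  If the whole clade dies out the simulation
#' restarts (with advanced random state), which realizes the conditioning on
#' reaching `n` extant taxa.  Only the topology is produced -- the costs in
#' this package ignore branch lengths, and the embedded chain has the same
#' topology distribution as the continuous-time process stopped at its n-th
#' extant lineage.
#'
#' @param n Number of extant taxa (`n >= 2`).
#' @param birth,death Rates with `birth > death >= 0` (defaults 1.0 and 0.5).
#' @param seed Optional integer seed.
#' @param labels Leaf labels; default `"t1" .. "tn"`, assigned to the extant
#'   leaves in uniformly random order.  (Assigning them in lineage-creation
#'   order would correlate independently simulated trees -- early-created
#'   lineages would carry low labels in every tree -- so a pair of simulated
#'   trees would share far more clusters than a random pair should.)
#' @return An `aff_tree` with `n` leaves.
#' @examples
#' tr <- simulate_birth_death(10, seed = 1)
#' n_leaves(tr)
#' @export
simulate_birth_death <- function(n, birth = 1.0, death = 0.5, seed = NULL,
                                 labels = paste0("t", seq_len(n))) {
  if (n < 2) stop("n must be at least 2")
  if (!(birth > death && death >= 0)) stop("need birth > death >= 0")
  if (!is.null(seed)) set.seed(seed)
  p_birth <- birth / (birth + death)
  repeat {
    res <- bd_attempt(n, p_birth)
    if (!is.null(res)) break
  }
  build_pruned(res$parent[seq_len(res$k)], res$children[seq_len(res$k), , drop = FALSE],
               res$alive[seq_len(res$k)], sample(labels))
}

# One forward attempt; NULL on extinction before n extant lineages.
bd_attempt <- function(n, p_birth) {
  cap <- max(64L, 4L * n)
  parent <- integer(cap); children <- matrix(0L, cap, 2L)
  alive <- logical(cap)
  extant <- integer(cap)   # stack of extant vertex ids
  k <- 1L; alive[1L] <- TRUE
  extant[1L] <- 1L; ne <- 1L
  while (ne < n) {
    pick <- sample.int(ne, 1L)
    v <- extant[pick]
    if (stats::runif(1) < p_birth) {
      if (k + 2L > cap) {
        cap2 <- 2L * cap
        parent <- c(parent, integer(cap2 - cap))
        alive <- c(alive, logical(cap2 - cap))
        extant <- c(extant, integer(cap2 - cap))
        ch <- matrix(0L, cap2, 2L); ch[seq_len(cap), ] <- children
        children <- ch
        cap <- cap2
      }
      a <- k + 1L; b <- k + 2L; k <- b
      children[v, ] <- c(a, b)
      parent[a] <- v; parent[b] <- v
      alive[v] <- FALSE; alive[a] <- TRUE; alive[b] <- TRUE
      extant[pick] <- a
      ne <- ne + 1L; extant[ne] <- b
    } else {
      alive[v] <- FALSE
      extant[pick] <- extant[ne]; ne <- ne - 1L
      if (ne == 0L) return(NULL)
    }
  }
  list(parent = parent, children = children, alive = alive, k = k)
}

# Prune extinct lineages and suppress unary vertices; relabel extant leaves.
build_pruned <- function(parent, children, alive, labels) {
  k <- length(parent)
  keep <- logical(k)
  # postorder over creation order works: children always have larger ids
  for (v in k:1) {
    keep[v] <- if (children[v, 1L] == 0L) alive[v]
               else keep[children[v, 1L]] || keep[children[v, 2L]]
  }
  n <- sum(alive)
  nv <- 2L * n - 1L
  np <- integer(nv); nc <- matrix(0L, nv, 2L)
  lab <- rep(NA_character_, nv)
  env <- new.env(); env$k <- 0L; env$leaf <- 0L
  copy <- function(v) {  # v has keep[v]; returns new id of its reduced subtree
    while (children[v, 1L] != 0L) {
      kc <- c(keep[children[v, 1L]], keep[children[v, 2L]])
      if (all(kc)) break
      v <- children[v, which(kc)]    # suppress unary vertex
    }
    env$k <- env$k + 1L; id <- env$k
    if (children[v, 1L] == 0L) {
      env$leaf <- env$leaf + 1L
      lab[id] <<- labels[env$leaf]
    } else {
      a <- copy(children[v, 1L]); b <- copy(children[v, 2L])
      nc[id, ] <<- c(a, b)
      np[a] <<- id; np[b] <<- id
    }
    id
  }
  root <- copy(1L)
  new_aff_tree(n, root = root, parent = np, children = nc, label = lab)
}
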