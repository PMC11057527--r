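#' Cost distribution study on random birth-death tree pairs
#'
#' Generates `reps` independent pairs of birth-death trees on `n` taxa and
#' computes, for each pair, the one-sided RF distance, the asymmetric CA cost
#' in both directions, the CS cost (first to second tree) and the separation
#' cost.  The summary rescales each cost by its maximum observed value across
#' the sample (the study's normalization of record) and also reports
#' theoretical-diameter normalizations.
#'
#' @param n Taxa per tree (default 100).
#' @param reps Number of tree pairs (`reps >= 2`).
#' @param birth,death Birth-death rates (defaults 1.0 / 0.5).
#' @param seed Optional integer seed for end-to-end reproducibility.
#' @return An object of class `aff_study`: a list with
#'   * `pairs`: tibble of raw per-pair costs (`rf`, `ca`, `ca_rev`, `cs`,
#'     `separation`) plus observed-max-normalized columns (`*_norm`),
#'   * `summary`: tibble of mean/SD/median/min/max of the normalized costs,
#'   * `params`.
#'   [generics::tidy()] returns the summary, [generics::glance()] a one-row
#'   overview, [ggplot2::autoplot()] the distribution histograms.
#' @examples
#' st <- distribution_study(n = 20, reps = 20, seed = 1)
#' tidy(st)
#' @export
distribution_study <- function(n = 100, reps = 1000, birth = 1.0, death = 0.5,
                               seed = NULL) {
  if (reps < 2) stop("reps must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  rf <- integer(reps); ca <- numeric(reps); ca_rev <- numeric(reps)
  cs <- numeric(reps)
  for (i in seq_len(reps)) {
    t1 <- simulate_birth_death(n, birth, death)
    t2 <- simulate_birth_death(n, birth, death)
    D <- cost_matrix(t1, t2)
    m12 <- row_mins(D); m21 <- row_mins(t(D))
    sz1 <- subtree_sizes(t1)
    rf[i] <- sum(m12 > 0)
    ca[i] <- sum(m12)
    ca_rev[i] <- sum(m21)
    cs[i] <- sum(m12 / sz1)
  }
  sep <- abs(ca - ca_rev)
  pairs <- tibble::tibble(
    pair = seq_len(reps), rf = rf, ca = ca, ca_rev = ca_rev, cs = cs,
    separation = sep,
    rf_norm = rf / max(rf), ca_norm = ca / max(ca), cs_norm = cs / max(cs),
    separation_norm = sep / max(ca, ca_rev))
  summ <- dplyr::bind_rows(
    study_summary_row("rf", pairs$rf, n - 2),
    study_summary_row("ca", pairs$ca, ca_diameter(n)),
    study_summary_row("cs", pairs$cs, cs_diameter(n)),
    study_summary_row("separation", pairs$separation, ca_diameter(n),
                      norm = pairs$separation_norm))
  structure(list(pairs = pairs, summary = summ,
                 params = list(n = n, reps = reps, birth = birth,
                               death = death, seed = seed)),
            class = "aff_study")
}

study_summary_row <- function(cost, raw, diameter, norm = raw / max(raw)) {
  tibble::tibble(
    cost = cost,
    mean = mean(norm), sd = stats::sd(norm), median = stats::median(norm),
    min = min(norm), max = max(norm),
    mean_diam = mean(raw) / diameter,
    normalization = "observed-max")
}

#' @export
print.aff_study <- function(x, ...) {
  cat("<aff_study>", x$params$reps, "birth-death tree pairs, n =",
      x$params$n, "\n")
  print(x$summary)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.aff_study <- function(x, ...) x$summary

#' @export
glance.aff_study <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n = x$params$n, reps = x$params$reps,
    mean_rf = s$mean[s$cost == "rf"], mean_ca = s$mean[s$cost == "ca"],
    mean_cs = s$mean[s$cost == "cs"],
    mean_separation = s$mean[s$cost == "separation"])
}

#' Separation-cost statistics of a random-pair sample
#'
#' `separation_summary()` condenses the separation costs of an existing
#' [distribution_study()]; `separation_study()` runs the simulation and the
#' summary in one call.  Separation is normalized by the maximum CA cost
#' observed in the sample (over both directions).
#'
#' @param study An `aff_study`.
#' @inheritParams distribution_study
#' @return A one-row tibble: `mean`, `sd`, `median`, `max` of the normalized
#'   separation cost, plus `max_raw` and the sample size.
#' @export
separation_summary <- function(study) {
  s <- study$pairs$separation_norm
  tibble::tibble(mean = mean(s), sd = stats::sd(s),
                 median = stats::median(s), max = max(s),
                 max_raw = max(study$pairs$separation),
                 reps = nrow(study$pairs))
}

#' @rdname separation_summary
#' @export
separation_study <- function(n = 100, reps = 1000, birth = 1.0, death = 0.5,
                             seed = NULL) {
  separation_summary(distribution_study(n, reps, birth, death, seed))
}

#' Robustness of the costs to accumulating tree edits
#'
#' Generates `num_trees` random birth-death start trees; from each, a seeded
#' random walk of `walk_len` NNI or SPR edits.  At every step the one-sided
#' RF, CA and CS costs from the start tree to the walked tree are computed --
#' incrementally via [tracked_tree_cost()] for NNI walks, from scratch for SPR
#' walks -- normalized, and averaged over the start trees.  The RF distance
#' saturates after a handful of edits while CA and especially CS grow slowly:
#' they are the more robust signals of genuine topological difference.
#'
#' @param num_trees Number of start trees (default 100).
#' @param n Taxa per tree (default 100).
#' @param walk_len Walk length; defaults to `2 * n` edits.
#' @param op `"nni"` or `"spr"`.
#' @param seed Optional integer seed.
#' @param birth,death Birth-death rates.
#' @param normalize `"diameter"` (RF by `n - 2`, CA and CS by their exact
#'   diameters) or `"observed-max"` (each cost by its maximum across the whole
#'   study).
#' @return An object of class `aff_robustness`: a list with `curve` (tibble:
#'   `step`, `cost`, `mean`) and `params`.  `tidy()` returns the curve,
#'   `autoplot()` plots it.
#' @examples
#' rb <- robustness_study(num_trees = 3, n = 20, walk_len = 5, seed = 1)
#' tidy(rb)
#' @export
robustness_study <- function(num_trees = 100, n = 100, walk_len = 2 * n,
                             op = c("nni", "spr"), seed = NULL,
                             birth = 1.0, death = 0.5,
                             normalize = c("diameter", "observed-max")) {
  op <- match.arg(op); normalize <- match.arg(normalize)
  if (walk_len < 1) stop("walk_len must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  acc <- list(rf = matrix(0, num_trees, walk_len + 1L),
              ca = matrix(0, num_trees, walk_len + 1L),
              cs = matrix(0, num_trees, walk_len + 1L))
  for (i in seq_len(num_trees)) {
    t0 <- simulate_birth_death(n, birth, death)
    wk <- random_walk(t0, walk_len, op)
    costs <- if (op == "nni") {
      tracked_tree_cost(t0, t0, wk)
    } else {
      steps <- lapply(wk$trees, function(tt) {
        m <- row_mins(cost_matrix(t0, tt))
        c(ca = sum(m), cs = sum(m / subtree_sizes(t0)), rf = sum(m > 0))
      })
      m <- do.call(rbind, steps)
      tibble::tibble(step = 0:walk_len, ca = m[, "ca"], cs = m[, "cs"],
                     rf = m[, "rf"])
    }
    acc$rf[i, ] <- costs$rf; acc$ca[i, ] <- costs$ca; acc$cs[i, ] <- costs$cs
  }
  div <- switch(normalize,
    "diameter" = c(rf = n - 2, ca = ca_diameter(n), cs = cs_diameter(n)),
    "observed-max" = c(rf = max(acc$rf), ca = max(acc$ca), cs = max(acc$cs)))
  curve <- dplyr::bind_rows(lapply(c("rf", "ca", "cs"), function(k) {
    tibble::tibble(step = 0:walk_len, cost = k,
                   mean = colMeans(acc[[k]]) / div[[k]])
  }))
  structure(list(curve = curve,
                 params = list(num_trees = num_trees, n = n,
                               walk_len = walk_len, op = op, seed = seed,
                               birth = birth, death = death,
                               normalize = normalize)),
            class = "aff_robustness")
}

#' @export
print.aff_robustness <- function(x, ...) {
  cat("<aff_robustness>", x$params$num_trees, "start trees, n =", x$params$n,
      ",", x$params$walk_len, toupper(x$params$op), "steps\n")
  print(utils::head(x$curve))
  invisible(x)
}

#' @export
tidy.aff_robustness <- function(x, ...) x$curve

#' @export
glance.aff_robustness <- function(x, ...) {
  last <- x$curve[x$curve$step == max(x$curve$step), ]
  tibble::tibble(op = x$params$op, n = x$params$n,
                 walk_len = x$params$walk_len,
                 final_rf = last$mean[last$cost == "rf"],
                 final_ca = last$mean[last$cost == "ca"],
                 final_cs = last$mean[last$cost == "cs"])
}
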