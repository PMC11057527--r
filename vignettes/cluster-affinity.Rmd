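---
title: "Asymmetric cluster-based comparison of rooted phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymmetric cluster-based comparison of rooted phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affinitree)
```

## The costs

A rooted binary phylogeny $T$ over a taxon set $M$ ($|M| = n$) is determined
by its $2n-1$ *clusters* — the leaf sets below each vertex, including the $n$
singletons and the root cluster $M$ (the *trivial* clusters).  The classic
one-sided Robinson–Foulds distance counts the clusters of a source tree $G$
that are absent from a target tree $S$.  It is brutally binary: a cluster one
taxon short of a match counts the same as a completely alien one, which is why
RF saturates after a handful of rearrangements and why almost every pair of
random trees sits at its maximum.

The **Cluster Affinity (CA) cost** replaces the presence/absence test by the
cheapest edit:

$$d(G,S) \;=\; \sum_{c \in C(G)} \min_{x \in C(S)} |c \,\Delta\, x|,$$

where $\Delta$ is the symmetric difference.  Each source cluster pays for its
nearest counterpart rather than for not having an exact twin.  The cost is
deliberately *asymmetric* — comparing a gene tree to a species tree, an
estimate to a ground truth, or input trees to a supertree are directional
questions — and mapping to trivial target clusters is allowed (a singleton
inside $c$ or the root cluster is always available, capping each term at
$\tau_G(c) = \min(|c| - 1,\; n - |c|)$).

The **Cluster Support (CS) cost** divides each term by the source cluster's
own size,

$$d'(G,S) \;=\; \sum_{c \in C(G)} \frac{\min_{x \in C(S)} |c \Delta x|}{|c|},$$

so that every cluster contributes a *fractional* mismatch in $[0,1)$: a 5%
disagreement in a 500-taxon clade no longer drowns out a 40% disagreement in
a 10-taxon clade.  `cs_normalized()` further divides by $|C(G)| = 2n-1$,
making the value a mean per-cluster support; a flag offers division by the
$n-2$ non-trivial clusters instead, since trivial source clusters always
contribute zero and dilute the average.

The **separation cost** $\sigma(G,S) = |d(G,S) - d(S,G)|$ quantifies how
directional a comparison is.  None of these costs is a metric; no triangle
inequality is claimed or used.

## Diameters and the extremal constructions

Costs are only comparable across studies after normalization, which requires
the *diameter* — the maximum value over all tree pairs on $n$ taxa.

* The CA diameter is $\lceil (n^2-2n)/4 \rceil$, which is $\tau(T^\ast) =
  \sum_v \tau(v)$ of a caterpillar $T^\ast$.  `caterpillar_tree(n)` against
  `reversed_caterpillar_tree(n)` attains it: in the reversed caterpillar every
  non-trivial cluster is a suffix set, so each prefix cluster of the plain
  caterpillar is $\tau$-far from everything.
* The CS diameter is $n - H_{\lceil n/2 \rceil} - H_{\lfloor n/2 \rfloor}$
  (harmonic numbers), which is $\phi(D_n) = \sum_v \tau(v)/|c_v|$ of the
  balanced 2-caterpillar `two_caterpillar_tree(n)`.

The package verifies both diameters *exhaustively* for $n = 4, 5, 6$
(`max_costs_exhaustive()`, $945^2$ ordered pairs at $n=6$) and via the
constructions up to $n = 128$.

The CS maximizing *target* deserves a note, because the construction is
genuinely under-determined by the shape alone.  A 2-caterpillar target with
the *same* taxa in corresponding halves contains $D_n$'s half-root clusters
at distance 0, so it cannot realize $\phi(D_n)$.  The first labeling we tried
— odd taxa in one half, even in the other — also fails from $n = 6$ on: the
even half's deepest cherry $\{4,6\}$ sits inside $D_6$'s cluster $\{4,5,6\}$
at distance 1, below its $\tau$ value of 2.  `crossed_two_caterpillar_tree()`
therefore interleaves *balanced pairs*: the sequence $1, n, 2, n-1, \dots$
(middle taxon last when $n$ is odd) is cut into two caterpillar halves,
deepest cherry first.  Every cluster $x$ of that tree then contains at most
$(|x|+1)/2$ taxa of any prefix $\{1..j\}$ or suffix $\{n-j+1..n\}$, so
$|c \Delta x| = |c| + |x| - 2|c \cap x| \ge |c| - 1 \ge \tau(c)$ for every
cluster $c$ of $D_n$, and the singleton bound is attained.  The equality
$d'(D_n, \bar D_n) = \phi(D_n)$ is brute-force-checked for $n = 4\ldots 12$
in the tests.  The same pairing idea underlies the balanced-tree labeling
(`balanced_tree(n)`, cherries $\{i, n-i+1\}$ in prefix order), which makes
$d(C_n, P_n) = \tau(C_n)$ and powers the $\Theta(n^2)$ separation diameter:
$\tau$ of a balanced tree is only $n \log_2 n - 2n + 2$ (the per-level sum
$\sum_{h=1}^{m-1} (2^h - 1)\, 2^{m-h}$; e.g. 10 at $n = 8$ — this is the
value the implementation computes and the tests pin down), so
$\sigma(C_n, P_n) \ge \lceil (n^2-2n)/4 \rceil - (n \log_2 n - 2n + 2)$.

## Transformation rules and why they terminate

The diameter proofs are algorithmic, and the package implements them as real
operations.  `caterpillar_extend()` merges two caterpillar child subtrees one
NNI at a time and never lowers $\tau$; `caterpillar_swap()`,
`caterpillar_split()` and `caterpillar_balance()` are the constrained moves
that never lower $\phi$.  `apply_rules_to_fixpoint()` drives any tree to a
balanced 2-caterpillar through five precondition-guarded rules; each
application raises $\phi$ by more than $1/n^2$, so a maximal sequence has at
most $(2n-1)\,n^2$ steps.  The engine applies the lowest-numbered applicable
rule at the shallowest qualifying vertex (ties by vertex id), one operation at
a time, re-scanning between operations; any maximal sequence reaches the same
$\phi$, so the deterministic order is purely for reproducibility.  Within a
rule-1 region the extend site is the *deepest* qualifying vertex, which makes
the subtree caterpillar bottom-up.  The tests check, over all 945 six-taxon
trees, that a rule applies exactly when the tree is not yet a balanced
2-caterpillar, that every application clears the $1/n^2$ bar, and that every
fixpoint hits the CS diameter.

## Incremental cost tracking under NNI

An NNI changes exactly one cluster of the tree: pruning $v$ (parent $u$, old
sibling $s$, parent's sibling $x$) replaces $c_u = c_v \cup c_s$ by
$c_v \cup c_x$.  Because the union is disjoint,

$$|c \,\Delta\, (c_v \cup c_x)| = d_v + d_x - |c|,$$

a constant-time update of the one stale entry among the per-vertex distances
$d_w = |c \Delta c_w|$.  `affinity_state()` keeps those distances in a
hand-written *indexed binary min-heap* (query-min $O(1)$, update — increase
or decrease — $O(\log n)$), so $d(c, T_i)$ follows an NNI walk at $O(\log n)$
per step after $O(n)$ preprocessing.  `tracked_tree_cost()` applies the same
update vectorised across *all* source clusters in a distance matrix (one
column rewritten per step, row minima re-read at C level), which also yields
the CS cost ($|c|$ is walk-invariant, so dividing the minima at query time
suffices) and the one-sided RF (a cluster is present iff its minimum is 0).
Both paths are cross-checked against from-scratch recomputation at every step
of every tested walk; SPR changes $O(n)$ clusters, so SPR walks recompute.

Edit operations keep vertex ids stable (the suppressed vertex's id is reused
for the created one) and states are versioned, so replaying events out of
order fails loudly instead of drifting.

## The simulator and the study pipelines

`simulate_birth_death()` draws the *embedded jump chain* of a birth–death
process: each event is a speciation with probability
$\lambda/(\lambda+\mu)$, else an extinction, on a uniformly chosen extant
lineage; the process stops at the first moment $n$ lineages are extant,
extinct lineages are pruned, and total extinction restarts the attempt.
Because every cost in the package is topology-only, waiting times are not
simulated — the embedded chain has exactly the topology law of the
continuous-time process stopped at its $n$-th extant lineage.  Defaults are
$\lambda = 1.0$, $\mu = 0.5$.  Leaf labels are attached in *uniformly random*
order; attaching them in lineage-creation order would correlate independently
simulated trees and roughly halve the apparent RF distance between random
pairs.  The generator emulates tree *shape* under a neutral diversification
null; it does not emulate branch lengths, taxon sampling biases, or any
signal-driven correlation between the two trees of a pair, so matching its
statistics says nothing about costs on trees estimated from real alignments.

`distribution_study(n, reps)` simulates independent tree pairs and tabulates
one-sided RF, CA (both directions), CS and separation;
`robustness_study()` follows seeded NNI/SPR walks from random start trees and
averages the three costs per step (incremental tracking for NNI).  Summaries
rescale each cost by its maximum *observed* value across the sample, with
theoretical-diameter normalization reported alongside.  A caution that our
own reproduction surfaced: the observed maximum is an extreme-value
statistic, so any mean normalized by it inherits the max's sampling noise —
at 100 taxa the normalized CA mean drifts by several percent between
replicate batches of a few hundred versus ten thousand pairs even though the
underlying raw distribution is stable to three digits.  Diameter
normalization is free of that artifact but makes CA look tiny (random pairs
sit near $0.2$ of the quadratic diameter).  Both normalizations are exposed;
comparisons across studies should state which one they use.

Random-edit sample spaces (not fixed by the description of the walks): NNI
steps are uniform over the vertices where NNI is defined (non-root, non-root
parent); SPR steps are uniform over valid prune/regraft *pairs*, excluding
the two regrafts that recreate the same tree.  Walk length defaults to $2n$.

## Numerical choices

* CA, RF, $\tau$ and all per-cluster minima are integers computed exactly
  (the pairwise distance matrix is one 0/1 matrix product).
* CS and $\phi$ are sums of fractions with denominators $\le n$; they are
  accumulated in doubles, and identity tests compare at $10^{-12}$.  The CS
  diameter is also available as an exact reduced fraction
  (`cs_diameter_exact()`), computed with gcd-reduced integer-valued doubles
  and overflow-checked against $2^{53}$ (fine up to roughly $n = 80$).
* Minimization scans all $2n-1$ target clusters; only the minimum is
  returned, so no tie-break is needed.  `affinity_profile(argmin = TRUE)`
  reports *all* minimizers in vertex order.
* Degenerate sizes: the two-leaf tree has $\tau = \phi = 0$ and both
  diameters 0; normalized quantities guard their denominators ($n \ge 3$ for
  RF's $n-2$, $n \ge 4$ for the 2-caterpillar constructions).
* Row minima use `max.col(-D, ties.method = "first")` — deterministic and
  independent of the RNG state, so seeded studies are bit-reproducible.

## Problem sizes used by the test-suite studies

Exact theory is verified at desk scale: exhaustive diameters for
$n \in \{4,5,6\}$, construction identities to $n = 128$, rule properties over all
945 six-taxon trees, incremental tracking on twenty 100-step walks at
$n = 50$.  The stochastic reproductions run 2,000 pairs at $n = 100$ for the
distribution and separation tables (the acceptance script uses 10,000, plus
100 pairs at $n = 1000$) and one hundred 30-step walks per operation for the
robustness curves.  These sizes were chosen so the whole suite stays
comfortably re-runnable while keeping Monte-Carlo error well below the
effects being tested.

## Known limitations

* Rooted, strictly binary trees over identical taxon sets only; polytomies
  and unequal leaf sets are rejected, not resolved.
* The quadratic all-pairs algorithm is the intended engine here (it is also
  what the incremental structure needs to warm-start); the asymptotically
  faster $O(n \log^3 n)$ static computation is out of scope.
* Incremental updates cover NNI only; SPR edits change $O(n)$ clusters and
  trigger recomputation.
* CA/CS are costs, not metrics; do not feed them to methods that assume the
  triangle inequality.
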