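# affinitree

Asymmetric, cluster-based comparison of rooted phylogenies in R.

Phylogenomic comparisons are frequently *directional*: a gene tree is judged
against a species tree, an estimated tree against a simulation's ground
truth, input trees against a supertree.  The standard Robinson–Foulds (RF)
distance is symmetric, saturates after a handful of rearrangements, and
treats a near-miss cluster the same as a completely alien one.  `affinitree`
implements the asymmetric **Cluster Affinity (CA)** cost and the
size-normalized **Cluster Support (CS)** cost, which grade cluster mismatches
instead of thresholding them, together with everything needed to use them in
practice: exact diameters for normalization, the extremal trees that attain
them, NNI/SPR edit operations, an incremental structure that follows CA/CS/RF
along NNI walks in logarithmic time per step, a birth–death topology
simulator, and tidy study pipelines.

For trees `G`, `S` over the same taxa, with `C(T)` the cluster set of `T`
(all 2n−1 clusters, trivial ones included):

- CA cost: `d(G,S) = Σ_{c ∈ C(G)} min_{x ∈ C(S)} |c Δ x|`
- CS cost: `d'(G,S) = Σ_{c ∈ C(G)} min_{x ∈ C(S)} |c Δ x| / |c|`
- one-sided RF: `|{c ∈ C(G) : c ∉ C(S)}|`
- separation: `σ(G,S) = |d(G,S) − d(S,G)|`
- diameters: `max CA = ⌈(n²−2n)/4⌉`; `max CS = n − H_⌈n/2⌉ − H_⌊n/2⌋`
  (harmonic numbers), both attained by explicit constructions shipped in the
  package and verified exhaustively at small n in the tests.

## A worked example

```r
library(affinitree)

g <- caterpillar_tree(8)   # (8,(7,(6,(5,(4,(3,(2,1)))))));
s <- balanced_tree(8)      # cherries (1,8),(2,7),(3,6),(4,5)
tree_comparison(g, s)
#>   cost       direction  value diameter normalized
#> 1 ca         a->b      12.000   12.000     1.0000
#> 2 ca         b->a       8.000   12.000     0.6667
#> 3 ca_sym     sym       10.000   12.000     0.8333
#> 4 cs         a->b       2.993    3.833     0.7807
#> 5 cs         b->a       3.000    3.833     0.7826
#> 6 rf         a->b       6.000    6.000     1.0000
#> 7 rf         b->a       6.000    6.000     1.0000
#> 8 separation sym        4.000   12.000     0.3333
```

Read the rows as follows.  RF is already at its maximum in *both* directions
— all six non-trivial clusters differ — so it cannot tell us anything finer.
CA from the caterpillar to the balanced tree is 12, the exact CA diameter for
eight taxa (this pair is the extremal construction), while the reverse
direction costs only 8: the asymmetry (separation 4, a third of the diameter)
reflects that a caterpillar's nested clusters are maximally far from
everything, whereas the balanced tree's small balanced clusters always find
nearby matches.  CS tells the per-cluster story: each cluster of `g` is on
average ~78% of the way to its worst case.

Simulation studies are one-liners returning tidy objects:

```r
st <- distribution_study(n = 50, reps = 200, seed = 7)
tidy(st)
#>   cost       mean     sd      median min   max  mean_diam
#> 1 rf         0.9952 0.00903 1.0000  0.958 1.00  0.9952
#> 2 ca         0.8211 0.06428 0.8193  0.687 1.00  0.3407
#> 3 cs         0.9280 0.02791 0.9298  0.840 1.00  0.7409
#> 4 separation 0.0719 0.05140 0.0627  0.000 0.24  0.0315
autoplot(st)                       # cost histograms
rb <- robustness_study(num_trees = 20, n = 50, walk_len = 30, op = "nni",
                       seed = 7, normalize = "observed-max")
autoplot(rb)                       # mean cost vs. accumulated edits
```

Random tree pairs sit at the RF ceiling (mean 0.995 of the observed maximum;
the median pair is *at* the maximum), while CA spreads far more broadly
(SD 0.064 vs 0.009) — the resolution argument for CA/CS in one table.  The
separation column says CA's two directions differ by ~7% of the largest
observed CA on average: asymmetry is the rule, not the exception, even
between exchangeable random trees.

A thin command-line wrapper (`exec/affinitree`) exposes the same operations
(`compare`, `diameter`, `make`, `simulate`, `robustness`, `walk`) with TSV
output and a plain-text run manifest; see `?aff_cli_run`.

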