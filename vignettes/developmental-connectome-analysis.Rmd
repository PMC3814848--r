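---
title: "Graph-theoretical analysis of developmental white-matter networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretical analysis of developmental white-matter networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devconnectome)
```

## The analysis

`devconnectome` implements a complete analysis chain for weighted structural
brain networks across developmental age groups: per-subject connectome
construction from tractography summaries, group-level backbone extraction,
weighted graph metrics with matched null models, module detection with hub
classification, and covariate-adjusted statistics between adjacent age
groups. A synthetic cohort generator reproduces the statistical structure
such data typically has, so every stage of the chain can be exercised and
tested without imaging data.

The intended input per subject is a pair of region-by-region matrices from
deterministic whole-brain tractography on a cortical parcellation with
`N = 78` regions (39 per hemisphere): the streamline count `FN_ij` between
regions i and j, and the mean fractional anisotropy `FA_ij` of the
connecting streamlines, plus the regional volumes.

## Network construction

Two regions are treated as connected only when at least `fn_threshold = 10`
streamlines join them; sparser connections are likely tractography noise.
The weight of a retained connection is

    w_ij = FN_ij * FA_ij / ((V_i + V_j) / 2),

the fiber count scaled by the tract's microstructural integrity and
normalized by the mean volume of the two regions, because larger regions
inherently send and receive more streamlines. The volume denominator is the
arithmetic mean of the two regional volumes. Each subject's network is then
divided by its mean nonzero edge weight (`normalize_by_mean_weight()`), so
all subjects sit at the same total cost and topological differences, not
global weight scale, drive the metrics. The normalization averages over
*existing* edges only; averaging over all possible pairs would re-introduce
a sparsity dependence, which is exactly what the step is meant to remove.

## Group backbones

A group of subjects is summarized by a *backbone network*
(`build_backbone()`): for each region pair, the number of subjects
possessing the edge is tested against the null hypothesis that the
connection does not exist, under which a subject shows it with probability
1/2. The test is the exact one-sided sign test,

    p = P(X >= k),  X ~ Binomial(n, 1/2),

computed from the exact binomial distribution — no normal approximation —
and Bonferroni-corrected over all `N(N-1)/2 = 3003` possible edges at
`alpha = 0.05`. Retention uses `<=` on the corrected threshold. At
`n = 36` subjects the smallest retained presence count is 31. A retained
edge's backbone weight is the mean weight over only the subjects that
possess it. One practical consequence worth knowing: below about 14
subjects (at 30 regions) even an always-present edge cannot reach the
Bonferroni threshold, so backbones of very small groups are empty by
construction.

## Weighted graph metrics

All metrics operate on the normalized weighted network.

* **Distances.** An edge's length is `1/w_ij`, so strong connections are
  short, and `d_ij` is the shortest weighted path length (Dijkstra).
  Without the inverse mapping, efficiency would *decrease* as connections
  strengthen, which would invert the developmental interpretation.
* **Strength.** `S = (1/N) sum_{i != j} w_ij`, the mean nodal strength.
  An alternative reading ("mean weight per edge", `sum w / K`) is exposed
  through `total_strength(G, per = "edge")` but is not the default.
* **Clustering.** The Onnela triangle-intensity form: weights are first
  scaled by the network's maximum weight, and
  `CC_i = sum_{(j,k)} (w_ij w_jk w_ik)^{1/3} / (k_i (k_i - 1) / 2)` over
  unordered neighbor pairs. Max-scaling keeps `CC` in [0, 1]; without it,
  mean-normalized networks can exceed 1. Nodes with fewer than two
  neighbors score 0.
* **Path length and efficiency.** `E_glob` is the mean inverse distance
  over ordered pairs with disconnected pairs contributing 0, and
  `L = 1/E_glob` (harmonic-mean distance). The harmonic convention exists
  precisely to keep disconnected node pairs from dominating; `L * E_glob
  = 1` is definitional and asserted in the tests. `E_loc` averages the
  global efficiency of each node's neighbor subgraph (node excluded,
  original weights kept). `E_nodal(i)` is the mean inverse distance from
  node i to all others.
* **Hubs.** A node is a hub when its nodal efficiency is at least one
  sample standard deviation (n - 1 denominator) above the network mean;
  `>=` is used, and a degenerate all-equal vector yields no hubs.

## Null models and small-worldness

Matched random networks are generated by Maslov–Sneppen double-edge swaps
(`rewire_maslov_sneppen()`): two edges (a,b), (c,d) are replaced by (a,d),
(c,b) unless a self-loop or duplicate would result. Each null uses
`10 * K` successful swaps, a standard mixing heuristic, with a proposal cap
of 100 per requested swap. Weights travel with the swapped edges, so the
degree sequence, the edge count, *and the multiset of edge weights* (hence
total strength) are preserved exactly while topology is randomized. The
reference literature specifies degree-matched nulls but is silent on weight
handling; carrying weights along is the convention adopted here and is
asserted exactly in the tests.

Small-worldness compares clustering and path length against the null
ensemble: `gamma = CC/CC_rand`, `lambda = L/L_rand`, and the summary ratio
`sigma = gamma/lambda`. The default ensemble size is 1000; the test-suite
uses 100 to keep runtimes sensible, which is plenty to rank an
Erdős–Rényi-like graph (`sigma ~ 1`) against a rewired ring lattice
(`sigma > 1.5`).

## Modules, participation, connector hubs

Weighted modularity of a partition p is

    Q(p) = sum_s [ w_s / W - (W_s / (2W))^2 ],

with `W` the total edge weight, `w_s` the intra-module weight and `W_s`
the summed strengths of module s. `greedy_modularity()` maximizes Q by
agglomeration: starting from singletons, each step merges the connected
module pair with the largest *size-normalized* gain `dQ / a_s`, where
`a_s = W_s/(2W)` of the lower-strength module of the pair. The
normalization (Danon-style) counteracts the plain greedy algorithm's bias
toward merging small modules into large ones; which module's `a_s`
normalizes the gain is not fixed by the literature, and the lower-strength
choice is this package's documented convention. Ties break on the lowest
module-index pair, so the algorithm is deterministic given node order.
The returned partition is the one along the merge path with maximal
*plain* Q, so the reported Q remains the standard quantity. Merging stops
when no connected module pair remains; with a disconnected network the Q
maximum always lies before that point.

The participation coefficient `P_i = 1 - sum_s (w_is / w_i)^2` includes
the node's own module in the sum, so a purely intra-modular node scores
exactly 0 and a node spreading evenly over all `N_M` modules approaches
`1 - 1/N_M`. Connector hubs apply the same one-SD rule to PC.

For cross-group comparability, `match_sparsity()` trims networks to a
common sparsity by deleting the weakest edges first (ties broken by edge
index), and the pipeline reports backbone modularity both raw and at the
lowest group sparsity.

## Group statistics

Between each pair of *adjacent* age groups, every metric is tested with an
ordinary least-squares model `value ~ 1 + group + age + sex` (QR
factorization; two-sided t on `n - 4` df). Age and sex enter as nuisance
covariates: groups span several years, so the within-group age spread is
real signal that should not masquerade as a group effect. The exact design
of such an adjacent-group GLM is underdetermined; this simple four-column
form is the package's documented reading, and centering age or recoding
sex leaves the group test unchanged (asserted). A rank-deficient design
(e.g. age perfectly separating the groups) fails with the collinear column
named; a response with zero residual variance returns `NA` rather than a
spurious verdict.

Global metrics are reported at the raw p-value. Nodal metrics are
corrected by Benjamini–Hochberg FDR at `q = 0.05`, with the family being
the 78 regions within one (metric, transition) cell — matching how
regional results are normally reported per transition.

## The synthetic cohort generator

`generate_cohort()` emulates the *statistical* structure of a
developmental tractography cohort; it simulates no imaging and no spatial
geometry. Its defaults are the study conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `n_groups`, `n_per_group` | 5, 36 | age groups and subjects per group |
| `n_regions`, `n_modules` | 78, 6 | nodes and planted modules (13 each) |
| `p_in`, `p_out` | 0.55, 0.035 | intra/inter-module template connection probability; yields template sparsity ~0.115 with ~74% of edges intra-modular |
| `sparsity_span_factor` | 1.2 | oldest/youngest expected sparsity ratio |
| `fn_span_factor` | 1.6 | oldest/youngest expected total fiber count ratio |
| `fn_mean`, `fn_dispersion` | 60, 3 | negative-binomial fiber counts per present edge |
| `fa_young`, `fa_old` | 0.40, 0.48 | group-mean tract FA endpoints; per-edge FA is normal (sd 0.06) truncated to [0.2, 0.9] |
| `hub_fraction` | 0.10 | nodes with boosted inter-module connectivity (x1.5) and fiber counts (x1.5) |
| `edge_consistency` | 0.97 | probability a template connection appears in a subject |
| `age_ranges` | five intervals spanning 6.0–29.7 y | uniform age sampling per group |
| `sex_ratio` | 0.5 | Bernoulli sex assignment |

Design notes, in the order they matter:

* **Anatomy as a nested template.** Each group has one anatomical template
  drawn from a planted-partition model; groups share a single matrix of
  uniforms, so as the sparsity factor grows with age, older groups *add*
  connections instead of reshuffling them. Each subject then expresses a
  template edge with probability `edge_consistency`. The value 0.97 was
  chosen so that, combined with the fiber-count floor, the effective
  per-subject presence probability of a template edge (~0.95) keeps the
  sign-test backbone essentially equal to the template at n = 36.
* **Fiber counts.** Present edges draw `FN = 1 + NB(mu, size)`.
  Negative-binomial overdispersion mimics streamline-count variability;
  the distribution family is a package choice since only qualitative
  trends are documented for such data. The per-group NB mean scales by
  `fn_span_factor / sparsity_span_factor`, so the *total* fiber count
  (mean count x edge count) grows by `fn_span_factor` overall.
* **FA truncation** to [0.2, 0.9] mirrors the usual FA-0.2 tracking floor
  and the physical bound FA < 1.
* **Volumes** are log-normal around region-level base volumes (cohort
  level, sdlog 0.3) with small per-subject variation (sdlog 0.08).
* **Ages** are uniform within each group's range — the least-committal
  choice when only ranges and means are known. **Sex** is independent
  Bernoulli; typical cohorts are near-balanced.

### Programmed group effects

`effect_map` plants group differences in specific metrics, e.g.

```r
em <- list(list(metric = "E_glob", transition = 1, delta = 0.10),
           list(metric = "Q",      transition = 1, delta = -0.10),
           list(metric = "E_loc",  transition = 2, delta = 0.10))
```

programs a +10% global-efficiency shift and a -10% modularity shift from
the second group onward and a +10% local-efficiency shift from the third
group onward. Internally three generator knobs implement this: the
inter-module connection propensity (integration), the intra-module
propensity (segregation density), and an intra-module fiber-count
multiplier (segregation weight). A single metric cannot be moved by a
single knob without disturbing the others — integration and segregation
metrics are inherently coupled — so programmed deltas are translated into
knob settings through the inverse of a fixed 3x3 sensitivity matrix
(relative metric change per unit knob). That matrix was estimated by
simulation at the default design and then refined at the two operating
points used above until residual cross-talk on the non-programmed metrics
fell below ~0.2%; it is frozen in the code and documented here as part of
the generator's design. Because the mapping is a local linearization, very
large deltas (beyond roughly ±15%) or non-default topology parameters
will realize programmed effects only approximately.

Two details matter for statistical cleanliness. First, knob-driven
topology changes are applied *per subject* (each subject independently
gains or drops the marginal connections), not to the group template:
a single template draw would carry sampling noise of its own into the
group contrast, and the downstream GLM — which treats subjects as the
unit of evidence — would flag that noise as real. Second, effects are
cumulative across transitions, matching the "shift and level off"
developmental pattern the pipeline is designed to detect.

### What the generator does not emulate

No spatial embedding or distance-dependent connectivity, no hemispheric
symmetry beyond labels, no anatomically meaningful module content, no
scanner or registration artifacts, and no dependence of FA on age at the
*edge* level (only group means shift). Passing tests therefore demonstrate
that the pipeline recovers the statistical structure it assumes — not that
it would be robust to every artifact of real tractography data.

## Numerical choices and degenerate inputs

* Sparsity matching computes the target edge count as
  `floor(target * N(N-1)/2 + 1e-9)`; the epsilon guards against a binary
  representation of the target pushing the floor one edge low.
* The greedy merge accepts a new best partition only when Q improves by
  more than 1e-12, keeping the merge path deterministic under floating
  noise.
* `identify_hubs()` on a zero-variance vector returns the empty set; the
  sign test at `k = 0` returns exactly 1; empty networks are rejected by
  `normalize_by_mean_weight()` (an unusable subject is an error, not a
  silent zero).
* Rewiring draws proposals in blocks for speed but is sequentially
  deterministic given the seed; a stalled run (e.g. a triangle, which
  admits no legal swap) returns the current state with a warning and an
  `"incomplete"` attribute.

## Problem sizes in the test-suite

The suite exercises oracle comparisons on 200 random graphs of up to 12
nodes (brute-force Floyd–Warshall and exhaustive 203-partition
modularity), backbone calibration at the full 78-region scale, null-model
invariance on 100 random graphs, module recovery on 50 planted-partition
draws, GLM calibration with 2000 null and 500 powered replicates, and 20
end-to-end replicates of the programmed-effect cohort at the full
5 x 36 x 78 design with 100-null small-world ensembles. These sizes are
the package's chosen compromise between Monte-Carlo resolution and a
test-suite that runs in minutes on one core.

## Known limitations

* The greedy optimizer is a heuristic: on small random graphs it reaches
  the exhaustive optimum within 10% in >=90% of cases (asserted), but it
  offers no optimality guarantee at 78 nodes.
* Small-world ratios depend on the weighted-null convention chosen here;
  binarized or strength-preserving-only nulls would give different
  gamma/lambda scales.
* The effect-injection calibration is local to the default cohort design,
  as described above.
* `sigma` summarizes gamma and lambda into one ratio; networks with
  `lambda` far from 1 should be read from gamma and lambda directly.
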