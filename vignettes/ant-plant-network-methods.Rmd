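---
title: "Methods: quantitative structure of ant-plant interaction networks"
author: "antplantnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative structure of ant-plant interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antplantnet)
```

# The data and its contract

The central object is a plants × ants matrix of non-negative integer
counts: cell $w_{ij}$ is the number of census occasions on which ant $j$
was recorded on the extrafloral nectaries of plant $i$. The
`InteractionNetwork` class enforces the contract all downstream metrics
assume: integral non-negative weights, unique labels within each guild, no
species without interactions, and a positive grand total. Files with
fractional cells are rejected rather than rounded — visit counts are
integers, and a fractional value signals a corrupted or misformatted file,
not data to be repaired silently. Label matching everywhere is exact and
case-sensitive after whitespace trimming: fuzzy matching hides data errors.

Rarely recorded interactions (fewer than `min_count = 3` occasions by
default) are removed before analysis: single records make a merely rare
species look like a specialist and inflate nestedness and strength
asymmetry. The filter zeroes sub-threshold cells and drops species left
with no interactions. It is idempotent at a fixed threshold, which settles
a practical ambiguity about archived matrices: whether a deposited matrix
is pre- or post-filter, applying the filter again is harmless, so the
pipeline always applies it (pass `min_count = 1` to disable).

# Network-level structure

**Nestedness (NODF).** For each unordered pair of rows (and of columns),
the member with the strictly larger degree receives
$100 \times |\text{shared partners}| / k_{lo}$; equal-degree pairs score
zero. This is the *decreasing fill* condition of the metric as originally
defined; we deliberately do not implement the lenient variant that scores
tied pairs, because the two differ on degenerate matrices and the strict
form is what the standard software computes. The weighted variant (WNODF)
replaces presence overlap by the count of partner cells where the
smaller-total member's weight is positive but strictly below the
larger-total member's.

**Null model.** Significance uses the degree-proportional Bernoulli model
(null model II, "Ce"): $p_{ij} = \tfrac12 (k_i/A + k_j/P)$ on the
binarized matrix, which preserves expected fill exactly
($\overline{p} = L/PA$, an algebraic identity asserted in the tests).
Draws containing an all-zero row or column are rejected and redrawn by
default, keeping the dimensions of every null matrix equal to the
observed one; this is the convention under which null means are
comparable across studies, but the conditioning does bias the accepted
fill slightly upward on sparse matrices, so the sampler exposes
`reject_degenerate = FALSE` for unconditioned draws and the calibration
tests use it. P-values follow the add-one convention
$(\#\{null \ge obs\} + 1)/(n + 1)$, so they are never exactly zero; the
nestedness test is one-sided ("greater"), the direction of the nestedness
hypothesis.

**Dependence and overlap.** The dependence of plant $i$ on ant $j$ is
$w_{ij}/\sum_j w_{ij}$, and a link's asymmetry is the absolute difference
of the two directed dependences normalized by the larger one (the
per-link normalization; a bias-corrected variant exists but the plain
form is the one in standard use, and the per-link mean is what we
report). Niche overlap is Horn's information-theoretic index on
partner-use proportions with natural logarithms and the $2\ln 2$
normalizer, which guarantees values in $[0,1]$; Morisita–Horn is a
different statistic and is not used.

# Species-level structure

**Species strength** is the sum over a species' partners of their
dependences on it. Its conservation law — ant strengths sum exactly to
the number of plants — holds to machine precision on every matrix and is
used as a standing invariant in the test suite.

**Specialization d′** standardizes the Kullback–Leibler divergence
$d_i = \sum_j p'_{ij}\ln(p'_{ij}/q_j)$ (partner use vs. partner
availability $q_j$, the partner's share of the grand total) between the
extremes achievable by *integer* reallocations of the species' observed
total: the minimum by the marginal-allocation algorithm (provably optimal
for this separable convex objective — the tests verify it against
exhaustive enumeration of all allocations), the maximum by the defining
greedy procedure that monopolizes the most exclusive partners up to their
observed totals. Because the extremes are integer-constrained they depend
slightly on count granularity: multiplying the whole matrix by a constant
changes $d'$ at the third decimal for realistic totals, which is why the
scale-invariance test uses a 0.02 tolerance rather than machine
precision. When no discrimination is possible ($d_{max} = d_{min}$),
$d' = 0$; observed divergences exceeding the greedy maximum clamp to 1.

**Core–periphery.** Standardized degree $G_c = (k_i - \bar k)/sd(k)$
within a guild; $G_c \ge 1$ (ties included — "equal or larger") marks the
generalist core. Two choices here were genuinely open: $k$ counts binary
partners, not summed weights, because the formula is defined on numbers
of links; and $sd$ is the sample standard deviation ($n-1$), the common
usage of the formula, with the population form available as an option.
Zero degree variance leaves the classification undefined and raises an
error rather than returning all-periphery.

# Modularity

Barber's bipartite modularity
$Q_B = \tfrac1F \sum_{ij} (B_{ij} - k_i d_j / F)\,\delta(g_i, g_j)$ is
computed on the binarized matrix ($F$ = number of links): the cited
metric is binary, and binarization also makes the annealing landscape
independent of count magnitudes. Optimization is simulated annealing over
partitions with single-species relocation moves (to an existing module or
one fresh empty module per proposal); merge/split moves are unnecessary
at these sizes — the optimizer matches an exhaustive search over all set
partitions on every ≤ 10-species network in the test suite, across
random instances. The default schedule is $T_0 = 1$, geometric cooling
0.95 to $T_{min} = 10^{-4}$, $2(P+A)^2$ proposals per temperature and 3
independent restarts: roughly $10^6$ proposal evaluations per restart at
the 50-species scale, a few tenths of a second with the compiled core.
The best-ever partition is returned with empty modules compacted, and the
stored $Q_B$ is recomputed from the membership in R, so the score always
equals its definition rather than an incrementally updated float.

Significance re-optimizes each of `n_reps` null-model matrices with a
single restart (the observed network keeps 3): the null ensemble needs
the *distribution* of optimized scores, and one restart per matrix keeps
a 200–1000 replicate ensemble tractable while the oracle tests show
single-restart annealing already attains the optimum on enumerable
networks.

# Ordination and attribute fitting

Plants are ordinated by 2-D non-metric multidimensional scaling of
Bray–Curtis dissimilarities among their interaction-count profiles.
Counts are square-root transformed and Wisconsin-standardized when the
matrix maximum exceeds 9 — the conventional auto-transformation for
heavily skewed counts — and the flag is exposed because archived analyses
differ in whether it was applied.

The NMDS minimizes Kruskal stress-1. Each start alternates (i) monotone
regression of configuration distances on the rank order of the input
dissimilarities — pool-adjacent-violators, with tied dissimilarities
pre-sorted by configuration distance (primary tie treatment) — with (ii)
a Guttman configuration update, accepted only if stress decreases
(step-halving otherwise), so the per-iteration stress trace is
non-increasing by construction. The first start is the classical metric
scaling solution and the rest are random: stress-1 only constrains the
configuration up to a monotone warp of the distances, so for
dissimilarities that are already Euclidean the metric start pins the
solution to the true shape instead of an arbitrary warp, and on real data
it is simply a good start. Defaults: 20 starts, iteration cap 300,
relative improvement tolerance $10^{-8}$. Convergence is declared when
another start agrees with the best within a symmetric Procrustes sum of
squares of $10^{-3}$; failure to converge flags the result rather than
raising an error, since the best-start solution is still the best found.
The returned scores are centered and rotated to principal axes. Ants are
then placed at the interaction-weight-weighted averages of their partner
plants' coordinates (on raw counts — the weights are the interactions
themselves, not transformed abundances).

Attribute fitting mirrors the standard post-hoc procedure: factors score
$r^2 = 1 - SS_{within}/SS_{total}$ of the 2-D scores about level
centroids, continuous vectors the $R^2$ of the best linear combination of
axes predicting the variable (both reproduce the reference
implementation's $r^2$ to machine precision in the cross-check tests);
p-values permute the attribute values with the add-one rule. Plant
attributes are fitted on plant scores and ant attributes on ant
(weighted-average) scores, separately — a joint fit across guilds is not
well defined because the two score sets live on different supports. The
habitat factor contrast is open vs. shaded: plants occurring in both
habitat types (`"B"`) are treated as missing in that fit, and missing
values generally are dropped per attribute with a reported count.

# The synthetic generator

`generateNetwork()` draws the structure the analysis assumes, so every
stage can be validated on data of known truth:

* a **nested backbone**: link probabilities proportional to the outer
  product of geometrically decaying species activities
  ($e^{-\lambda (i-1)/(n-1)}$, $\lambda$ = `nestedness_shape`, default
  2.5), with the base rate calibrated by root-finding so the backbone
  fill is 0.27 — the connectance typical of intensively sampled EFN
  networks at this scale;
* a **habitat signal**: every species is assigned to an open ("O") or
  shaded ("S") block, and the realization *odds* of a same-habitat link
  are multiplied by `habitat_effect` (default 8). The signal enters
  through interaction odds, not species composition, so it is detectable
  exactly where the analysis looks for it — in the ordination of
  interaction profiles. Note the boost raises realized connectance above
  the backbone's 0.27 (to roughly 0.43 at the default effect; exactly
  0.27 at `habitat_effect = 1`);
* **counts** on realized links drawn zero-truncated Poisson with mean
  `mean_frequency` (default 8, the order of the mean records-per-link in
  intensive multi-year censuses), keeping the binary topology and the
  weights consistent;
* **ant head lengths** built from a Gaussian copula on realized degree
  targeting Spearman `headlength_degree_rho` (default 0.565, a typical
  published trait–degree correlation), mapped to a realistic 0.4–3.0 mm
  range; and
* **plant cover** drawn log-normally, independent of everything — the
  null covariate whose fitted significance must stay at the nominal
  rate, which the test suite checks.

Defaults are 31 plants × 19 ants, the scale of the motivating study
system. The generator does *not* emulate several features of real census
data: no seasonal or spatial replication, no sampling-effort artefacts
(every realized link is observed), habitat is exactly two blocks with no
"both" species, and counts are conditionally independent Poisson rather
than overdispersed. Tests passing on synthetic data therefore validate
the *computations*, not robustness to those field realities.

`generateModularNetwork()` plants a partition (within-block probability
vs. between-block) as ground truth for the modularity stack.

# Reproducibility and problem sizes

Every randomized stage — null ensembles, annealing restarts, NMDS starts,
permutation tests — consumes a child seed derived deterministically from
one root seed (`childSeeds()`), so reports are bit-reproducible and
stages remain statistically independent. The test suite validates each
metric against independent brute-force oracles on random small matrices
(around a hundred draws per metric), checks the annealing optimizer
against exhaustive partition enumeration up to 10 species, calibrates the
permutation and null-model machinery (200-replicate type-I checks), and
measures detection power for the planted habitat signal over 100
generator replicates; the full suite runs in about a minute on one CPU.
The acceptance script runs the complete pipeline at the default study
scale with a 1000-replicate nestedness ensemble, 200 modularity nulls,
20 NMDS starts and 999 permutations, in well under a minute.

# Known limitations

* WNODF is reported alongside binary NODF, but "weighted nestedness" in
  the older literature sometimes denotes a different estimator (WINE);
  values from different metrics are not comparable.
* The d′ extremes follow the defining greedy procedure; the true
  capacitated maximum of the divergence can exceed the greedy one, in
  which case d′ saturates at 1 by clamping.
* The modularity null distribution depends on the annealing budget given
  to the null matrices; with the single-restart default the null scores
  are very slightly conservative (under-optimized), which makes the
  significance test conservative as well.
* NMDS convergence between restarts is judged by Procrustes agreement,
  which cannot distinguish two distinct optima of equal stress; the
  `converged` flag should be read as "the best solution was found at
  least twice", not as a guarantee of global optimality.
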