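# antplantnet

Quantitative analysis of bipartite ant–plant interaction networks.

Communities of plants bearing extrafloral nectaries (EFNs) and the ants that
feed on them form weighted bipartite networks: a plants × ants matrix whose
cell *w<sub>ij</sub>* counts how often ant species *j* was recorded feeding
on plant species *i* across censuses. Community ecologists ask a standard
battery of questions of such a matrix — is the network nested? is it
modular? which species form its generalist core? and which biological or
ecological attributes of the species (habitat, body size, abundance,
behavior) explain the pattern of pairwise interactions? `antplantnet`
implements that complete analysis as a reusable, tested R package, for
anyone working with two-guild count networks (pollination, seed dispersal,
ant–plant protection, host–parasite).

## What it computes

With *P* plants, *A* ants, *L* realized links and *F* total interaction
frequency:

* **Connectance** *C = L / (P·A)*, and **nestedness** by NODF (paired
  overlap with decreasing fill, 0–100) in binary and weighted forms, with
  significance against the degree-proportional Bernoulli null model
  ("null model II" / *Ce*: cell probability *p<sub>ij</sub> =
  (k<sub>i</sub>/A + k<sub>j</sub>/P)/2*), add-one Monte Carlo p-values.
* **Dependence asymmetry**: per link, |d<sup>plant</sup> − d<sup>ant</sup>| /
  max(d<sup>plant</sup>, d<sup>ant</sup>), where a species' dependence on a
  partner is the fraction of its total interactions the partner carries;
  and **Horn niche overlap** within each guild.
* **Species-level metrics**: degree, **species strength** (the summed
  dependences of a species' partners on it; guild totals conserve the
  opposite guild's size exactly), **d′ specialization** (standardized
  Kullback–Leibler divergence of partner use from partner availability),
  and **core–periphery** status via standardized degree
  *G<sub>c</sub> = (k<sub>i</sub> − k̄)/sd(k)*, core ⇔ *G<sub>c</sub>* ≥ 1.
* **Barber bipartite modularity** *Q<sub>B</sub>*, maximized by simulated
  annealing (compiled core, exact brute-force oracle for ≤ 10 species),
  with Monte Carlo significance against the same null model.
* **Ordination**: Bray–Curtis dissimilarities of the plants' interaction
  profiles, two-dimensional NMDS minimizing Kruskal stress-1 (monotone
  regression by pool-adjacent-violators; metric-scaling first start plus
  random restarts), ants placed at interaction-weighted averages of their
  partners' coordinates, and **permutation fitting of attributes**
  (vectors and factors, r² with permutation p-values) onto the scores.
* **Classical companions**: Spearman rank correlation (e.g. ant head
  length vs. degree), χ² goodness of fit, one-way ANOVA, Sørensen
  floristic similarity.
* A **synthetic network generator** with a geometric nested backbone,
  a two-habitat block signal on link odds, trait–degree correlation, and a
  null abundance covariate — so every stage of the analysis is testable
  against data of known structure.

## Worked example

```r
library(antplantnet)

## a synthetic study-scale community: 31 plants x 19 ants, nested backbone,
## open/shaded habitat signal on the link odds, head length tracking degree
sim <- generateNetwork(syntheticConfig(seed = 7))

report <- runPipeline(sim$network, sim$plants, sim$ants,
                      min_count = 1, n_null = 500, n_null_modularity = 99,
                      n_perm = 999, n_starts = 10, seed = 7)
print(report)
```

```
Ant-plant network analysis report
  input: 31 plants x 19 ants, L = 266, F = 2148
  connectance = 0.452, NODF = 62.45 (null mean 51.74, p = 0.001996)
  WNODF = 31.60, dependence asymmetry = 0.412
  niche overlap: ants 0.470, plants 0.465
  modularity: Q_B = 0.203 in 4 modules (p = 0.15)
  core: 6 plants, 4 ants
  NMDS stress = 0.173 (10 starts)
  plant attribute fit:
EnvFit: 3 attributes, 999 permutations
  efn            factor r2 = 0.003  p = 0.916
  habitat        factor r2 = 0.308  p = 0.001
  cover          vector r2 = 0.060  p = 0.43
  ant attribute fit:
EnvFit: 4 attributes, 999 permutations
  invasive       factor r2 = 0.050  p = 0.396
  dominance      factor r2 = 0.174  p = 0.805
  habitat        factor r2 = 0.570  p = 0.001
  head_length    vector r2 = 0.261  p = 0.105
  head length ~ degree: rho = 0.426, p = 0.06906
```

Reading the report: the network is significantly nested (NODF 62.5 against
a null mean of 51.7) but not significantly modular (p = 0.15); the
generalist core holds 6 plants and 4 ants; the 2-D ordination is a good
summary (stress 0.17 ≤ 0.2); and of all species attributes only the
habitat factor — the signal the generator actually planted — explains the
pairwise interaction pattern (r² = 0.31, p = 0.001 for plants), while the
abundance covariate, generated independently of the network, correctly
shows nothing. `writeReport(report, "out/")` serializes everything as flat
JSON/TSV.

For field data, start instead from files:

```r
net    <- readInteractionMatrix("matrix.csv")         # plants as rows
plants <- readSpeciesAttributes("plants.tsv", "plant")
ants   <- readSpeciesAttributes("ants.tsv", "ant")
report <- runPipeline(net, plants, ants, min_count = 3, seed = 1)
```

`min_count = 3` drops pairwise interactions recorded fewer than three
times before analysis — the usual guard against overestimating
specialization and nestedness from rare records; the filter is idempotent,
so already-filtered matrices pass through unchanged. The package ships the
attribute tables of a 31-plant / 19-ant tropical coastal EFN community
under `inst/extdata/` (`plant_attributes.tsv`, `ant_attributes.tsv`) as a
ready-made example of the attribute format.

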