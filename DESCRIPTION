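Package: antplantnet
Title: Structure and Correlates of Quantitative Ant-Plant Interaction Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of bipartite ant-plant
    interaction networks mediated by extrafloral nectaries. Implements
    network-level structure (connectance, binary and weighted NODF
    nestedness, dependence asymmetry, Horn niche overlap), species-level
    metrics (species strength, Bluethgen's d' specialization, standardized
    degree and core-periphery classification), degree-proportional Bernoulli
    null models with Monte Carlo significance tests, Barber bipartite
    modularity maximized by simulated annealing with an exact brute-force
    oracle for small networks, non-metric multidimensional scaling of
    Bray-Curtis dissimilarities with permutation-based fitting of species
    and habitat attributes onto the ordination, and a synthetic network
    generator with controllable nestedness, habitat block structure and
    trait-degree correlation for power and calibration studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, vegan, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
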