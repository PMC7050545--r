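# Species strength, d' specialization and core-periphery classification.

test_that("species strength matches hand arithmetic and conserves guild totals", {
  net <- make_net(matrix(c(2, 0, 1, 3), 2, 2))
  s <- speciesStrength(net, "ant")
  expect_equal(unname(s), c(2/3, 4/3), tolerance = 1e-12)
  expect_equal(sum(s), 2)  # = number of plants
  # single-plant network: ant strengths are that plant's dependences
  single <- make_net(matrix(c(3, 1), 1, 2))
  expect_equal(unname(speciesStrength(single, "ant")), c(0.75, 0.25))
  expect_equal(sum(speciesStrength(single, "ant")), 1)
})

test_that("strength conservation and the oracle hold on random matrices", {
  set.seed(31)
  for (r in 1:100) {
    net <- rand_net(sample(2:6, 1), sample(2:6, 1))
    w <- interactionCounts(net)
    expect_equal(unname(speciesStrength(net, "ant")), oracle_strength_ants(w),
                 tolerance = 1e-10)
    expect_equal(sum(speciesStrength(net, "ant")), nrow(w), tolerance = 1e-10)
    expect_equal(sum(speciesStrength(net, "plant")), ncol(w), tolerance = 1e-10)
  }
})

test_that("d' is 0 for availability-proportional use and bounded in [0,1]", {
  # every plant's use proportions equal the ants' availability profile
  neutral <- make_net(matrix(c(1, 2, 3, 2, 4, 6), 2, 3, byrow = TRUE))
  expect_equal(unname(dPrime(neutral, "plant")), c(0, 0), tolerance = 1e-10)
  set.seed(32)
  for (r in 1:30) {
    net <- rand_net(sample(3:5, 1), sample(3:5, 1))
    for (g in c("plant", "ant")) {
      d <- dPrime(net, g)
      expect_true(all(d >= 0 & d <= 1))
    }
  }
})

test_that("d' extremes agree with exhaustive allocation enumeration on small rows", {
  set.seed(33)
  for (r in 1:40) {
    # small totals so every integer allocation can be enumerated
    repeat {
      w <- matrix(rbinom(12, 2, 0.5), 4, 3)
      if (all(rowSums(w) > 0) && all(colSums(w) > 0)) break
    }
    net <- make_net(w)
    d_pkg <- dPrime(net, "plant")
    for (i in seq_len(nrow(w)))
      expect_equal(unname(d_pkg[i]), oracle_dprime_row(w, i), tolerance = 1e-10)
  }
})

test_that("d' is stable under integer rescaling of the whole matrix", {
  # the integer-allocation extremes are granularity-dependent, so stability
  # is asserted at a coarse tolerance, not machine precision
  set.seed(34)
  for (r in 1:10) {
    repeat {
      m <- matrix(rpois(16, 8) * (runif(16) < 0.7), 4, 4)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
    }
    net <- make_net(m)
    scaled <- make_net(m * 3)
    expect_equal(unname(dPrime(scaled, "plant")), unname(dPrime(net, "plant")),
                 tolerance = 0.02)
  }
})

test_that("standardized degree reproduces the worked example and flags the core", {
  # degrees 5,2,2,1 across 5 ants
  w <- rbind(c(1, 1, 1, 1, 1),
             c(1, 1, 0, 0, 0),
             c(0, 0, 1, 1, 0),
             c(0, 0, 0, 0, 1))
  cp <- corePeriphery(make_net(w), "plant")
  expect_equal(cp$Gc, c(1.44, -0.29, -0.29, -0.87), tolerance = 0.005)
  expect_identical(cp$core, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(cp$Gc, unname(oracle_gc(rowSums(w > 0))), tolerance = 1e-12)
  # Gc values standardize to mean 0, sd 1 by construction
  expect_equal(mean(cp$Gc), 0, tolerance = 1e-12)
  expect_equal(sd(cp$Gc), 1, tolerance = 1e-12)
  expect_error(corePeriphery(make_net(matrix(1, 3, 3)), "plant"),
               "zero degree variance")
})

test_that("strength rank-correlates with degree on synthetic nested networks", {
  rhos <- vapply(1:5, function(s) {
    net <- generateNetwork(syntheticConfig(n_plants = 20, n_ants = 15,
                                           habitat_effect = 1, seed = s))$network
    cor(speciesStrength(net, "ant"), speciesDegrees(net, "ant"),
        method = "spearman")
  }, numeric(1))
  expect_true(all(rhos > 0.8))
})

test_that("the species-level report is consistent across its columns", {
  set.seed(35)
  net <- rand_net(6, 5)
  rep <- speciesLevel(net)
  expect_setequal(rep$species[rep$guild == "plant"], plantNames(net))
  expect_equal(rep$core, rep$Gc >= 1)
  expect_equal(sum(rep$strength[rep$guild == "ant"]), dim(net)[1],
               tolerance = 1e-10)
})
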