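# Barber modularity: scoring identities, annealing vs exhaustive oracle,
# planted-partition recovery, significance.

test_that("Q_B identities: single module scores 0, 2x2 identity scores +-0.5", {
  set.seed(51)
  net <- rand_net(4, 4)
  one <- setNames(rep(1L, 8), c(plantNames(net), antNames(net)))
  expect_equal(qbScore(net, one), 0, tolerance = 1e-12)
  id2 <- interactionNetwork(diag(2), plants = c("P1", "P2"), ants = c("A1", "A2"))
  expect_equal(qbScore(id2, c(P1 = 1, P2 = 2, A1 = 1, A2 = 2)), 0.5)
  expect_equal(qbScore(id2, c(P1 = 1, P2 = 2, A1 = 2, A2 = 1)), -0.5)
  expect_error(qbScore(id2, c(P1 = 1, P2 = 2, A1 = 1)), "missing.*A2")
})

test_that("Q_B matches the direct double-loop oracle and is relabeling-invariant", {
  set.seed(52)
  for (r in 1:30) {
    net <- rand_net(4, 3)
    sp <- c(plantNames(net), antNames(net))
    memb <- setNames(sample(1:3, length(sp), replace = TRUE), sp)
    memb <- as.integer(factor(memb)); names(memb) <- sp
    expect_equal(qbScore(net, memb),
                 oracle_qb(interactionCounts(net), memb, plantNames(net), antNames(net)),
                 tolerance = 1e-12)
    # permuting module labels changes nothing
    relab <- setNames(as.integer(factor(memb, levels = sample(unique(memb)))), sp)
    expect_equal(qbScore(net, relab), qbScore(net, memb), tolerance = 1e-12)
  }
})

test_that("brute force finds the known optima of canonical small networks", {
  id2 <- interactionNetwork(diag(2), plants = c("P1", "P2"), ants = c("A1", "A2"))
  bf <- bruteForceModules(id2)
  expect_equal(qbValue(bf), 0.5)
  m <- moduleMembership(bf)
  expect_equal(m[["P1"]], m[["A1"]])
  expect_equal(m[["P2"]], m[["A2"]])
  expect_false(m[["P1"]] == m[["P2"]])
  # saturated network: no partition beats one module
  full <- make_net(matrix(1, 3, 3))
  expect_equal(qbValue(bruteForceModules(full)), 0, tolerance = 1e-12)
  expect_error(bruteForceModules(make_net(matrix(1, 6, 5))), "<= 10")
})

test_that("annealing attains the exhaustive optimum on random small networks", {
  set.seed(53)
  for (r in 1:25) {
    net <- rand_net(sample(3:4, 1), sample(3:4, 1), fill = 0.5)
    bf <- bruteForceModules(net)
    sa <- optimizeModules(net, seed = r)
    expect_gte(qbValue(sa), qbValue(bf) - 1e-12)
    expect_equal(qbValue(sa), qbValue(bf), tolerance = 1e-10)
  }
})

test_that("two disconnected perfect blocks are recovered exactly at Q_B = 0.5", {
  out <- generateModularNetwork(2, 4, 4, within_p = 1, between_p = 0, seed = 5)
  part <- optimizeModules(out$network, seed = 6)
  expect_equal(qbValue(part), 0.5, tolerance = 1e-12)
  expect_equal(nModules(part), 2)
  m <- moduleMembership(part)
  planted <- out$membership[names(m)]
  # identical partition up to label swap
  expect_equal(length(unique(paste(m, planted))), 2)
})

test_that("annealing is seed-deterministic, reports a valid compact partition and a monotone trace", {
  net <- generateNetwork(syntheticConfig(n_plants = 12, n_ants = 8, seed = 3))$network
  p1 <- optimizeModules(net, seed = 99)
  p2 <- optimizeModules(net, seed = 99)
  expect_identical(moduleMembership(p1), moduleMembership(p2))
  expect_identical(qbValue(p1), qbValue(p2))
  # qb slot equals recomputation from the membership
  expect_equal(qbValue(p1), qbScore(net, moduleMembership(p1)), tolerance = 1e-12)
  ids <- sort(unique(moduleMembership(p1)))
  expect_identical(ids, seq_along(ids))
  expect_false(is.unsorted(p1@trace[, "best_qb"]))
  expect_error(optimizeModules(net, cooling = 1.2), "cooling")
  expect_error(optimizeModules(net, t0 = -1), "t0")
})

test_that("a strongly modular planted network tests significant; significance is reproducible", {
  out <- generateModularNetwork(3, 4, 3, within_p = 0.95, between_p = 0.02, seed = 7)
  sig <- modularitySignificance(out$network, n_reps = 99, seed = 8)
  expect_lte(pValue(sig), 0.02)
  sig2 <- modularitySignificance(out$network, n_reps = 99, seed = 8)
  expect_identical(nullValues(sig), nullValues(sig2))
})
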