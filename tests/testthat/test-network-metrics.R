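# Network-level metrics against hand-worked values and brute-force oracles.

test_that("connectance is the realized fraction of possible links", {
  expect_equal(connectance(make_net(matrix(c(2, 0, 1, 3), 2, 2))), 0.75)
  expect_equal(connectance(make_net(matrix(1, 3, 4))), 1)
})

test_that("NODF scores nested, anti-nested and hand-enumerated matrices correctly", {
  perfect <- make_net(matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE))
  expect_equal(nodf(perfect), 100)
  # all six pairs enumerated by hand: only (row1,row3) and (col2,col3) score
  hand <- make_net(matrix(c(1, 1, 0, 0, 1, 1, 1, 0, 0), 3, 3, byrow = TRUE))
  expect_equal(nodf(hand), 100 * 2 / 6, tolerance = 1e-12)
  # checkerboard with equal degrees: every pair tied, decreasing fill fails
  checker <- make_net(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(nodf(checker), 0)
  expect_error(nodf(make_net(matrix(1:3, 1, 3))), "single-row")
})

test_that("NODF is invariant to species permutations and matches the oracle on random draws", {
  set.seed(21)
  for (r in 1:100) {
    net <- rand_net(sample(3:5, 1), sample(3:5, 1))
    w <- interactionCounts(net)
    expect_equal(nodf(net), oracle_nodf(w), tolerance = 1e-10)
    perm <- make_net(w[sample(nrow(w)), sample(ncol(w)), drop = FALSE])
    expect_equal(nodf(perm), nodf(net), tolerance = 1e-10)
  }
})

test_that("weighted NODF is 100 on strictly nested decreasing weights and 0 on flat ties", {
  strict <- make_net(matrix(c(5, 4, 3, 4, 3, 0, 3, 0, 0), 3, 3, byrow = TRUE))
  expect_equal(nodf(strict, weighted = TRUE), 100)
  flat <- make_net(matrix(c(2, 2, 2, 2), 2, 2))
  expect_equal(nodf(flat, weighted = TRUE), 0)
})

test_that("dependences are row-stochastic shares of each species' total", {
  net <- make_net(matrix(c(2, 0, 1, 3), 2, 2))
  dp <- dependenceMatrix(net, "plant")
  expect_equal(unname(dp), matrix(c(2/3, 0, 1/3, 1), 2, 2))
  expect_equal(unname(rowSums(dp)), c(1, 1))
  da <- dependenceMatrix(net, "ant")
  expect_equal(unname(colSums(da)), c(1, 1))
  # one-partner species depends fully on it
  single <- make_net(matrix(c(4, 0, 2, 3), 2, 2, byrow = TRUE))
  expect_equal(dependenceMatrix(single, "plant")[1, 1], 1)
})

test_that("dependence asymmetry matches hand arithmetic, vanishes on perfect matchings, stays in [0,1]", {
  expect_equal(dependenceAsymmetry(make_net(matrix(c(2, 0, 1, 3), 2, 2))),
               mean(c(1/3, 0.25, 0.25)), tolerance = 1e-12)
  expect_equal(dependenceAsymmetry(make_net(matrix(1, 1, 1))), 0)
  expect_equal(dependenceAsymmetry(make_net(diag(3) * 4 + 0)), 0)
  set.seed(22)
  for (r in 1:50) {
    net <- rand_net(4, 4)
    a <- dependenceAsymmetry(net)
    expect_equal(a, oracle_asymmetry(interactionCounts(net)), tolerance = 1e-10)
    expect_true(a >= 0 && a <= 1)
  }
})

test_that("Horn overlap is 1 for identical profiles, 0 for disjoint, scale-invariant, oracle-exact", {
  ident <- make_net(matrix(c(1, 2, 2, 4, 3, 6), 2, 3))  # row2 = 2 x row1
  expect_equal(nicheOverlap(ident, "plant"), 1, tolerance = 1e-12)
  disjoint <- make_net(rbind(c(1, 2, 0, 0), c(0, 0, 3, 1)))
  expect_equal(nicheOverlap(disjoint, "plant"), 0, tolerance = 1e-12)
  set.seed(23)
  for (r in 1:50) {
    net <- rand_net(4, 4)
    w <- interactionCounts(net)
    expect_equal(nicheOverlap(net, "plant"), oracle_horn_mean(w, "row"),
                 tolerance = 1e-10)
    expect_equal(nicheOverlap(net, "ant"), oracle_horn_mean(w, "col"),
                 tolerance = 1e-10)
    # rescaling one species' weights leaves its proportional profile alone
    w2 <- w; w2[1, ] <- w[1, ] * 7
    expect_equal(nicheOverlap(make_net(w2), "plant"),
                 nicheOverlap(net, "plant"), tolerance = 1e-10)
  }
})

test_that("the network-level report stays within its stated bounds", {
  set.seed(24)
  rep <- networkLevel(rand_net(6, 5))
  expect_true(rep$connectance > 0 && rep$connectance <= 1)
  expect_true(rep$nodf >= 0 && rep$nodf <= 100)
  expect_true(rep$wnodf >= 0 && rep$wnodf <= 100)
  expect_true(rep$dependence_asymmetry >= 0 && rep$dependence_asymmetry <= 1)
  expect_true(rep$niche_overlap_ants >= 0 && rep$niche_overlap_ants <= 1)
  expect_true(rep$niche_overlap_plants >= 0 && rep$niche_overlap_plants <= 1)
})
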