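# Bray-Curtis, isotonic regression, NMDS and permutation attribute fitting.

test_that("Bray-Curtis matches the formula and its boundary cases", {
  x <- make_net(rbind(c(1, 2), c(3, 0)))
  d <- brayCurtis(x, "plant", autotransform = FALSE)
  expect_equal(as.numeric(d), 4 / 6, tolerance = 1e-12)
  ident <- make_net(rbind(c(1, 2), c(1, 2)))
  expect_equal(as.numeric(brayCurtis(ident, "plant", autotransform = FALSE)), 0)
  disj <- make_net(rbind(c(1, 2, 0, 0), c(0, 0, 3, 1)))
  expect_equal(as.numeric(brayCurtis(disj, "plant", autotransform = FALSE)), 1)
  set.seed(61)
  for (r in 1:30) {
    net <- rand_net(4, 5)
    w <- interactionCounts(net)
    d <- as.matrix(brayCurtis(net, "plant", autotransform = FALSE))
    i <- sample(4, 1); j <- sample(4, 1)
    expect_equal(d[i, j], if (i == j) 0 else oracle_bray(w[i, ], w[j, ]),
                 tolerance = 1e-10)
  }
})

test_that("the auto-transform kicks in only above the count threshold", {
  small <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_identical(transformCounts(small), small)
  big <- matrix(c(10, 2, 3, 40), 2, 2)
  expect_equal(transformCounts(big), vegan::wisconsin(sqrt(big)))
})

test_that("PAVA equals the exhaustive least-squares monotone oracle, ties included", {
  expect_equal(pava(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(pava(c(3, 2, 1)), c(2, 2, 2))
  set.seed(62)
  for (r in 1:40) {
    n <- sample(3:8, 1)
    y <- if (r %% 2 == 0) round(rnorm(n), 1) else rnorm(n)  # force ties half the time
    expect_equal(pava(y), oracle_isotonic(y), tolerance = 1e-10)
  }
  # weighted blocks pool to weighted means
  expect_equal(pava(c(4, 1), w = c(1, 3)), c(1.75, 1.75))
})

test_that("NMDS embeds exact planar distances at ~zero stress and recovers the shape", {
  set.seed(63)
  pts <- cbind(runif(6), runif(6))
  rownames(pts) <- paste0("s", 1:6)
  fit <- nmdsFit(dist(pts), n_starts = 10, seed = 5)
  expect_lt(fit$stress, 1e-3)
  expect_lt(procrustes_error(pts, fit$points), 1e-2)
})

test_that("NMDS is seed-deterministic with a non-increasing stress trace and centered, rotated scores", {
  net <- generateNetwork(syntheticConfig(n_plants = 14, n_ants = 9, seed = 4))$network
  d <- brayCurtis(net, "plant")
  f1 <- nmdsFit(d, n_starts = 6, seed = 11)
  f2 <- nmdsFit(d, n_starts = 6, seed = 11)
  expect_identical(f1$points, f2$points)
  expect_identical(f1$stress, f2$stress)
  expect_false(is.unsorted(rev(f1$trace)))
  expect_equal(unname(colMeans(f1$points)), c(0, 0), tolerance = 1e-10)
  # principal-axis rotation: cross-products diagonal, axis 1 carries most spread
  cp <- crossprod(f1$points)
  expect_equal(cp[1, 2], 0, tolerance = 1e-8)
  expect_gte(cp[1, 1], cp[2, 2])
  # adding starts can only improve (or tie) the returned stress
  f3 <- nmdsFit(d, n_starts = 12, seed = 11)
  expect_lte(f3$stress, f1$stress + 1e-12)
})

test_that("configuration distances rank-correlate strongly with input dissimilarities at low stress", {
  net <- generateNetwork(syntheticConfig(n_plants = 16, n_ants = 10, seed = 6))$network
  d <- brayCurtis(net, "plant")
  fit <- nmdsFit(d, n_starts = 8, seed = 7)
  expect_lt(fit$stress, 0.2)
  rho <- cor(as.vector(d), as.vector(dist(fit$points)), method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("second-guild scores are interaction-weighted averages", {
  w <- rbind(c(1, 0, 1), c(0, 1, 3))
  net <- make_net(w)
  # P1 at (0, 0), P2 at (1, 1)
  ps <- matrix(c(0, 1, 0, 1), 2, 2, dimnames = list(plantNames(net), NULL))
  as_ <- secondGuildScores(net, ps)
  expect_equal(unname(as_[1, ]), c(0, 0))           # only partner is P1
  expect_equal(unname(as_[2, ]), c(1, 1))           # only partner is P2
  expect_equal(unname(as_[3, ]), c(0.75, 0.75))     # weights (1,3): 1/4-3/4 split
  even <- make_net(rbind(c(1, 2), c(1, 2)))
  ps2 <- matrix(c(0, 2, 0, 4), 2, 2, dimnames = list(plantNames(even), NULL))
  # equal weights from both plants: ants sit at the plants' midpoint
  expect_equal(unname(secondGuildScores(even, ps2)[1, ]), c(1, 2))
  expect_equal(unname(secondGuildScores(even, ps2)[2, ]), c(1, 2))
})

test_that("attribute fitting reproduces vegan::envfit r2 exactly for vectors and factors", {
  set.seed(64)
  sc <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("s", 1:30),
                                                 c("NMDS1", "NMDS2")))
  df <- data.frame(v = rnorm(30), f = sample(letters[1:3], 30, TRUE),
                   row.names = rownames(sc))
  ours <- fitTable(fitAttributes(sc, df, n_perm = 49, seed = 1))
  ref <- vegan::envfit(sc, data.frame(v = df$v, f = factor(df$f)),
                       permutations = 49)
  expect_equal(ours$r2[ours$attribute == "v"], unname(ref$vectors$r),
               tolerance = 1e-10)
  expect_equal(ours$r2[ours$attribute == "f"], unname(ref$factors$r),
               tolerance = 1e-10)
})

test_that("attribute fits are rotation-invariant, detect perfect separation, and handle NAs", {
  set.seed(65)
  # two tight distant clusters labeled by a 2-level factor
  sc <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
              matrix(rnorm(20, 5, 0.05), 10, 2))
  rownames(sc) <- paste0("s", 1:20); colnames(sc) <- c("NMDS1", "NMDS2")
  grp <- rep(c("x", "y"), each = 10)
  v <- sc[, 1] + rnorm(20, 0, 0.1)
  df <- data.frame(grp = grp, v = v, row.names = rownames(sc))
  ef <- fitTable(fitAttributes(sc, df, n_perm = 999, seed = 2))
  expect_gt(ef$r2[ef$attribute == "grp"], 0.99)
  expect_lte(ef$p_value[ef$attribute == "grp"], 0.001)
  # rotation leaves r2 unchanged
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  scr <- sc %*% R; rownames(scr) <- rownames(sc); colnames(scr) <- colnames(sc)
  ef_rot <- fitTable(fitAttributes(scr, df, n_perm = 49, seed = 2))
  expect_equal(ef_rot$r2, ef$r2, tolerance = 1e-10)
  # missing values dropped with a warning and counted
  df$v[1:3] <- NA
  expect_warning(out <- fitAttributes(sc, df, n_perm = 49, seed = 3),
                 "dropped 3")
  expect_equal(fitTable(out)$n_dropped[fitTable(out)$attribute == "v"], 3)
  # single-level factor errors
  expect_error(fitAttributes(sc, data.frame(g = rep("x", 20),
                                            row.names = rownames(sc)),
                             n_perm = 9, seed = 1), "single level")
})

test_that("the full network ordination returns a valid object with both guilds placed", {
  net <- generateNetwork(syntheticConfig(n_plants = 14, n_ants = 9, seed = 8))$network
  ord <- ordinateNetwork(net, n_starts = 6, seed = 9)
  expect_s4_class(ord, "NetworkOrdination")
  expect_equal(rownames(plantScores(ord)), plantNames(net))
  expect_equal(rownames(antScores(ord)), antNames(net))
  expect_true(ordinationStress(ord) >= 0 && ordinationStress(ord) <= 1)
})
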