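# Reading, validation, filtering and edge-list round trips.

test_that("matrix files read back exactly, in either orientation and delimiter", {
  m <- matrix(c(2, 0, 1, 3), 2, 2, dimnames = list(c("P1", "P2"), c("A1", "A2")))
  for (sep in c(",", "\t")) {
    f <- write_net_csv(m, sep)
    net <- readInteractionMatrix(f)
    expect_identical(interactionCounts(net), m)
    expect_equal(linkCount(net), 3)
    expect_equal(totalFrequency(net), 6)
  }
  # ants-as-rows file normalizes to plants as rows
  ft <- write_net_csv(t(m))
  net_t <- readInteractionMatrix(ft, orientation = "ants_rows")
  expect_identical(interactionCounts(net_t), m)
  # write/read round trip
  out <- tempfile(fileext = ".csv")
  writeInteractionMatrix(readInteractionMatrix(write_net_csv(m)), out)
  expect_identical(interactionCounts(readInteractionMatrix(out)), m)
})

test_that("malformed matrices are rejected with informative errors", {
  m <- matrix(c(2, 0, 1, 3), 2, 2, dimnames = list(c("P1", "P1"), c("A1", "A2")))
  expect_error(readInteractionMatrix(write_net_csv(m)), "duplicate label.*P1")
  m2 <- matrix(c(2, 0, -1, 3), 2, 2, dimnames = list(c("P1", "P2"), c("A1", "A2")))
  expect_error(readInteractionMatrix(write_net_csv(m2)), "negative count.*P1.*A2")
  m3 <- matrix(c(2, 0, 1.5, 3), 2, 2, dimnames = list(c("P1", "P2"), c("A1", "A2")))
  expect_error(readInteractionMatrix(write_net_csv(m3)), "fractional")
  f <- tempfile(); writeLines("species,A1", f)
  expect_error(readInteractionMatrix(f), "no data rows")
  # non-numeric cell
  f2 <- tempfile(); writeLines(c("species,A1,A2", "P1,2,x", "P2,1,3"), f2)
  expect_error(readInteractionMatrix(f2), "non-numeric cell.*P1.*A2")
  # all-zero row fails validation
  m4 <- matrix(c(0, 2, 0, 3), 2, 2, dimnames = list(c("P1", "P2"), c("A1", "A2")))
  expect_error(interactionNetwork(m4), "all-zero row")
})

test_that("rare-interaction filter zeroes sparse cells, drops empty species, and is idempotent", {
  net <- make_net(matrix(c(1, 2, 3, 5), 2, 2, byrow = TRUE))
  filt <- filterRareInteractions(net, 3)
  expect_equal(dim(filt), c(1, 2))
  expect_equal(unname(interactionCounts(filt)[1, ]), c(3, 5))
  expect_identical(plantNames(filt), "P2")
  # identity at threshold 1
  expect_identical(interactionCounts(filterRareInteractions(net, 1)),
                   interactionCounts(net))
  # idempotent at fixed threshold
  expect_identical(interactionCounts(filterRareInteractions(filt, 3)),
                   interactionCounts(filt))
  # input untouched
  expect_equal(interactionCounts(net)[1, 1], 1)
  # everything below threshold -> error
  all2 <- make_net(matrix(2, 2, 2))
  expect_error(filterRareInteractions(all2, 3), "no interactions survive")
})

test_that("L and F equal brute-force recounts on random matrices", {
  set.seed(11)
  for (r in 1:20) {
    net <- rand_net(sample(2:6, 1), sample(2:6, 1))
    w <- interactionCounts(net)
    expect_equal(linkCount(net), sum(w != 0))
    expect_equal(totalFrequency(net), sum(w))
  }
})

test_that("edge lists have exactly L positive triples and round-trip", {
  net <- make_net(matrix(c(2, 0, 1, 3), 2, 2))
  el <- asEdgeList(net)
  expect_equal(nrow(el), linkCount(net))
  expect_true(all(el$weight > 0))
  back <- edgeListToNetwork(el)
  expect_equal(interactionCounts(back)[plantNames(net), antNames(net)],
               interactionCounts(net))
  expect_identical(asEdgeList(back), el)
})

test_that("attribute tables read with typed validation; bad levels and label mismatches error", {
  plants <- readSpeciesAttributes(
    system.file("extdata", "plant_attributes.tsv", package = "antplantnet"),
    guild = "plant")
  tab <- attributeTable(plants)
  expect_equal(nrow(tab), 31)
  expect_equal(tab["Arundo donax", "cover"], 151.66)
  expect_equal(tab["Arundo donax", "habitat"], "O")
  expect_equal(tab["Arundo donax", "efn"], "C")

  ants <- readSpeciesAttributes(
    system.file("extdata", "ant_attributes.tsv", package = "antplantnet"),
    guild = "ant")
  atab <- attributeTable(ants)
  expect_equal(nrow(atab), 19)
  expect_equal(atab["Camponotus planatus", "invasive"], "NO")
  expect_equal(atab["Camponotus planatus", "dominance"], "C")
  expect_equal(atab["Camponotus planatus", "head_length"], 1.198)

  f <- tempfile(); writeLines(c("species,habitat", "p1,X"), f)
  expect_error(readSpeciesAttributes(f, "plant"), "unknown habitat level: 'X'")

  net <- make_net(matrix(c(2, 0, 1, 3), 2, 2))
  attrs <- speciesAttributes(data.frame(species = c("P1", "P9"), cover = c(1, 2)),
                             "plant")
  expect_error(matchAttributes(net, attrs), "P9")
  expect_true(matchAttributes(
    net, speciesAttributes(data.frame(species = "P1", cover = 1), "plant")))
})
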