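# Edges of the shared two-family fixture, computed once per file.
fixtureSeqs <- twoFamilyFixture()
fixtureEdges <- allVsAll(fixtureSeqs)
isIntra <- substr(fixtureEdges$id_a, 1, 4) == substr(fixtureEdges$id_b, 1, 4)
maxInter <- max(fixtureEdges$AS[!isIntra])
minIntra <- min(fixtureEdges$AS[isIntra])

test_that("the two-family fixture separates intra- from inter-family scores", {
  expect_gt(minIntra, maxInter)
})

test_that("thresholding splits the network into the generating families", {
  # low threshold: one connected component
  gLow <- buildSSN(fixtureEdges, threshold = 0)
  expect_equal(max(nodeData(gLow)$cluster), 1L)

  # between the inter- and intra-family AS ranges: exactly the 2 families
  mid <- (maxInter + minIntra) / 2
  gMid <- buildSSN(fixtureEdges, threshold = mid)
  cl <- ssnClusters(gMid)
  expect_equal(max(cl), 2L)
  famOf <- substr(names(cl), 1, 4)
  expect_length(unique(cl[famOf == "famA"]), 1L)
  expect_length(unique(cl[famOf == "famB"]), 1L)
  expect_false(cl[famOf == "famA"][1] == cl[famOf == "famB"][1])

  # above the maximum AS: all singletons
  gHigh <- buildSSN(fixtureEdges, threshold = max(fixtureEdges$AS) + 1)
  expect_equal(max(ssnClusters(gHigh)), length(fixtureSeqs))
})

test_that("raising the threshold never decreases the component count", {
  set.seed(55)
  for (rep in 1:5) {
    n <- 10
    ids <- paste0("n", 1:n)
    pairs <- t(combn(ids, 2))
    keep <- runif(nrow(pairs)) < 0.4
    e <- data.frame(id_a = pairs[keep, 1], id_b = pairs[keep, 2],
                    AS = runif(sum(keep), 0, 100))
    counts <- vapply(seq(0, 110, by = 10), function(th)
      max(ssnClusters(buildSSN(e, th, nodeIds = ids))), integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("cluster membership is invariant to edge order", {
  e <- fixtureEdges
  set.seed(1)
  eShuf <- e[sample(nrow(e)), ]
  th <- (maxInter + minIntra) / 2
  expect_identical(ssnClusters(buildSSN(e, th)),
                   ssnClusters(buildSSN(eShuf, th)))
})

test_that("centralities match closed forms and brute-force enumeration", {
  # path graph a-b-c: betweenness (0, 1, 0) in unnormalised pair counts
  path <- data.frame(id_a = c("a", "b"), id_b = c("b", "c"), AS = 1)
  cp <- centralityProfile(buildSSN(path, 0))
  expect_equal(cp$betweenness[cp$id == "b"], 1)
  expect_equal(cp$betweenness[cp$id %in% c("a", "c")], c(0, 0))

  # complete graph K4: all betweenness 0
  k4 <- t(combn(letters[1:4], 2))
  cpK4 <- centralityProfile(
    buildSSN(data.frame(id_a = k4[, 1], id_b = k4[, 2], AS = 1), 0))
  expect_equal(cpK4$betweenness, rep(0, 4))
  expect_equal(cpK4$degree, rep(3, 4))

  # random graphs up to 12 nodes: exhaustive shortest-path enumeration
  set.seed(77)
  for (rep in 1:4) {
    n <- sample(8:12, 1)
    ids <- paste0("v", seq_len(n))
    pairs <- t(combn(ids, 2))
    keep <- runif(nrow(pairs)) < 0.3
    if (sum(keep) < 2) next
    e <- data.frame(id_a = pairs[keep, 1], id_b = pairs[keep, 2], AS = 1)
    cp <- centralityProfile(buildSSN(e, 0, nodeIds = ids))
    oracle <- bfBetweenness(data.frame(from = e$id_a, to = e$id_b), ids)
    expect_equal(setNames(cp$betweenness, cp$id), oracle[cp$id],
                 tolerance = 1e-10)
  }
})

test_that("threshold selection lands between the family score ranges", {
  grid <- seq(5, 95, by = 5)
  sw <- selectThreshold(fixtureEdges, grid, nodeIds = names(fixtureSeqs))
  expect_s4_class(sw, "ThresholdSweep")
  expect_equal(sw@status, "ok")
  sel <- selectedThreshold(sw)
  expect_gt(sel, maxInter)
  expect_lt(sel, minIntra)
  tab <- sweepTable(sw)
  expect_equal(nrow(tab), length(grid))
  # cluster counts never decrease along the sweep
  expect_true(all(diff(tab$n_clusters) >= 0))
})

test_that("degenerate and trivial sweeps behave as specified", {
  # single clique: plateau everywhere, selected = grid minimum
  k5 <- t(combn(paste0("q", 1:5), 2))
  clique <- data.frame(id_a = k5[, 1], id_b = k5[, 2], AS = 50)
  sw <- selectThreshold(clique, c(10, 20, 30))
  expect_equal(selectedThreshold(sw), 10)

  # no edges anywhere: selected = none with degenerate status
  empty <- data.frame(id_a = character(), id_b = character(),
                      AS = numeric())
  sw2 <- selectThreshold(empty, c(1, 2, 3), nodeIds = paste0("z", 1:4))
  expect_true(is.na(selectedThreshold(sw2)))
  expect_equal(sw2@status, "degenerate")

  expect_error(selectThreshold(clique, c(1, 2)), "grid")
  expect_error(selectThreshold(clique, c(3, 2, 1)), "grid")
})

test_that("annotated networks export and round-trip through XGMML", {
  th <- (maxInter + minIntra) / 2
  g <- buildSSN(fixtureEdges, th)
  meta <- data.frame(id = names(fixtureSeqs),
                     taxonomy = S4Vectors::mcols(fixtureSeqs)$taxonomy)
  out <- annotateAndExport(g, meta, scheme = "taxonomy",
                           path = file.path(tempdir(), "ssn_test"))
  expect_true(all(file.exists(out)))

  # GraphML readable by igraph with attributes intact
  gml <- igraph::read_graph(out[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(gml), length(fixtureSeqs))

  # XGMML round-trip: same topology, labels and AS values
  back <- readXGMML(out[["xgmml"]])
  expect_equal(igraph::vcount(back), igraph::vcount(g@graph))
  expect_equal(igraph::ecount(back), igraph::ecount(g@graph))
  expect_setequal(igraph::V(back)$name, igraph::V(g@graph)$name)
  expect_setequal(round(igraph::E(back)$AS, 6),
                  round(igraph::edge_attr(g@graph, "AS"), 6))
  # two taxa -> two colour classes
  expect_length(unique(igraph::V(back)$fillColor[
    igraph::V(back)$label != "unannotated"]), 2L)

  # metadata id collisions are an error
  bad <- rbind(meta, meta[1, ])
  expect_error(annotateAndExport(g, bad, "taxonomy",
                                 file.path(tempdir(), "x")),
               "collision")
})
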