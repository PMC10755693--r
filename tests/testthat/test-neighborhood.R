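rules <- loadPathwayRules()

# small hand-built feature table helper
featTable <- function(tags, contig = "c1") {
  n <- length(tags)
  starts <- seq(1, by = 1000, length.out = n)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(contig, n),
    ranges = IRanges::IRanges(start = starts, end = starts + 800),
    strand = rep("+", n))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    locus_id = sprintf("L%03d", seq_len(n)), domain_tags = tags,
    product = tags, genome_id = rep("hand", n))
  gr
}

test_that("neighbourhood extraction windows correctly, even at contig edges", {
  g <- makeGenome("none", nBackground = 24, seed = 61, genomeId = "w")
  mid <- g$locus_id[13]
  nb <- extractNeighborhood(g, mid, k = 10)
  expect_equal(length(nb), 21L)                   # 2k + 1
  expect_equal(nb@seed, mid)

  # seed 4th from the contig end: 3 downstream + up to 10 upstream + seed
  edgeLocus <- g$locus_id[order(BiocGenerics::start(g))][22]
  nbEdge <- extractNeighborhood(g, edgeLocus, k = 10)
  expect_equal(length(nbEdge), 3 + 10 + 1)

  expect_error(extractNeighborhood(g, "missing_locus"), "not found")

  # the window is positional: flipping every strand changes nothing
  gFlip <- g
  BiocGenerics::strand(gFlip) <- ifelse(
    as.character(BiocGenerics::strand(g)) == "+", "-", "+")
  nbF <- extractNeighborhood(gFlip, mid, k = 10)
  expect_identical(nbF@features$locus_id, nb@features$locus_id)
})

test_that("signature tags classify to their pathway with SQase flags", {
  emp <- featTable(c("GH188", "SQ_isomerase", "SF_kinase", "SFP_aldolase",
                     "SLA_dehydrogenase", "DUF1234"))
  call <- classifyNeighborhood(emp, rules)
  expect_equal(pathwayLabel(call), "sulfo-EMP")
  expect_true(call@gh188Present)
  expect_false(call@gh31Present)
  expect_setequal(names(call@matchedLoci),
                  c("isomerase", "kinase", "aldolase", "dehydrogenase"))

  # empty neighbourhood
  expect_equal(pathwayLabel(classifyNeighborhood(featTable(character(0)),
                                                 rules)),
               "unclassified")

  # GH31 flag
  withGh31 <- featTable(c("GH31", "SQ_monooxygenase"))
  c31 <- classifyNeighborhood(withGh31, rules)
  expect_true(c31@gh31Present)
  expect_equal(pathwayLabel(c31), "sulfo-SMO")
})

test_that("removing any required group defeats the classification", {
  sig <- list(
    "sulfo-EMP" = c("SQ_isomerase", "SF_kinase", "SFP_aldolase",
                    "SLA_dehydrogenase"),
    "sulfo-ED" = c("SQ_dehydrogenase", "SGL_lactonase", "SG_dehydratase",
                   "KDSG_aldolase"),
    "sulfo-SMO" = "SQ_monooxygenase")
  for (pw in names(sig)) {
    tags <- sig[[pw]]
    expect_equal(pathwayLabel(classifyNeighborhood(featTable(tags),
                                                   rules)), pw)
    for (drop in seq_along(tags)) {
      call <- classifyNeighborhood(featTable(tags[-drop]), rules)
      expect_equal(pathwayLabel(call), "unclassified",
                   label = paste(pw, "without", tags[drop]))
    }
  }
})

test_that("classification is invariant to gene order and strand flips", {
  tags <- c("DUF9", "SQ_isomerase", "SF_kinase", "SFP_aldolase",
            "SLA_dehydrogenase", "GH188")
  base <- featTable(tags)
  set.seed(3)
  perm <- base[sample(length(base))]
  expect_equal(pathwayLabel(classifyNeighborhood(perm, rules)),
               "sulfo-EMP")
  flipped <- base
  BiocGenerics::strand(flipped) <- "-"
  expect_equal(pathwayLabel(classifyNeighborhood(flipped, rules)),
               "sulfo-EMP")
})

test_that("generated genomes round-trip through the classifier", {
  pathways <- c("sulfo-EMP", "sulfo-ED", "sulfo-SFT", "sulfo-SMO",
                "sulfo-SDO")
  for (i in seq_along(pathways)) {
    g <- makeGenome(pathways[i], nBackground = 24, seed = 70 + i)
    nb <- extractNeighborhood(g, S4Vectors::metadata(g)$seed_locus)
    expect_equal(pathwayLabel(classifyNeighborhood(nb, rules)),
                 pathways[i])
  }
  gNone <- makeGenome("none", nBackground = 50, seed = 99)
  nb0 <- extractNeighborhood(gNone, S4Vectors::metadata(gNone)$seed_locus)
  expect_equal(pathwayLabel(classifyNeighborhood(nb0, rules)),
               "unclassified")
})

test_that("cohort reports tabulate pathway by SQase family", {
  genomes <- lapply(1:10, function(i)
    makeGenome("sulfo-SMO", nBackground = 20, seed = 300 + i,
               includeGH31 = FALSE, genomeId = paste0("smo", i)))
  names(genomes) <- paste0("smo", 1:10)
  rep <- cohortReport(genomes)
  expect_equal(nrow(rep$calls), 10L)
  row <- rep$summary[rep$summary$pathway == "sulfo-SMO" &
                       rep$summary$sqase == "gh188-only", ]
  expect_equal(row$n, 10L)

  # empty cohort: empty table, no error
  rep0 <- cohortReport(list())
  expect_equal(nrow(rep0$calls), 0L)

  # per-genome failures are reported, not fatal
  bad <- genomes[1:2]
  repBad <- cohortReport(bad, seeds = c("nope", bad[[2]]$locus_id[11]))
  expect_equal(repBad$calls$pathway[1], "error")
  expect_false(repBad$calls$pathway[2] == "error")
})

test_that("feature tables round-trip through GFF3", {
  g <- makeGenome("sulfo-SFT", nBackground = 15, seed = 88,
                  genomeId = "gff")
  f <- tempfile(fileext = ".gff3")
  writeFeaturesGFF3(g, f)
  g2 <- readFeaturesGFF3(f)
  expect_equal(length(g2), length(g))
  expect_identical(g2$locus_id, g$locus_id)
  expect_identical(g2$domain_tags, g$domain_tags)
  expect_equal(BiocGenerics::start(g2), BiocGenerics::start(g))
  expect_equal(BiocGenerics::end(g2), BiocGenerics::end(g))
  expect_identical(as.character(BiocGenerics::strand(g2)),
                   as.character(BiocGenerics::strand(g)))

  # and the re-read table still classifies
  nb <- extractNeighborhood(g2, g$locus_id[match("sqgA", g$product)])
  expect_equal(pathwayLabel(classifyNeighborhood(nb, rules)), "sulfo-SFT")
})
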