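test_that("profile construction matches hand-computed log-odds", {
  # two sequences, three columns, pseudocount 0.5 — worked by hand from
  # f = (c + 0.5 p) / (N + 0.5), score = log2(f / p)
  p <- buildProfile(c(a = "ACD", b = "AVD"))
  s <- unname(profileScores(p))
  expect_equal(s[1, 1], 3.385409, tolerance = 1e-6)   # A observed twice
  expect_equal(s[2, 5], 4.390889, tolerance = 1e-6)   # C observed once
  expect_equal(s[2, 20], 2.680373, tolerance = 1e-6)  # V observed once
  expect_equal(s[2, 1], -2.321928, tolerance = 1e-6)  # A unobserved
  expect_equal(s[3, 4], 3.917837, tolerance = 1e-6)   # D observed twice
})

test_that("identical sequences give profiles peaked on the observed residue", {
  msa <- rep("MKVLA", 4)
  names(msa) <- paste0("s", 1:4)
  p <- buildProfile(msa)
  top <- colnames(profileScores(p))[apply(profileScores(p), 1,
                                          which.max)]
  expect_equal(top, c("M", "K", "V", "L", "A"))
})

test_that("columns with more than half gaps are masked", {
  msa <- c(a = "AC-D", b = "AC-D", c = "ACWD", d = "AC-D")
  p <- buildProfile(msa)            # column 3 is 75% gaps
  expect_equal(length(p), 3L)
  expect_equal(p@keptColumns, c(1L, 2L, 4L))

  expect_error(buildProfile(c(a = "AC", b = "ACD")), "ragged")
  expect_error(buildProfile(c(a = "A-", b = "A-")), "all-gap")
  expect_error(buildProfile(c(a = "ACD")), "at least two")
})

test_that("profile search separates a family from shuffled decoys", {
  fam <- makeFamily(10, 80, 150, seed = 31, prefix = "fam")
  dec <- makeDecoys(fam, 60, seed = 32)
  db <- c(fam, dec)
  prof <- buildProfile(as.character(fam[1:4]))
  hits <- profileSearch(prof, db, evalueCutoff = 1e-3, nCalibrate = 100)
  expect_setequal(hits$target_id, names(fam))      # full recall, no decoys

  # E-values sorted ascending, spans are 1-based and sane
  expect_true(all(diff(hits$evalue) >= 0))
  expect_true(all(hits$span_start >= 1 & hits$span_end <= 150))

  # cutoff 0 retains nothing
  expect_equal(nrow(profileSearch(prof, db, evalueCutoff = 0,
                                  nCalibrate = 100)), 0L)

  # determinism of identical runs
  hits2 <- profileSearch(prof, db, evalueCutoff = 1e-3, nCalibrate = 100)
  expect_identical(hits, hits2)
})

test_that("the seed sequence is its own best hit", {
  fam <- makeFamily(3, 90, 100, seed = 35)
  db <- fam[1]
  prof <- buildProfile(setNames(rep(as.character(fam[[1]]), 2),
                                c(names(fam)[1], "copy")))
  hits <- profileSearch(prof, db, evalueCutoff = 1, nCalibrate = 60)
  expect_equal(hits$target_id[1], names(fam)[1])
})

test_that("iteration reaches a stable set that is a fixed point", {
  fam <- makeFamily(12, 80, 150, seed = 41, prefix = "fam")
  dec <- makeDecoys(fam, 60, seed = 42)
  db <- c(fam, dec)
  seedMsa <- as.character(fam[1:4])
  res <- iterateProfileSearch(seedMsa, db, evalueCutoff = 1e-3,
                              maxIters = 8, nCalibrate = 100)
  expect_equal(res$status, "converged")
  expect_setequal(res$ids, names(fam))
  expect_lte(res$n_iterations, 3L)

  # fixed point: searching again with the final profile returns the set
  again <- profileSearch(res$profile, db, evalueCutoff = 1e-3,
                         nCalibrate = 100)
  expect_setequal(again$target_id, res$ids)

  # seed-only database is a one-iteration fixed point
  solo <- iterateProfileSearch(as.character(fam[1:4]), fam[1:4],
                               evalueCutoff = 1e-2, maxIters = 5,
                               nCalibrate = 60)
  expect_equal(solo$status, "converged")
  expect_equal(solo$n_iterations, 1L)
  expect_setequal(solo$ids, names(fam)[1:4])

  # maxIters = 1 with a changing set reports non-convergence
  one <- iterateProfileSearch(setNames(as.character(fam[1:4]),
                                       c("q1", "q2", "q3", "q4")),
                              db, evalueCutoff = 1e-3, maxIters = 1,
                              nCalibrate = 100)
  expect_equal(one$status, "not converged")
  expect_equal(one$n_iterations, 1L)
})

test_that("E-value calibration is conservative on pure-decoy databases", {
  fam <- makeFamily(6, 85, 120, seed = 51)
  prof <- buildProfile(as.character(fam))
  cutoff <- 1
  nHits <- vapply(1:50, function(s) {
    db <- makeDecoys(fam, 30, seed = 1000 + s)
    nrow(profileSearch(prof, db, evalueCutoff = cutoff, nCalibrate = 60,
                       calibrationSeed = 2000 + s))
  }, numeric(1))
  expect_lte(mean(nHits), 2 * cutoff)
})
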