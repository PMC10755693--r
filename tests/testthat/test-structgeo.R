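test_that("atomic distances are exact and symmetric", {
  toy <- makeToyStructure("sphere-pair", separation = 3.4)
  d12 <- atomDistance(toy, list(eleno = 1), list(eleno = 2))
  expect_equal(d12, 3.4)
  expect_equal(atomDistance(toy, list(eleno = 2), list(eleno = 1)), d12)
  expect_error(atomDistance(toy, list(chain = "A"), list(eleno = 1)),
               "exactly one")
})

test_that("side-chain rotation recovers constructed chi1 differences", {
  same <- makeToyStructure("rotated-copy", angle = 0)
  expect_equal(sidechainRotation(same$reference, same$rotated, "A", 1), 0,
               tolerance = 1e-8)
  rc <- makeToyStructure("rotated-copy", angle = 72)
  expect_equal(sidechainRotation(rc$reference, rc$rotated, "A", 1), 72,
               tolerance = 1e-6)
  # the circle convention maps 200 degrees to 160
  big <- makeToyStructure("rotated-copy", angle = 200)
  expect_equal(sidechainRotation(big$reference, big$rotated, "A", 1), 160,
               tolerance = 1e-6)
  expect_error(sidechainRotation(rc$reference, rc$rotated, "B", 1),
               "lacks")
})

test_that("superposition RMSD is zero under rigid motion and matches the quaternion oracle", {
  hd <- makeToyStructure("helix-dimer")
  expect_equal(superposeRmsd(hd, hd)$rmsd, 0, tolerance = 1e-10)

  # rigidly moved copy
  a <- atomData(hd)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + 12; a$y <- xyz[, 2] - 7; a$z <- xyz[, 3] + 3
  moved <- new("Structure", atoms = a, title = "moved")
  expect_equal(superposeRmsd(hd, moved)$rmsd, 0, tolerance = 1e-9)

  # random perturbed sets: Kabsch equals Horn's quaternion eigen-solution
  set.seed(23)
  for (rep in 1:8) {
    n <- 5
    X <- matrix(rnorm(3 * n, sd = 4), ncol = 3)
    Y <- X + matrix(rnorm(3 * n, sd = 0.6), ncol = 3)
    mk <- function(M) new("Structure", atoms = data.frame(
      eleno = 1:n, elety = "CA", elesy = "C", resid = "GLY", chain = "A",
      resno = 1:n, x = M[, 1], y = M[, 2], z = M[, 3], o = 1,
      het = FALSE), title = "rand")
    res <- superposeRmsd(mk(X), mk(Y))
    expect_equal(res$rmsd, quatRmsd(X, Y), tolerance = 1e-8)
    expect_equal(det(res$rotation), 1, tolerance = 1e-10)
  }
  expect_error(superposeRmsd(makeToyStructure("sphere-pair"),
                             makeToyStructure("sphere-pair")),
               "common residues")
})

test_that("SASA matches the closed form, is additive, and detects burial", {
  one <- makeToyStructure("single-atom")
  expect_equal(sasa(one)$total, 4 * pi * (1.70 + 1.4)^2,
               tolerance = 0.005)

  # two far-separated atoms: areas add
  far <- makeToyStructure("sphere-pair", separation = 50)
  expect_equal(sasa(far)$total, 2 * 4 * pi * (1.70 + 1.4)^2,
               tolerance = 0.005)

  # a fully caged atom has zero accessible surface
  cage <- makeToyStructure("cage")
  expect_equal(sasa(cage)$per_atom[1], 0)

  # lattice-size convergence: 960 points within 1% of 10^4 points
  hd <- makeToyStructure("helix-dimer")
  s960 <- sasa(hd, nPoints = 960)$total
  s1e4 <- sasa(hd, nPoints = 10000)$total
  expect_lt(abs(s960 - s1e4) / s1e4, 0.01)

  # rigid rotation changes the estimate only within lattice noise
  a <- atomData(hd)
  th <- 0.6
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3,
              byrow = TRUE)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  rot <- new("Structure", atoms = a, title = "rot")
  expect_lt(abs(sasa(rot)$total - s960) / s960, 0.005)

  expect_error(sasa(makeToyStructure("single-atom",
                                     radiusElement = "Zz")),
               "no radius")
})

test_that("interface burial matches a dense Monte-Carlo oracle", {
  hd <- makeToyStructure("helix-dimer", separation = 6)
  ir <- interfaceReport(hd, "A", "B")
  expect_gt(ir@buriedTotal, 0)

  # non-touching chains bury nothing
  apart <- makeToyStructure("helix-dimer", separation = 60)
  expect_equal(interfaceReport(apart, "A", "B")@buriedTotal, 0,
               tolerance = 1e-9)

  # dense random-direction sampling oracle (different point set and code)
  sub <- function(s, ch) new("Structure",
                             atoms = atomData(s)[atomData(s)$chain %in% ch, ],
                             title = "sub")
  oracleBuried <- mcSasa(sub(hd, "A")) + mcSasa(sub(hd, "B")) -
    mcSasa(hd)
  expect_lt(abs(ir@buriedTotal - oracleBuried) / oracleBuried, 0.02)

  expect_error(interfaceReport(hd, "A", "Z"), "chain missing")
})

test_that("structures round-trip through PDB and mmCIF identically", {
  hd <- makeToyStructure("helix-dimer")
  fp <- tempfile(fileext = ".pdb")
  fc <- tempfile(fileext = ".cif")
  writeStructurePDB(hd, fp)
  writeStructureCIF(hd, fc)
  sp <- readStructure(fp)
  sc <- readStructure(fc)
  a0 <- atomData(hd)
  for (s in list(sp, sc)) {
    a <- atomData(s)
    expect_equal(nrow(a), nrow(a0))
    expect_equal(a$x, a0$x, tolerance = 1e-3)
    expect_equal(a$y, a0$y, tolerance = 1e-3)
    expect_equal(a$z, a0$z, tolerance = 1e-3)
    expect_identical(a$chain, a0$chain)
    expect_identical(a$resno, a0$resno)
  }
  expect_equal(atomData(sp)[, c("x", "y", "z")],
               atomData(sc)[, c("x", "y", "z")], tolerance = 1e-6)
})

test_that("alternate locations resolve to the highest occupancy and waters drop", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "HETATM    4  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- readStructure(f)
  a <- atomData(s)
  expect_equal(nrow(a), 2L)               # water dropped, one CA kept
  expect_equal(a$x[a$elety == "CA"], 1.0) # the 0.60-occupancy conformer
  sWat <- readStructure(f, keepWaters = TRUE)
  expect_equal(nrow(atomData(sWat)), 3L)
})
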