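sq <- chemFormula("C6H12O8S")          # sulfoquinovose
sqgro <- chemFormula("C9H18O10S")      # sulfoquinovosyl glycerol

test_that("nominal anion masses match the instrument-nominal values", {
  expect_equal(formulaMass(deprotonate(sq), "nominal"), 243)
  expect_equal(formulaMass(deprotonate(sqgro), "nominal"), 317)
  expect_equal(formulaMass(chemFormula(""), "nominal"), 0)
})

test_that("monoisotopic masses match the element-mass summation oracle", {
  # reference values computed independently from IUPAC isotope masses
  expect_equal(formulaMass(deprotonate(sq), "monoisotopic"),
               243.018012, tolerance = 1e-5)
  expect_equal(formulaMass(deprotonate(sqgro), "monoisotopic"),
               317.054791, tolerance = 1e-5)
  expect_equal(formulaMass(deprotonate(deuterate(sq, 1)), "monoisotopic"),
               244.024289, tolerance = 1e-5)
  expect_equal(formulaMass(chemFormula("C4H7O6S", charge = -1L),
                           "monoisotopic"), 182.996883, tolerance = 1e-5)
  expect_equal(formulaMass(chemFormula("C3H5O5S", charge = -1L),
                           "monoisotopic"), 152.986318, tolerance = 1e-5)
  expect_equal(formulaMass(chemFormula("C2H3O4S", charge = -1L),
                           "monoisotopic"), 122.975753, tolerance = 1e-5)
})

test_that("mass is additive over formula union in both modes", {
  set.seed(13)
  for (k in 1:10) {
    c1 <- setNames(sample(0:6, 6, TRUE), c("C", "H", "D", "N", "O", "S"))
    c2 <- setNames(sample(0:6, 6, TRUE), c("C", "H", "D", "N", "O", "S"))
    f1 <- chemFormula(c1)
    f2 <- chemFormula(c2)
    f12 <- chemFormula(c1 + c2)
    for (mode in c("nominal", "monoisotopic"))
      expect_equal(formulaMass(f12, mode),
                   formulaMass(f1, mode) + formulaMass(f2, mode),
                   tolerance = 1e-10)
  }
  expect_error(chemFormula("C2Zn"), "unknown element")
})

test_that("deuteration shifts the nominal mass by exactly n", {
  expect_equal(formulaMass(deprotonate(deuterate(sq, 1)), "nominal"), 244)
  expect_identical(formulaCounts(deuterate(sq, 0)), formulaCounts(sq))
  expect_error(deuterate(chemFormula("C2H2O"), 3), "only 2 H")
  set.seed(14)
  for (k in 1:5) {
    f <- chemFormula(setNames(c(sample(1:5, 1), sample(2:9, 1), 0,
                                sample(0:3, 1), sample(0:5, 1),
                                sample(0:2, 1)),
                              c("C", "H", "D", "N", "O", "S")))
    expect_equal(formulaMass(deuterate(f, 1), "nominal") -
                   formulaMass(f, "nominal"), 1)
  }
})

test_that("neutral losses reproduce the 244 -> 207 and 243 -> 207 products", {
  labelled <- fragmentIon("[M-H]-", deprotonate(deuterate(sq, 1)),
                          paste0("C", 1:6))
  expect_equal(formulaMass(labelled@formula, "nominal"), 244)
  prod <- applyLosses(labelled, list("HDO", "H2O"))
  expect_equal(formulaMass(prod@formula, "nominal"), 207)

  unlabelled <- fragmentIon("[M-H]-", deprotonate(sq), paste0("C", 1:6))
  prod0 <- applyLosses(unlabelled, list("H2O", "H2O"))
  expect_equal(formulaMass(prod0@formula, "nominal"), 207)

  # identity and underflow
  expect_identical(formulaCounts(applyLosses(labelled, list())@formula),
                   formulaCounts(labelled@formula))
  expect_error(applyLosses(labelled, list("N2")), "negative")
})

test_that("deuteration and losses commute when the loss misses the label", {
  f <- chemFormula("C6H12O8S")
  lossThenLabel <- deuterate(chemFormula(formulaCounts(f) -
                                           formulaCounts(chemFormula("H2O"))),
                             1)
  labelThenLoss <- applyLosses(fragmentIon("x", deuterate(f, 1),
                                           "C1"), list("H2O"))@formula
  expect_identical(formulaCounts(lossThenLabel),
                   formulaCounts(labelThenLoss))
})

test_that("the reference observation pattern localises the label to C2", {
  frags <- sqFragmentIons()
  frags$product207 <- frags$molecular
  obs <- rbind(
    labelObservation("[M-H]-", 1),
    labelObservation("frag183", 0),
    labelObservation("frag153", 0),
    labelObservation("frag123", 0),
    labelObservation("product207", 0,
                     lossCarbons = c("C2", "C3", "C4", "C5")))
  res <- inferLabelPosition(frags, obs)
  expect_equal(res$feasible, "C2")
  expect_equal(res$status, "ok")
  expect_equal(bfLabelFeasible(frags, obs), "C2")
})

test_that("degenerate observation sets report their status", {
  frags <- sqFragmentIons()
  res <- inferLabelPosition(frags, labelObservation("frag123", 0))
  expect_equal(res$status, "no label detected")
  expect_length(res$feasible, 0L)

  # contradictory: molecular ion shifted but every carbon excluded
  all6 <- fragmentIon("all", chemFormula("C6H11O8S", charge = -1L),
                      paste0("C", 1:6))
  obs <- rbind(labelObservation("[M-H]-", 1), labelObservation("all", 0))
  res2 <- inferLabelPosition(c(sqFragmentIons(), list(all = all6)), obs)
  expect_equal(res2$status, "inconsistent")

  expect_error(inferLabelPosition(sqFragmentIons(),
                                  labelObservation("nope", 1)),
               "unknown fragment")
  expect_error(labelObservation("x", 2), "0 or 1")
})

test_that("inference equals brute-force hypothesis testing on random panels", {
  carbons <- paste0("C", 1:6)
  set.seed(19)
  for (rep in 1:25) {
    planted <- sample(carbons, 1)
    nFrag <- sample(2:5, 1)
    frags <- lapply(seq_len(nFrag), function(i)
      fragmentIon(paste0("f", i), chemFormula("C3H5O5S", charge = -1L),
                  sample(carbons, sample(1:5, 1))))
    names(frags) <- paste0("f", seq_len(nFrag))
    frags$mol <- fragmentIon("mol", chemFormula("C6H11O8S", charge = -1L),
                             carbons)
    obs <- do.call(rbind, lapply(names(frags), function(nm) {
      cov <- frags[[nm]]@coverage
      labelObservation(nm, as.integer(planted %in% cov))
    }))
    res <- inferLabelPosition(frags, obs)
    oracle <- bfLabelFeasible(frags, obs)
    expect_setequal(res$feasible, oracle)
    expect_true(planted %in% res$feasible)
  }
})
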