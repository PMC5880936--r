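# Half-reaction registry, dechlorination ladder and unit conversions.

test_that("registry returns the ladder's electron equivalents per mole", {
  expect_identical(eeqPerMol("ferrous_iron"), 1L)
  expect_identical(eeqPerMol("sulfide"), 8L)
  expect_identical(eeqPerMol("methane_acetoclastic"), 8L)
  expect_identical(eeqPerMol("methane_hydrogenotrophic"), 8L)
  expect_identical(eeqPerMol("TeCP"), 2L)
  expect_identical(eeqPerMol("TCP"), 4L)
  expect_identical(eeqPerMol("DCP"), 6L)
  expect_error(eeqPerMol("nitrate"), "unknown redox couple")
})

test_that("every registry half reaction is charge balanced", {
  for (hr in halfReactionRegistry()) {
    expect_true(validObject(hr, test = TRUE) == TRUE ||
                  isTRUE(validObject(hr, test = TRUE)), info = hr@name)
    expect_equal(hr@oxidizedCharge + hr@protons - hr@electrons,
                 hr@reducedCharge, info = hr@name)
  }
})

test_that("dechlorination electrons follow 2 x (Cl removed) and are additive", {
  expect_identical(dechlorinationEeq("PCP", "PCP"), 0L)
  expect_identical(dechlorinationEeq("PCP", "TeCP_2345"), 2L)
  expect_identical(dechlorinationEeq("PCP", "TCP_345"), 4L)
  expect_identical(dechlorinationEeq("PCP", "DCP_35"), 6L)
  expect_error(dechlorinationEeq("TCP_345", "PCP"), "more chlorinated")
  # additivity along every ladder path
  ladder <- chlorophenolLadder()$species
  for (i in seq_along(ladder)) for (j in i:length(ladder)) for (k in j:length(ladder)) {
    expect_identical(dechlorinationEeq(ladder[i], ladder[k]),
                     dechlorinationEeq(ladder[i], ladder[j]) +
                       dechlorinationEeq(ladder[j], ladder[k]))
  }
  # ladder metadata: strictly decreasing Cl, ~34.44 g/mol per Cl->H step
  expect_true(all(diff(chlorophenolLadder()$chlorines) == -1L))
  expect_equal(diff(chlorophenolLadder()$molarMass),
               rep(-34.445, 3), tolerance = 0.001)
})

test_that("mass-to-micromoles conversion is exact, linear and invertible", {
  mw <- molarMasses()
  expect_equal(massToMicromoles(0.40, "mg_per_g", mw[["SO4"]]),
               0.40 * 15 * 1000 / 96.06)
  expect_equal(massToMicromoles(20, "ug_per_g", mw[["PCP"]]),
               20 * 15 / 266.34)
  expect_equal(massToMicromoles(0, "ug_per_g", mw[["PCP"]]), 0)
  # linear in concentration and soil mass
  g2 <- bottleGeometry(soilMass = 30)
  expect_equal(massToMicromoles(4.2, "mg_per_g", mw[["Fe"]]) * 2,
               massToMicromoles(8.4, "mg_per_g", mw[["Fe"]]))
  expect_equal(massToMicromoles(4.2, "mg_per_g", mw[["Fe"]], g2),
               2 * massToMicromoles(4.2, "mg_per_g", mw[["Fe"]]))
  # round trip to 1e-9 relative
  for (v in c(0.001, 0.5, 7, 123)) {
    um <- massToMicromoles(v, "mg_per_g", mw[["SO4"]])
    expect_equal(micromolesToMass(um, "mg_per_g", mw[["SO4"]]), v,
                 tolerance = 1e-9)
  }
})

test_that("headspace permil conversion respects the calibrated gas basis", {
  expect_equal(permilToMicromoles(0), 0)
  expect_equal(permilToMicromoles(169.1), 169.1)
  expect_equal(permilToMicromoles(169.1,
                                  bottleGeometry(headspaceGasBasis = 500)),
               84.55)
  expect_error(permilToMicromoles(1500), "\\[0, 1000\\]")
  # 4.34 permil at 8 e-/mol -> 34.7 umol e-, within 0.5% of 34.56
  expect_equal(permilToMicromoles(4.34) * 8, 34.56, tolerance = 0.005)
})

test_that("the printed permil/micromole pairs imply the adopted 1000 umol basis", {
  # solve basis from each printed (permil, umol e-) pair at 8 e-/mol CH4
  basisBiochar <- 1351.80 / 8 / 169.1 * 1000
  basisControl <- 34.56 / 8 / 4.34 * 1000
  expect_equal(basisBiochar, 1000, tolerance = 0.005)
  expect_equal(basisControl, 1000, tolerance = 0.005)
})

test_that("bottle geometry validity catches impossible bottles", {
  expect_error(bottleGeometry(soilMass = -1), "positive")
  expect_error(bottleGeometry(waterVolume = 200), "smaller than bottleVolume")
})
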