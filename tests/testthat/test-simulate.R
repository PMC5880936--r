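# Synthetic endpoint and community generators.

test_that("a noiseless simulation round-trips through the ledger exactly", {
  sim <- simulateIncubation(seed = 1, noiseCv = 0)
  led <- computeLedgers(sim$endpoints)
  truth <- sim$truth[sim$truth$group != "sterile_abiotic", ]
  comp <- c("e_fe", "e_so4", "e_dechlor", "e_ch4", "e_total")
  expect_equal(as.matrix(led[comp]), as.matrix(truth[comp]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("sterile bottles release no methane and carry no products", {
  sim <- simulateIncubation(seed = 2)
  sterile <- sim$endpoints[sim$endpoints$group == "sterile_abiotic", ]
  expect_true(all(sterile$ch4_permil == 0))
  expect_true(all(sterile$tecp_ug_g == 0 & sterile$tcp_ug_g == 0 &
                    sterile$dcp_ug_g == 0))
})

test_that("hidden truth conserves the component sum", {
  sim <- simulateIncubation(seed = 3)
  expect_equal(sim$truth$e_total,
               with(sim$truth, e_fe + e_so4 + e_dechlor + e_ch4))
})

test_that("molybdate halves the simulated total electron budget", {
  sim <- simulateIncubation(seed = 4)
  led <- suppressWarnings(computeLedgers(sim$endpoints))
  mTot <- mean(led$e_total[led$group == "biotic_molybdate"])
  bTot <- mean(led$e_total[led$group == "biotic"])
  expect_equal(mTot / bTot, 0.493, tolerance = 0.1)
})

test_that("simulation is reproducible under a fixed seed", {
  a <- simulateIncubation(seed = 5)
  b <- simulateIncubation(seed = 5)
  expect_identical(a, b)
  ca <- simulateCommunity(seed = 5, communityConfig(nOtus = 40))
  cb <- simulateCommunity(seed = 5, communityConfig(nOtus = 40))
  expect_identical(otuCounts(ca), otuCounts(cb))
  expect_identical(otuTree(ca)$edge.length, otuTree(cb)$edge.length)
})

test_that("community counts track the configured proportions at high depth", {
  cfg <- communityConfig(nOtus = 60, depth = 50000, theta = 1e5)
  oe <- simulateCommunity(seed = 6, cfg)
  cd <- as.data.frame(SummarizedExperiment::colData(oe))
  ctrl <- otuCounts(oe)[, cd$group == "biotic" & cd$amendment == "control"]
  fam <- taxonomyTable(oe)$family
  rel <- rowsum(rowMeans(sweep(ctrl, 2, colSums(ctrl), "/")), fam)
  for (f in c("Desulforudaceae", "Clostridiaceae", "SB-1"))
    expect_equal(unname(rel[f, 1]), unname(cfg$baseFamilies[f]),
                 tolerance = 0.25)
})

test_that("biochar enriches SB-1 as configured", {
  oe <- simulateCommunity(seed = 7)
  cd <- as.data.frame(SummarizedExperiment::colData(oe))
  ag <- aggregateTaxa(oe, "family", 0)
  sb <- ag$relAbundance["SB-1", ]
  expect_gt(mean(sb[cd$amendment == "biochar"]),
            2.5 * mean(sb[cd$amendment == "control"]))
})

test_that("an effect on an unknown taxon is a config error", {
  cfg <- communityConfig(nOtus = 40)
  cfg$effects$amendment$biochar <- c(Atlantisaceae = 2)
  expect_error(simulateCommunity(seed = 8, cfg), "unknown taxon")
})

test_that("a null community shows no group separation", {
  cfg <- communityConfig(nOtus = 50, depth = 20000)
  cfg$effects$amendment <- list(control = c(), AQDS = c(), biochar = c())
  cfg$effects$molybdate <- c()
  oe <- simulateCommunity(seed = 9, cfg)
  d <- generalizedUniFrac(oe, alpha = 0.5)
  cd <- as.data.frame(SummarizedExperiment::colData(oe))
  same <- d[cd$group == "biotic", cd$group == "biotic"]
  cross <- d[cd$group == "biotic", cd$group == "biotic_molybdate"]
  within <- mean(same[upper.tri(same)])
  between <- mean(cross)
  expect_equal(between / within, 1, tolerance = 0.15)
})
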