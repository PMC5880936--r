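# Abiotic baselines, per-bottle ledgers and the group summary with letters.

.bottle <- function(group = "biotic", amendment = "control", replicate = 1,
                    fe2 = 5, so4 = 0.74, ch4 = 0, pcp = 10, tecp = 0,
                    tcp = 0, dcp = 0) {
  data.frame(group = group, amendment = amendment, replicate = replicate,
             fe2_mg_g = fe2, sulfate_mg_g = so4, nitrate_mg_g = 0.02,
             ch4_permil = ch4, co2_permil = 0, pcp_ug_g = pcp,
             tecp_ug_g = tecp, tcp_ug_g = tcp, dcp_ug_g = dcp,
             ph = 8.5, eh_mv = -150, doc_mg_kg = 150, don_mg_kg = 15,
             stringsAsFactors = FALSE)
}

test_that("abiotic baseline pools or matches the sterile bottles", {
  eps <- rbind(.bottle("sterile_abiotic", "control", 1, fe2 = 4.4),
               .bottle("sterile_abiotic", "biochar", 1, fe2 = 6.8),
               .bottle("biotic", "control", 1, fe2 = 10))
  expect_equal(abioticBaseline(eps, "fe2_mg_g", "pooled"), 5.6)
  expect_equal(abioticBaseline(eps, "fe2_mg_g", "matched",
                               amendment = "biochar"), 6.8)
  # single sterile bottle: the baseline is its own value
  one <- rbind(.bottle("sterile_abiotic", "control", 1, fe2 = 5.1))
  expect_equal(abioticBaseline(one, "fe2_mg_g", "pooled"), 5.1)
  # matched with no matching sterile cell falls back to pooled, with warning
  expect_warning(
    bl <- abioticBaseline(eps, "fe2_mg_g", "matched", amendment = "AQDS"),
    "pooled")
  expect_equal(bl, 5.6)
  expect_error(abioticBaseline(.bottle(), "fe2_mg_g", "pooled"), "sterile")
})

test_that("sulfate drop 0.74 -> 0.34 mg/g over 15 g soil yields ~500 umol e-", {
  ep <- .bottle(so4 = 0.34, fe2 = 5)
  led <- computeLedger(ep, baselines = list(fe2_mg_g = 5, sulfate_mg_g = 0.74))
  expect_equal(led$e_so4, 0.40 * 15 * 1000 / 96.06 * 8)  # 499.7
  expect_equal(led$e_so4, 501, tolerance = 0.005)
})

test_that("dechlorination electrons come from accumulated products", {
  ep <- .bottle(tecp = 10, tcp = 0.5, fe2 = 5)
  led <- computeLedger(ep, baselines = list(fe2_mg_g = 5, sulfate_mg_g = 0.74))
  expect_equal(led$e_dechlor, 2 * 150 / 231.89 + 4 * 7.5 / 197.45,
               tolerance = 1e-9)
  expect_equal(led$e_dechlor, 1.446, tolerance = 1e-3)
})

test_that("endpoints at baseline give the all-zero ledger", {
  ep <- .bottle(fe2 = 5, so4 = 0.74, ch4 = 0)
  led <- computeLedger(ep, baselines = list(fe2_mg_g = 5, sulfate_mg_g = 0.74))
  expect_equal(unlist(led[c("e_fe", "e_so4", "e_dechlor", "e_ch4", "e_total")]),
               c(e_fe = 0, e_so4 = 0, e_dechlor = 0, e_ch4 = 0, e_total = 0))
})

test_that("ledger is linear in the deltas and conserves the total", {
  base <- list(fe2_mg_g = 5, sulfate_mg_g = 0.8)
  set.seed(11)
  for (i in 1:10) {
    dfe <- runif(1, 0, 8); dso <- runif(1, 0, 0.5); ch4 <- runif(1, 0, 300)
    tecp <- runif(1, 0, 12); tcp <- runif(1, 0, 1)
    l1 <- computeLedger(.bottle(fe2 = 5 + dfe, so4 = 0.8 - dso, ch4 = ch4,
                                tecp = tecp, tcp = tcp), base)
    l2 <- computeLedger(.bottle(fe2 = 5 + 2 * dfe, so4 = 0.8 - 2 * dso,
                                ch4 = 2 * ch4, tecp = 2 * tecp,
                                tcp = 2 * tcp), base)
    comp <- c("e_fe", "e_so4", "e_dechlor", "e_ch4")
    expect_equal(unlist(l2[comp]), 2 * unlist(l1[comp]), tolerance = 1e-12)
    expect_equal(l1$e_total, sum(unlist(l1[comp])), tolerance = 1e-9)
  }
})

test_that("negative deltas clip to zero with a warning; e_fe is monotone", {
  base <- list(fe2_mg_g = 5, sulfate_mg_g = 0.74)
  expect_warning(led <- computeLedger(.bottle(fe2 = 4.6), base), "clipped")
  expect_equal(led$e_fe, 0)
  # increasing measured Fe(II) never decreases e_fe
  fe <- seq(4, 12, by = 0.5)
  efe <- vapply(fe, function(v)
    suppressWarnings(computeLedger(.bottle(fe2 = v), base))$e_fe, numeric(1))
  expect_true(all(diff(efe) >= 0))
})

test_that("group summary suppresses statistics for degenerate cells", {
  d <- data.frame(group = "biotic",
                  amendment = rep(c("control", "AQDS", "biochar"), each = 3),
                  y = rep(5, 9))
  s <- summarizeGroups(d, "y")
  expect_true(all(is.na(s$F)))
  expect_true(all(s$letter == "a"))
})

test_that("well-separated amendments earn three distinct letters", {
  d <- data.frame(group = "biotic",
                  amendment = rep(c("control", "AQDS", "biochar"), each = 3),
                  y = c(1, 1.1, 0.9, 10, 10.1, 9.9, 20, 20.1, 19.9))
  s <- summarizeGroups(d, "y")
  expect_length(unique(s$letter), 3)
  expect_true(all(nchar(s$letter) == 1))
  expect_lt(s$p[1], 0.05)
})

test_that("letters agree with the pairwise Tukey tests on random fixtures", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    mu <- runif(k, 0, 6)
    g <- rep(letters[1:k], each = 4)
    y <- rnorm(length(g), mean = rep(mu, each = 4), sd = 1)
    s <- summarizeGroups(data.frame(group = "g", amendment = g, y = y), "y")
    pmat <- tukeyPairwiseP(y, g)
    lab <- setNames(s$letter, s$amendment)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      a <- levels(factor(g))[i]; b <- levels(factor(g))[j]
      share <- length(intersect(strsplit(lab[[a]], "")[[1]],
                                strsplit(lab[[b]], "")[[1]])) > 0
      if (pmat[a, b] < 0.05) {
        expect_false(share, label = sprintf("rep %d: %s/%s share a letter despite p=%.3g",
                                            rep, a, b, pmat[a, b]))
      } else {
        expect_true(share, label = sprintf("rep %d: %s/%s p=%.3g but disjoint letters",
                                           rep, a, b, pmat[a, b]))
      }
    }
  }
})
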