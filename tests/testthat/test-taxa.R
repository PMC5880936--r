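# Taxon aggregation with dominance thresholds.

test_that("a single shared family collapses to one row of abundance 1", {
  counts <- matrix(rpois(12, 20), 4, 3,
                   dimnames = list(paste0("o", 1:4), paste0("s", 1:3)))
  tax <- data.frame(family = rep("Clostridiaceae", 4), row.names = rownames(counts))
  ag <- aggregateTaxa(counts, "family", 0.02, taxonomy = tax)
  expect_equal(nrow(ag$counts), 1L)
  expect_equal(unname(ag$relAbundance[1, ]), rep(1, 3))
})

test_that("threshold zero preserves column sums and proportions sum to one", {
  set.seed(51)
  counts <- matrix(rpois(60, 10), 12, 5,
                   dimnames = list(paste0("o", 1:12), paste0("s", 1:5)))
  tax <- data.frame(family = sample(c("A", "B", "C"), 12, replace = TRUE),
                    row.names = rownames(counts))
  ag <- aggregateTaxa(counts, "family", 0, taxonomy = tax)
  expect_equal(unname(colSums(ag$counts)), unname(colSums(counts)))
  expect_equal(unname(colSums(ag$relAbundance)), rep(1, 5))
})

test_that("known family proportions are recovered exactly", {
  counts <- rbind(o1 = c(60, 30), o2 = c(20, 30), o3 = c(20, 40))
  colnames(counts) <- c("s1", "s2")
  tax <- data.frame(family = c("F1", "F1", "F2"), row.names = rownames(counts))
  ag <- aggregateTaxa(counts, "family", 0, taxonomy = tax)
  expect_equal(ag$relAbundance["F1", ], c(s1 = 0.8, s2 = 0.6))
  expect_equal(ag$relAbundance["F2", ], c(s1 = 0.2, s2 = 0.4))
})

test_that("sub-threshold lineages pool into 'other'", {
  counts <- rbind(o1 = c(96, 96), o2 = c(2, 2), o3 = c(2, 2))
  colnames(counts) <- c("s1", "s2")
  tax <- data.frame(family = c("big", "tiny1", "tiny2"),
                    row.names = rownames(counts))
  ag <- aggregateTaxa(counts, "family", 0.02, taxonomy = tax)
  expect_setequal(rownames(ag$counts), c("big", "other"))
  expect_equal(unname(ag$relAbundance["other", ]), c(0.04, 0.04))
})

test_that("missing rank labels become unclassified_<parent>", {
  counts <- rbind(o1 = c(5, 5), o2 = c(5, 5))
  colnames(counts) <- c("s1", "s2")
  tax <- data.frame(phylum = c("Firmicutes", "Firmicutes"),
                    family = c("Clostridiaceae", NA),
                    row.names = rownames(counts))
  ag <- aggregateTaxa(counts, "family", 0, taxonomy = tax)
  expect_true("unclassified_Firmicutes" %in% rownames(ag$counts))
})

test_that("semicolon lineages parse with QIIME-style prefixes", {
  counts <- rbind(o1 = c(5L, 5L), o2 = c(5L, 5L))
  colnames(counts) <- c("s1", "s2")
  lin <- c("k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Clostridiaceae",
           "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Peptococcaceae")
  ag <- aggregateTaxa(counts, "family", 0, taxonomy = lin)
  expect_setequal(rownames(ag$counts), c("Clostridiaceae", "Peptococcaceae"))
})
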