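# Spearman association screening and Benjamini-Hochberg adjustment.

test_that("perfectly monotone pairs give rho of +/- 1", {
  x <- c(1, 3, 9, 27, 81, 243)
  expect_equal(spearmanTest(x, log(x))$rho, 1)
  expect_equal(spearmanTest(x, -sqrt(x))$rho, -1)
})

test_that("constant vectors yield NA rho", {
  st <- spearmanTest(rep(2, 6), rnorm(6))
  expect_true(is.na(st$rho) && is.na(st$p))
})

test_that("small-sample p-values are exact, larger ones use the t approximation", {
  set.seed(61)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(spearmanTest(x, y)$p,
               cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  x <- rnorm(20); y <- rnorm(20)
  st <- spearmanTest(x, y)
  r <- cor(rank(x), rank(y))
  tt <- r * sqrt(18 / (1 - r^2))
  expect_equal(st$p, 2 * pt(-abs(tt), 18))
})

test_that("ties are handled by average ranks", {
  x <- c(1, 2, 2, 3, 4, 5, 5, 6)
  y <- c(2, 1, 3, 3, 5, 4, 6, 7)
  expect_equal(spearmanTest(x, y)$rho, cor(rank(x), rank(y)))
})

test_that("BH step-up reproduces the hand-worked example and p.adjust", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_true(all(bhAdjust(c(0.2, 0.01, 0.9)) >= c(0.2, 0.01, 0.9)))
  set.seed(62)
  for (i in 1:10) {
    p <- runif(sample(5:40, 1))
    expect_equal(bhAdjust(p), p.adjust(p, method = "BH"))
  }
  # NAs pass through
  expect_equal(bhAdjust(c(0.5, NA))[2], NA_real_)
})

test_that("BH never declares more discoveries than raw testing", {
  set.seed(63)
  for (i in 1:20) {
    p <- runif(30)^sample(1:3, 1)
    expect_lte(sum(bhAdjust(p) < 0.05), sum(p < 0.05))
  }
})

test_that("the association screen flags a planted monotone signal", {
  set.seed(64)
  n <- 24
  env <- cbind(pcp = rnorm(n), ph = rnorm(n))
  taxa <- cbind(t1 = -2 * env[, "pcp"] + rnorm(n, sd = 0.1),
                t2 = rnorm(n), t3 = rnorm(n))
  res <- associateTaxa(taxa, env)
  hit <- res[res$taxon == "t1" & res$variable == "pcp", ]
  expect_lt(hit$rho, -0.9)
  expect_true(hit$significant)
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
})

test_that("too few paired observations error", {
  expect_error(associateTaxa(matrix(1:6, 3), matrix(1:6, 3)), "at least 4")
})
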