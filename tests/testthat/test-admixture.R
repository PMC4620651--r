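test_that("D is zero when the test populations are identical", {
  set.seed(21)
  p <- runif(200, 0.1, 0.9)
  ft <- fixtureFreqTable(cbind(P1 = p, P2 = p, A = runif(200), O = runif(200)))
  r <- dStatistic(ft, "P1", "P2", "A", "O")
  expect_equal(dValue(r), 0)
  expect_equal(zScore(r), 0)
})

test_that("the canonical single-site ABBA pattern gives D = 1", {
  ft <- fixtureFreqTable(cbind(P1 = 0, P2 = 1, A = 1, O = 0))
  r <- dStatistic(ft, "P1", "P2", "A", "O")
  expect_equal(r@sumAbba, 1)
  expect_equal(r@sumBaba, 0)
  expect_equal(dValue(r), 1)
  expect_true(is.na(standardError(r)))  # one block: no jackknife SE
})

test_that("frequency-formula D equals brute-force pattern counting on haplotypes", {
  set.seed(22)
  for (rep in 1:5) {
    h <- matrix(sample(0:1, 20 * 4, TRUE), 20, 4,
                dimnames = list(NULL, c("P1", "P2", "A", "O")))
    # oracle: site-pattern counting on the 0/1 haplotypes; with the
    # symmetric form ABBA sites are 0110/1001 and BABA sites 1010/0101
    pat <- apply(h, 1, paste, collapse = "")
    nABBA <- sum(pat %in% c("0110", "1001"))
    nBABA <- sum(pat %in% c("1010", "0101"))
    ft <- fixtureFreqTable(h, count = matrix(1L, 20, 4))
    if (nABBA + nBABA == 0) {
      expect_error(dStatistic(ft, "P1", "P2", "A", "O"), "no informative")
    } else {
      r <- dStatistic(ft, "P1", "P2", "A", "O", blockSize = 5)
      expect_equal(r@sumAbba, nABBA)
      expect_equal(r@sumBaba, nBABA)
      expect_equal(dValue(r), (nABBA - nBABA) / (nABBA + nBABA))
    }
  }
})

test_that("swapping P1 and P2 negates D and z; allele relabelling is neutral", {
  set.seed(23)
  f <- cbind(P1 = runif(400), P2 = runif(400), A = runif(400), O = runif(400))
  ft <- fixtureFreqTable(f)
  a <- dStatistic(ft, "P1", "P2", "A", "O")
  b <- dStatistic(ft, "P2", "P1", "A", "O")
  expect_equal(dValue(a), -dValue(b))
  expect_equal(zScore(a), -zScore(b))
  flipped <- fixtureFreqTable(1 - f)
  c <- dStatistic(flipped, "P1", "P2", "A", "O")
  expect_equal(dValue(c), dValue(a))
})

test_that("polarized mode skips sites with a polymorphic outgroup", {
  f <- cbind(P1 = c(0, 0.5, 0.2), P2 = c(1, 0.5, 0.8),
             A = c(1, 0.5, 0.9), O = c(0, 0.5, 0.3))
  ft <- fixtureFreqTable(f)
  r <- dStatistic(ft, "P1", "P2", "A", "O", polarize = TRUE)
  expect_identical(r@nSitesUsed, 1L)
  expect_identical(r@nSitesSkipped, 2L)
  expect_equal(dValue(r), 1)
})

test_that("missing frequencies are skipped and tallied", {
  f <- cbind(P1 = c(0.2, NA, 0.4), P2 = c(0.3, 0.1, 0.5),
             A = c(0.9, 0.2, 0.8), O = c(0.1, 0.3, 0.2))
  ft <- fixtureFreqTable(f)
  r <- dStatistic(ft, "P1", "P2", "A", "O")
  expect_identical(r@nSitesUsed, 2L)
  expect_identical(r@nSitesSkipped, 1L)
})

test_that("weighted jackknife with equal weights equals delete-one exactly", {
  set.seed(24)
  num <- rnorm(30); den <- runif(30, 5, 10)
  got <- blockJackknife(num, den, rep(7, 30))
  oracle <- deleteOneJackknife(num, den)
  expect_equal(got$estimate, oracle$estimate, tolerance = 1e-12)
  expect_equal(got$se, oracle$se, tolerance = 1e-12)
  # identical blocks have no between-block variance
  same <- blockJackknife(rep(2, 10), rep(4, 10), rep(5, 10))
  expect_equal(same$se, 0)
  # all weight concentrated in one block is degenerate
  expect_error(blockJackknife(1:2, c(3, 4), c(5, 0)), "2 blocks")
})

test_that("f3 identities: zero factor, single-site arithmetic, source symmetry", {
  set.seed(25)
  x <- runif(100)
  ft <- fixtureFreqTable(cbind(T = x, S1 = x, S2 = runif(100)),
                         count = matrix(10L, 100, 3))
  r <- f3Statistic(ft, "T", "S1", "S2", biasCorrection = FALSE)
  expect_equal(f3Value(r), 0)
  one <- fixtureFreqTable(cbind(T = 0.5, S1 = 0, S2 = 1),
                          count = matrix(10L, 1, 3))
  expect_equal(f3Value(f3Statistic(one, "T", "S1", "S2",
                                   biasCorrection = FALSE)), -0.25)
  f <- cbind(T = runif(300), S1 = runif(300), S2 = runif(300))
  ft2 <- fixtureFreqTable(f, count = matrix(20L, 300, 3))
  a <- f3Statistic(ft2, "T", "S1", "S2")
  b <- f3Statistic(ft2, "T", "S2", "S1")
  expect_equal(f3Value(a), f3Value(b))
  expect_equal(a@se, b@se)
  # bias correction needs at least two target allele copies
  ft3 <- fixtureFreqTable(cbind(T = 0.5, S1 = 0, S2 = 1),
                          count = matrix(1L, 1, 3))
  expect_error(f3Statistic(ft3, "T", "S1", "S2"), "2 allele copies")
})

test_that("per-population mean D matches recomputing each pair", {
  set.seed(26)
  f <- matrix(runif(300 * 7), 300, 7,
              dimnames = list(NULL, c("e1", "e2", "e3", "w1", "w2", "A", "O")))
  ft <- fixtureFreqTable(f)
  grid <- populationMeanD(ft, c("e1", "e2", "e3"), c("w1", "w2"), "A", "O")
  expect_identical(nrow(grid$pairs), 6L)
  for (p1 in c("e1", "e2", "e3")) {
    ds <- vapply(c("w1", "w2"), function(p2)
      dValue(dStatistic(ft, p1, p2, "A", "O")), numeric(1))
    expect_equal(grid$meanD$meanD[grid$meanD$p1 == p1], mean(ds))
  }
  # a single-population panel reduces to that D
  single <- populationMeanD(ft, "e1", "w1", "A", "O")
  expect_equal(single$meanD$meanD, dValue(dStatistic(ft, "e1", "w1", "A", "O")))
  # duplicated P2 frequencies give the same mean as either member
  f2 <- cbind(f[, c("e1", "A", "O")], wa = f[, "w1"], wb = f[, "w1"])
  ftdup <- fixtureFreqTable(f2)
  dup <- populationMeanD(ftdup, "e1", c("wa", "wb"), "A", "O")
  expect_equal(dup$meanD$meanD, dup$pairs$d[1])
  expect_error(populationMeanD(ft, "e1", character(0), "A", "O"), "empty")
})
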