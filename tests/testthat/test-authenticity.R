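test_that("contamination estimates reproduce the worked mtDNA examples", {
  panel <- fixturePanel()
  # 1,959 informative reads of which 10 carry a modern-lineage allele
  reads <- fixtureReads(panel, 1949, 10)
  est <- estimateContamination(reads, panel)
  expect_identical(informativeReads(est), 1959L)
  expect_identical(contaminantReads(est), 10L)
  expect_equal(round(contaminationPct(est), 2), 0.51)
  # 97 reads spanning the single transversion locus, all endogenous
  tvLocus <- panelTable(panel)$locus[panelTable(panel)$class == "transversion"]
  readsTv <- fixtureReads(panel, 97, 0, lociSubset = tvLocus)
  estTv <- estimateContamination(readsTv, panel, transversionsOnly = TRUE)
  expect_identical(informativeReads(estTv), 97L)
  expect_equal(contaminationPct(estTv), 0)
  # boundary: everything contaminant
  allCont <- fixtureReads(panel, 0, 25)
  expect_equal(contaminationPct(estimateContamination(allCont, panel)), 100)
})

test_that("multi-locus reads count once; third alleles are uninformative", {
  panel <- makeDiagnosticPanel("MT", c(10, 20), c("A", "C"), c("G", "T"))
  calls <- data.frame(
    read = c("r1", "r1", "r2", "r2", "r3"),
    locus = c("MT:10", "MT:20", "MT:10", "MT:20", "MT:10"),
    allele = c("A", "T",       # endogenous at one locus, contaminant at other
               "T", "G",       # third alleles only -> uninformative... but
               "A"))           # T at MT:10 is neither class; G at MT:20 neither
  est <- estimateContamination(makeReadObservationSet(calls), panel)
  # r1 contaminant (any contaminant allele wins), r2 uninformative, r3 endo
  expect_identical(informativeReads(est), 2L)
  expect_identical(contaminantReads(est), 1L)
})

test_that("contamination is scale-invariant and monotone in contaminants", {
  panel <- fixturePanel()
  for (k in c(1, 3)) {
    a <- estimateContamination(fixtureReads(panel, 100 * k, 5 * k), panel)
    expect_equal(contaminationPct(a), 100 * 5 / 105)
  }
  pcts <- vapply(c(0, 2, 5, 9), function(nc)
    contaminationPct(estimateContamination(
      fixtureReads(panel, 50, nc), panel)), numeric(1))
  expect_true(all(diff(pcts) > 0))
  # transversion-only informative reads are a subset of all-sites
  reads <- fixtureReads(panel, 150, 6)
  allEst <- estimateContamination(reads, panel)
  tvEst <- estimateContamination(reads, panel, transversionsOnly = TRUE)
  expect_lte(informativeReads(tvEst), informativeReads(allEst))
  # and a panel without transversions refuses the mode
  noTv <- makeDiagnosticPanel("MT", 1:2, c("A", "C"), c("G", "T"))
  expect_error(estimateContamination(reads, noTv, transversionsOnly = TRUE),
               "no informative loci")
})

test_that("the Jeffreys interval brackets the point estimate within [0, 100]", {
  panel <- fixturePanel()
  est <- estimateContamination(fixtureReads(panel, 200, 3), panel,
                               interval = "jeffreys")
  expect_lte(est@lowerPct, contaminationPct(est))
  expect_gte(est@upperPct, contaminationPct(est))
  expect_gte(est@lowerPct, 0)
  expect_lte(est@upperPct, 100)
})

test_that("X contamination recovers an injected fraction and demands a male", {
  xPanel <- makeDiagnosticPanel(
    chrom = rep("X", 200), pos = seq(1000, by = 500, length.out = 200),
    endogenous = rep(c("A", "C", "G", "T"), 50),
    contaminant = rep(c("G", "T", "A", "C"), 50))
  set.seed(505)
  sim <- simulateAncientReads(
    ancientReadParams(nReads = 20000, c = 0.05, e = 0, damageK = 0), xPanel)
  male <- inferSex(c("1" = 6.2, "2" = 6.1, X = 3.1))
  ests <- estimateXContamination(sim$reads, list(taurine = xPanel), male)
  got <- contaminationPct(ests$taurine) / 100
  expect_lt(abs(got - 0.05), 3 * sqrt(0.05 * 0.95 / 20000))
  # zero injected contamination -> exactly zero
  sim0 <- simulateAncientReads(
    ancientReadParams(nReads = 5000, c = 0, e = 0, damageK = 0), xPanel)
  est0 <- estimateXContamination(sim0$reads, list(src = xPanel), male)
  expect_equal(contaminationPct(est0$src), 0)
  # refuses on a female or ambiguous assignment
  female <- inferSex(c("1" = 6.2, "2" = 6.1, X = 6.0))
  expect_error(estimateXContamination(sim$reads, list(s = xPanel), female),
               "male")
})

test_that("sex inference thresholds and depth-ratio arithmetic", {
  m <- inferSex(c("1" = 6.2, "2" = 6.2, X = 3.1))
  expect_equal(m@ratio, 0.5)
  expect_identical(sexCall(m), "male")
  f <- inferSex(c("1" = 6.0, X = 6.0))
  expect_equal(f@ratio, 1.0)
  expect_identical(sexCall(f), "female")
  amb <- inferSex(c("1" = 10, X = 7))
  expect_identical(sexCall(amb), "ambiguous")
  expect_error(inferSex(c("1" = 0, X = 0)), "zero")
  expect_error(inferSex(c("1" = 5)), "absent")
})

test_that("fragment-length summaries match a sort-based oracle", {
  s1 <- summarizeFragmentLengths(50)
  expect_equal(s1@medianBp, 50)
  expect_equal(s1@fractions$fraction[1], 1.0)
  s2 <- summarizeFragmentLengths(c(40, 50, 60), ranges = list(c(45, 150)))
  expect_equal(s2@medianBp, 50)
  expect_equal(s2@fractions$fraction, 2 / 3)
  # lower-median convention for even counts
  expect_equal(summarizeFragmentLengths(c(10, 20))@medianBp, 10)
  expect_error(summarizeFragmentLengths(numeric(0)), "no fragment lengths")
  set.seed(606)
  lens <- round(rlnorm(10000, log(50), 0.4))
  got <- summarizeFragmentLengths(lens, ranges = list(c(16, 150), c(20, 150)))
  srt <- sort(lens)
  expect_equal(got@medianBp, srt[(length(srt) + 1) %/% 2])
  expect_equal(got@fractions$fraction[1],
               sum(srt >= 16 & srt <= 150) / length(srt))
  expect_equal(got@fractions$fraction[2],
               sum(srt >= 20 & srt <= 150) / length(srt))
})

test_that("damage profile rates are conditional and NA when unobserved", {
  mm <- data.frame(read = "r1", end = "5p", pos = 1L, ref = "C", obs = "T")
  dp <- damageProfile(makeReadObservationSet(mismatches = mm), k = 2)
  expect_equal(unname(ctRate5p(dp)[1]), 1.0)
  expect_true(is.na(ctRate5p(dp)[2]))       # no read reaches position 2
  expect_true(is.na(gaRate3p(dp)[1]))       # no 3' observations at all
})

test_that("damage rates equal brute-force tallies on a random fixture", {
  set.seed(707)
  n <- 4000
  mm <- data.frame(read = sprintf("r%d", seq_len(n)),
                   end = sample(c("5p", "3p"), n, TRUE),
                   pos = sample(1:5, n, TRUE),
                   ref = sample(c("A", "C", "G", "T"), n, TRUE),
                   obs = sample(c("A", "C", "G", "T"), n, TRUE))
  dp <- damageProfile(makeReadObservationSet(mismatches = mm), k = 5)
  r <- dp@rates
  for (i in sample(nrow(r), 50)) {
    sub <- mm[mm$end == r$end[i] & mm$pos == r$pos[i] & mm$ref == r$ref[i], ]
    if (nrow(sub) == 0) expect_true(is.na(r$rate[i]))
    else expect_equal(r$rate[i], mean(sub$obs == r$obs[i]))
  }
})

test_that("simulated exponential-decay damage is recovered within 3 SD", {
  panel <- fixturePanel()
  set.seed(808)
  sim <- simulateAncientReads(
    ancientReadParams(nReads = 3000, c = 0, e = 0, dMax = 0.3, lambda = 0.5,
                      damageK = 5), panel)
  dp <- damageProfile(sim$reads, k = 5)
  ct <- ctRate5p(dp); ga <- gaRate3p(dp)
  nRef <- sapply(1:5, function(i) {
    r <- dp@rates
    r$nRef[r$end == "5p" & r$pos == i & r$ref == "C" & r$obs == "T"]
  })
  expected <- 0.3 * 0.5^(0:4)
  for (i in 1:5) {
    sd3 <- 3 * sqrt(expected[i] * (1 - expected[i]) / nRef[i])
    expect_lt(abs(ct[i] - expected[i]), sd3)
    expect_lt(abs(ga[i] - expected[i]), sd3 * 1.5)  # independent draw, same model
  }
  # null model: no damage, error only; C>T rate is e/3 (uniform misread)
  sim0 <- simulateAncientReads(
    ancientReadParams(nReads = 20000, c = 0, e = 0.003, dMax = 0,
                      lambda = 0.5, damageK = 3), panel)
  ct0 <- ctRate5p(damageProfile(sim0$reads, k = 3))
  e3 <- 0.003 / 3
  for (i in 1:3)
    expect_lt(abs(ct0[i] - e3), 3 * sqrt(e3 * (1 - e3) / 5000) + 1e-3)
})
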