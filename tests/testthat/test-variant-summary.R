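test_that("variant classification follows the SNP/indel and ti/tv rules", {
  expect_identical(classifyVariant("A", "G")[c("kind", "class")],
                   list(kind = "snp", class = "transition"))
  expect_identical(classifyVariant("A", "T")$class, "transversion")
  expect_identical(classifyVariant("AC", "A")[c("kind", "class")],
                   list(kind = "indel", class = "not_applicable"))
  expect_error(classifyVariant("A", "A"), "identical")
  expect_error(classifyVariant("A", "N"), "A/C/G/T")
  # genotype: exactly one non-reference allele = heterozygous, two = homozygous
  expect_identical(classifyVariant("A", "G", "A/G")$genotype, "heterozygous")
  expect_identical(classifyVariant("A", "G", "G/G")$genotype, "homozygous")
  # heterozygous for two non-reference alleles is outside the biallelic scope
  expect_true(is.na(classifyVariant("A", "G", "G/T")$genotype))
})

test_that("printed-cell reconstruction reproduces totals, fractions and weighted means", {
  vs <- summarizeVariantCells(table1Cells())
  snp <- vs$byKind[vs$byKind$kind == "snp", ]
  ind <- vs$byKind[vs$byKind$kind == "indel", ]
  expect_identical(snp$total, 2009261L)
  expect_identical(ind$total, 104655L)
  # the printed 73.3 truncates the computed 73.36; compare within one unit
  # of the last printed digit
  expect_lt(abs(snp$homozygousFraction - 73.3), 0.1)
  expect_equal(round(ind$homozygousFraction, 1), 86.3)
  expect_equal(round(snp$wmeanDbsnp, 1), 96.9)
  expect_equal(round(ind$wmeanDbsnp, 1), 94.2)
  expect_equal(round(snp$wmeanPanel, 1), 84.9)
  expect_equal(round(ind$wmeanPanel, 1), 81.3)
  expect_equal(round(titvRatio(vs), 2), 2.19)
})

test_that("weighted mean of equal-count cells is the midpoint", {
  cells <- data.frame(kind = "snp", genotype = c("homozygous", "heterozygous"),
                      class = "transition", count = c(10L, 10L),
                      pctDbsnp = c(80, 100), pctPanel = NA_real_)
  vs <- summarizeVariantCells(cells)
  expect_equal(vs$byKind$wmeanDbsnp, 90)
})

test_that("ti/tv ratio matches a brute-force per-record tally", {
  set.seed(11)
  n <- 300
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  gtp <- ifelse(runif(n) < 0.5, paste(ref, alt, sep = "/"),
                paste(alt, alt, sep = "/"))
  vs <- tabulateVariants(data.frame(ref = ref, alt = alt, genotype = gtp))
  ti <- sum(isTransition(ref, alt))
  expect_equal(titvRatio(vs), ti / (n - ti))
  expect_identical(sum(vs$cells$count), as.integer(n))
  # equal transition and transversion counts give exactly 1
  cells <- data.frame(kind = "snp", genotype = "homozygous",
                      class = c("transition", "transversion"),
                      count = c(7L, 7L), pctDbsnp = NA_real_,
                      pctPanel = NA_real_)
  expect_equal(titvRatio(summarizeVariantCells(cells)), 1.0)
})

test_that("quality filter boundaries: depth inclusive, LOD exclusive", {
  v <- data.frame(depth = c(5, 4, 5, 10), lod = c(2.1, 9, 2.0, 1.9))
  out <- applyQualityFilter(v)
  expect_identical(attr(out, "nBefore"), 4L)
  expect_identical(attr(out, "nAfter"), 1L)
  expect_equal(out$depth, 5)
  expect_equal(out$lod, 2.1)
  expect_error(applyQualityFilter(data.frame(depth = 5)), "lod")
  expect_identical(nrow(applyQualityFilter(data.frame(depth = 4:6),
                                           noLod = TRUE)), 2L)
})

test_that("quality filter agrees with a hand filter on random records", {
  set.seed(12)
  v <- data.frame(depth = sample(1:10, 100, TRUE),
                  lod = round(runif(100, 0, 5), 2))
  out <- applyQualityFilter(v, minDepth = 5, minLod = 2)
  expect_identical(nrow(out), sum(v$depth >= 5 & v$lod > 2))
})

test_that("tabulation is permutation-invariant and additive over subsets", {
  set.seed(13)
  n <- 120
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  df <- data.frame(ref = ref, alt = alt,
                   genotype = ifelse(runif(n) < 0.5,
                                     paste(ref, alt, sep = "/"),
                                     paste(alt, alt, sep = "/")),
                   inDbsnp = runif(n) < 0.9)
  key <- function(vs) {
    c <- vs$cells[order(vs$cells$kind, vs$cells$genotype, vs$cells$class), ]
    rownames(c) <- NULL
    c
  }
  whole <- tabulateVariants(df)
  shuffled <- tabulateVariants(df[sample(n), ])
  expect_equal(key(whole), key(shuffled))
  a <- tabulateVariants(df[1:50, ])$cells
  b <- tabulateVariants(df[51:n, ])$cells
  merged <- merge(a[c("kind", "genotype", "class", "count")],
                  b[c("kind", "genotype", "class", "count")],
                  by = c("kind", "genotype", "class"), all = TRUE)
  merged[is.na(merged)] <- 0
  expect_equal(sort(merged$count.x + merged$count.y),
               sort(key(whole)$count[order(key(whole)$count)]))
})

test_that("empty input yields an empty summary, not an error", {
  vs <- tabulateVariants(data.frame(ref = character(), alt = character(),
                                    genotype = character()))
  expect_identical(nrow(vs$cells), 0L)
  expect_identical(vs$untabulated, 0L)
})

test_that("non-biallelic heterozygotes are counted as untabulated", {
  df <- data.frame(ref = c("A", "A"), alt = c("G", "G"),
                   genotype = c("G/G", "G/T"))
  vs <- tabulateVariants(df)
  expect_identical(sum(vs$cells$count), 1L)
  expect_identical(vs$untabulated, 1L)
})
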