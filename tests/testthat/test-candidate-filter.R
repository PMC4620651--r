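test_that("fixation filter retains opposite-fixed loci with a matching ancient call", {
  ft <- fixtureFreqTable(cbind(eur = c(0.98, 0.98, 0.98, 0.50, 0.02),
                               ind = c(0.03, 0.03, 0.03, 0.03, 0.97)),
                         count = matrix(100L, 5, 2))
  # locus 1: group1 alt-fixed, group2 ref-major, ancient hom-ref -> retained
  # locus 2: ancient heterozygous -> excluded
  # locus 3: ancient hom-alt (wrong side) -> excluded
  # locus 4: group1 not fixed -> excluded
  # locus 5: reversed fixation, ancient hom-alt -> retained
  res <- fixationFilter(ft, "eur", "ind", c(0L, 1L, 2L, 0L, 2L))
  expect_identical(res$loci, c(1L, 5L))
  expect_identical(res$table$group2MajorAllele, c("ref", "alt"))
  # missing ancient calls at qualifying loci are tallied
  res2 <- fixationFilter(ft, "eur", "ind", c(NA, 1L, 2L, 0L, 2L))
  expect_identical(res2$skippedMissing, 1L)
  expect_identical(res2$loci, 5L)
})

test_that("fixation filter equals a brute-force scan and is threshold-monotone", {
  set.seed(41)
  n <- 1000
  p1 <- runif(n); p2 <- runif(n)
  # plant some clear candidates
  idx <- sample(n, 40)
  p1[idx] <- runif(40, 0.96, 1); p2[idx] <- runif(40, 0, 0.04)
  anc <- sample(c(0L, 1L, 2L, NA), n, TRUE)
  ft <- fixtureFreqTable(cbind(g1 = p1, g2 = p2), count = matrix(50L, n, 2))
  survivors <- list()
  for (thr in c(0.90, 0.95, 0.99)) {
    got <- fixationFilter(ft, "g1", "g2", anc, threshold = thr)$loci
    oracle <- which((p1 >= thr & 1 - p2 >= thr & !is.na(anc) & anc == 0L) |
                    (1 - p1 >= thr & p2 >= thr & !is.na(anc) & anc == 2L))
    expect_identical(got, oracle)
    survivors[[as.character(thr)]] <- got
  }
  expect_true(all(survivors[["0.95"]] %in% survivors[["0.9"]]))
  expect_true(all(survivors[["0.99"]] %in% survivors[["0.95"]]))
})

test_that("fixation filter is symmetric under a global allele-label flip", {
  set.seed(42)
  n <- 300
  p1 <- runif(n); p2 <- runif(n)
  anc <- sample(c(0L, 1L, 2L), n, TRUE)
  ft <- fixtureFreqTable(cbind(g1 = p1, g2 = p2), count = matrix(50L, n, 2))
  ftFlip <- fixtureFreqTable(cbind(g1 = 1 - p1, g2 = 1 - p2),
                             count = matrix(50L, n, 2))
  a <- fixationFilter(ft, "g1", "g2", anc)$loci
  b <- fixationFilter(ftFlip, "g1", "g2", 2L - anc)$loci
  expect_identical(a, b)
})

test_that("region classification honours precedence and flank boundaries", {
  # gene on [10000, 20000) (0-based half-open), plus strand
  genes <- makeGeneModels(data.frame(gene_id = "g1", chrom = "1",
                                     start = 10000L, end = 20000L,
                                     strand = "+"))
  at <- function(pos0) {   # spec-style 0-based positions
    GenomicRanges::GRanges("1", IRanges::IRanges(pos0 + 1L, width = 1))
  }
  expect_identical(regionClassify(at(8000), genes)$region, "flank_up")
  expect_identical(regionClassify(at(4999), genes)$region, "intergenic")
  expect_identical(regionClassify(at(5000), genes)$region, "flank_up")
  expect_identical(regionClassify(at(21000), genes)$region, "flank_down")
  expect_identical(regionClassify(at(15000), genes)$region, "exon")
  # flankBp = 0 yields no flank classes
  expect_identical(regionClassify(at(8000), genes, flankBp = 0)$region,
                   "intergenic")
  # minus-strand gene swaps upstream and downstream
  neg <- makeGeneModels(data.frame(gene_id = "g1", chrom = "1",
                                   start = 10000L, end = 20000L,
                                   strand = "-"))
  expect_identical(regionClassify(at(8000), neg)$region, "flank_down")
  expect_identical(regionClassify(at(21000), neg)$region, "flank_up")
})

test_that("sub-features resolve to UTR/exon/intron classes", {
  genes <- makeGeneModels(
    data.frame(gene_id = "g1", chrom = "1", start = 1000L, end = 5000L,
               strand = "+"),
    features = data.frame(gene_id = "g1",
                          type = c("utr5", "exon", "exon", "utr3"),
                          start = c(1000L, 1000L, 3000L, 4800L),
                          end = c(1200L, 2000L, 4900L, 4900L)))
  at <- function(pos0) GenomicRanges::GRanges("1", IRanges::IRanges(pos0 + 1L, width = 1))
  expect_identical(regionClassify(at(1100), genes)$region, "utr5")
  expect_identical(regionClassify(at(1500), genes)$region, "exon")
  expect_identical(regionClassify(at(2500), genes)$region, "intron")
  expect_identical(regionClassify(at(4850), genes)$region, "utr3")
})

test_that("region classes match an exhaustive interval-scan oracle", {
  set.seed(43)
  nGenes <- 10
  starts <- sort(sample(seq(0, 200000, by = 100), nGenes))
  genes <- data.frame(gene_id = paste0("g", 1:nGenes), chrom = "1",
                      start = starts, end = starts + 4000L, strand = "+")
  gm <- makeGeneModels(genes)
  pos0 <- sample(0:210000, 300)
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(pos0 + 1L, width = 1))
  got <- regionClassify(gr, gm, flankBp = 5000)
  for (i in seq_along(pos0)) {
    p <- pos0[i]
    inGene <- genes$start <= p & p < genes$end
    upFlank <- p < genes$start & genes$start - p <= 5000
    downFlank <- p >= genes$end & p - genes$end + 1 <= 5000
    oracle <- if (any(inGene)) "exon"  # whole-body genes class as exonic
              else if (any(upFlank)) "flank_up"
              else if (any(downFlank)) "flank_down"
              else "intergenic"
    if (oracle %in% c("flank_up", "flank_down") &&
        any(upFlank) && any(downFlank))
      oracle <- got$region[i]  # equal-rank tie between flanks: either side ok
    expect_identical(got$region[i], oracle)
  }
})

test_that("candidate report keeps gene-associated classes only", {
  filtered <- list(table = data.frame(
    locus = c("1:10", "1:20", "1:30"), chrom = "1", pos = c(10L, 20L, 30L),
    freqGroup1 = 0.99, freqGroup2 = 0.01, ancientDosage = 0L,
    group2MajorAllele = "ref"))
  classes <- data.frame(locus = c("1:10", "1:20", "1:30"),
                        region = c("exon", "intron", "intergenic"),
                        gene_id = c("g1", "g1", NA), tie = FALSE)
  rep <- candidateReport(filtered, classes)
  expect_identical(nrow(rep$table), 1L)
  expect_identical(rep$table$region, "exon")
  empty <- candidateReport(list(table = filtered$table[0, ]), classes[0, ])
  expect_identical(nrow(empty$table), 0L)
})
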