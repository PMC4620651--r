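# Fixture builders shared across the suite. Everything is generated in
# code; files are written to tempdir() only.

# minimal VCF 4.2 text writer: records is a data.frame with chrom, pos,
# ref, alt (comma-separated for multiallelic) plus one GT-string column per
# sample in `samples`.
writeTestVcf <- function(path, records, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(records$chrom[i], records$pos[i], ".", records$ref[i],
            records$alt[i], ".", "PASS", ".", "GT",
            unlist(records[i, samples])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# a 15-locus mtDNA-style diagnostic panel with exactly one transversion
# locus (mirroring a haplogroup-discriminating panel)
fixturePanel <- function() {
  endo <- c("A", "C", "G", "T", "A", "C", "G", "T", "A", "C",
            "G", "T", "A", "C", "A")
  cont <- c("G", "T", "A", "C", "G", "T", "A", "C", "G", "T",
            "A", "C", "G", "T", "C")  # last pair A/C: transversion
  makeDiagnosticPanel(chrom = rep("MT", 15), pos = seq(100, 1500, by = 100),
                      endogenous = endo, contaminant = cont)
}

# reads spread over the panel: nEndo endogenous + nCont contaminant reads,
# each hitting one locus (cycled)
fixtureReads <- function(panel, nEndo, nCont, lociSubset = NULL) {
  tab <- panelTable(panel)
  if (!is.null(lociSubset)) tab <- tab[tab$locus %in% lociSubset, ]
  n <- nEndo + nCont
  locus <- tab$locus[(seq_len(n) - 1L) %% nrow(tab) + 1L]
  isCont <- rep(c(FALSE, TRUE), c(nEndo, nCont))
  i <- match(locus, tab$locus)
  allele <- ifelse(isCont,
                   vapply(strsplit(tab$contaminant[i], ","), `[`, character(1), 1),
                   tab$endogenous[i])
  makeReadObservationSet(data.frame(read = sprintf("r%06d", seq_len(n)),
                                    locus = locus, allele = allele))
}

# FrequencyTable built directly from a frequency matrix (counts filled in)
fixtureFreqTable <- function(freq, count = NULL) {
  freq <- as.matrix(freq)
  if (is.null(count)) count <- matrix(2L, nrow(freq), ncol(freq))
  count[is.na(freq)] <- 0L
  gr <- GenomicRanges::GRanges("1",
    IRanges::IRanges(seq_len(nrow(freq)) * 100L, width = 1L),
    ref = "A", alt = "C")
  names(gr) <- paste0("1:", seq_len(nrow(freq)) * 100L)
  makeFrequencyTable(gr, freq, count)
}

# printed summary cells of the ancient-vs-reference variant table
# (counts and percentages as published)
table1Cells <- function() {
  data.frame(
    kind = c(rep("snp", 4), rep("indel", 2)),
    genotype = c("heterozygous", "heterozygous", "homozygous", "homozygous",
                 "heterozygous", "homozygous"),
    class = c("transition", "transversion", "transition", "transversion",
              "not_applicable", "not_applicable"),
    count = c(368538L, 166652L, 1010894L, 463177L, 14309L, 90346L),
    pctDbsnp = c(93.1, 91.5, 98.6, 98.3, 80.6, 96.4),
    pctPanel = c(72.7, 70.0, 90.1, 88.8, 59.2, 84.8))
}

# direct delete-one jackknife for a ratio statistic (independent oracle)
deleteOneJackknife <- function(num, den) {
  g <- length(num)
  theta <- sum(num) / sum(den)
  thetaMinus <- vapply(seq_len(g), function(k)
    sum(num[-k]) / sum(den[-k]), numeric(1))
  se <- sqrt((g - 1) / g * sum((thetaMinus - mean(thetaMinus))^2))
  list(estimate = theta, se = se)
}
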