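#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file (GT field required) into a [GenotypeTable] of
#' alternate-allele dosages. Multiallelic records are dropped when
#' `biallelicOnly = TRUE`; a missing GT (`./.` or `.`) becomes a missing
#' dosage; loci are sorted by (chrom, pos). Haploid GT fields yield dosages
#' in \{0, 1\} and the sample is marked pseudo-haploid when every call it
#' carries is haploid.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param biallelicOnly drop records with more than one ALT allele
#'   (default `TRUE`); with `FALSE`, multiallelic records are an error.
#' @return A [GenotypeTable]. The number of dropped multiallelic records is
#'   recorded in `metadata(x)$multiallelicDropped`.
#' @export
readGenotypeVcf <- function(path, biallelicOnly = TRUE) {
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  alt <- VariantAnnotation::alt(vcf)
  nAlt <- lengths(alt)
  multi <- nAlt != 1L
  if (any(multi) && !biallelicOnly)
    stop(sum(multi), " multiallelic records present; ",
         "use biallelicOnly = TRUE to drop them")
  vcf <- vcf[!multi]
  alt <- VariantAnnotation::alt(vcf)
  gtField <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gtField)) stop("VCF has no GT field")
  gtField <- as.matrix(gtField)
  parse1 <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(c(NA_integer_, 2L))
    parts <- strsplit(g, "[/|]")[[1]]
    if (any(parts == ".")) return(c(NA_integer_, length(parts)))
    c(sum(parts == "1"), length(parts))
  }
  parsed <- apply(gtField, c(1, 2), function(g) parse1(g)[1])
  plo <- apply(gtField, 2, function(col) {
    n <- vapply(col, function(g) parse1(g)[2], integer(1))
    if (all(n == 1L)) 1L else 2L
  })
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- makeGenotypeTable(
    parsed,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alt)),
    sampleIds = colnames(gtField), ploidy = plo)
  metadata(gt)$multiallelicDropped <- sum(multi)
  gt
}

#' Read/write a genotype dosage matrix as TSV
#'
#' The TSV layout is one row per locus with columns `chrom`, `pos`, `ref`,
#' `alt` followed by one column per sample holding dosages 0/1/2 (0/1 for
#' pseudo-haploid samples) or `NA`.
#'
#' @param path file path.
#' @param ploidy per-sample ploidy passed through to [makeGenotypeTable].
#' @return `readGenotypeTsv` returns a [GenotypeTable]; `writeGenotypeTsv`
#'   returns `path` invisibly.
#' @export
readGenotypeTsv <- function(path, ploidy = 2L) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(pos = "integer"))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("genotype TSV must start with columns: ", paste(need, collapse = ", "))
  samp <- setdiff(names(df), need)
  makeGenotypeTable(as.matrix(df[, samp, drop = FALSE]),
                    chrom = df$chrom, pos = df$pos, ref = df$ref,
                    alt = df$alt, sampleIds = samp, ploidy = ploidy)
}

#' @rdname readGenotypeTsv
#' @param gt a [GenotypeTable].
#' @export
writeGenotypeTsv <- function(gt, path) {
  rr <- loci(gt)
  df <- data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
                   ref = mcols(rr)$ref, alt = mcols(rr)$alt,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(dosage(gt), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validatePopulationMap <- function(popmap) {
  if (!all(c("sample", "population") %in% names(popmap)))
    stop("population map needs columns 'sample' and 'population'")
  extra <- setdiff(names(popmap), c("sample", "population", "group"))
  if (length(extra))
    stop("unknown population-map column(s): ", paste(extra, collapse = ", "))
  if (anyDuplicated(popmap$sample))
    stop("duplicated samples in population map")
  if ("group" %in% names(popmap)) {
    # groups must partition populations: one group per population
    gp <- unique(popmap[, c("population", "group")])
    if (anyDuplicated(gp$population))
      stop("a population maps to more than one group")
  }
  invisible(popmap)
}

#' Read/write a population map
#'
#' TSV with columns `sample`, `population` and optional `group` (a regional
#' grouping; each population must belong to exactly one group).
#'
#' @param path file path.
#' @return `readPopulationMap` returns the map as a data.frame.
#' @export
readPopulationMap <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  validatePopulationMap(df)
}

#' @rdname readPopulationMap
#' @param popmap a population-map data.frame.
#' @export
writePopulationMap <- function(popmap, path) {
  validatePopulationMap(popmap)
  utils::write.table(popmap, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a diagnostic panel
#'
#' TSV with columns `chrom`, `pos`, `endogenous`, `contaminant`
#' (comma-separated alleles) and `class`; the declared class is validated
#' against the alleles (A/G and C/T pairs are transitions).
#'
#' @param path file path.
#' @return `readDiagnosticPanel` returns a [DiagnosticPanel].
#' @export
readDiagnosticPanel <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("chrom", "pos", "endogenous", "contaminant", "class")
  extra <- setdiff(names(df), c(need, "locus"))
  if (length(extra))
    stop("unknown diagnostic-panel column(s): ", paste(extra, collapse = ", "))
  if (!all(need %in% names(df)))
    stop("diagnostic panel needs columns: ", paste(need, collapse = ", "))
  makeDiagnosticPanel(df$chrom, as.integer(df$pos), df$endogenous,
                      df$contaminant, class = df$class,
                      locusId = if ("locus" %in% names(df)) df$locus
                                else paste0(df$chrom, ":", df$pos))
}

#' @rdname readDiagnosticPanel
#' @param panel a [DiagnosticPanel].
#' @export
writeDiagnosticPanel <- function(panel, path) {
  utils::write.table(panelTable(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write read observations
#'
#' The allele-call table is a TSV (`read`, `locus`, `allele`, optional
#' `length`); fragment lengths and terminal mismatches may also be supplied
#' as separate TSVs (`read`/`length` and `read`/`end`/`pos`/`ref`/`obs`).
#'
#' @param callsPath TSV of per-read allele calls.
#' @param lengthsPath optional TSV of fragment lengths.
#' @param mismatchesPath optional TSV of terminal mismatches.
#' @return `readReadObservations` returns a [ReadObservationSet].
#' @export
readReadObservations <- function(callsPath, lengthsPath = NULL,
                                 mismatchesPath = NULL) {
  calls <- utils::read.delim(callsPath, colClasses = "character")
  if (!all(c("read", "locus", "allele") %in% names(calls)))
    stop("read-observation TSV needs columns read, locus, allele")
  lengths <- NULL
  if ("length" %in% names(calls) && is.null(lengthsPath)) {
    lengths <- unique(data.frame(read = calls$read,
                                 length = as.numeric(calls$length)))
    calls$length <- NULL
  }
  if (!is.null(lengthsPath)) {
    lengths <- utils::read.delim(lengthsPath)
    lengths$length <- as.numeric(lengths$length)
  }
  mism <- NULL
  if (!is.null(mismatchesPath)) {
    mism <- utils::read.delim(mismatchesPath, colClasses = "character")
    mism$pos <- as.integer(mism$pos)
  }
  makeReadObservationSet(calls, lengths, mism)
}

#' @rdname readReadObservations
#' @param reads a [ReadObservationSet].
#' @param dir output directory; files `read_calls.tsv`,
#'   `fragment_lengths.tsv`, `terminal_mismatches.tsv` are written for the
#'   non-empty components.
#' @export
writeReadObservations <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths["calls"] <- w(readCalls(reads), "read_calls.tsv")
  if (nrow(fragmentLengths(reads)))
    paths["lengths"] <- w(fragmentLengths(reads), "fragment_lengths.tsv")
  if (nrow(terminalMismatches(reads)))
    paths["mismatches"] <- w(terminalMismatches(reads), "terminal_mismatches.tsv")
  invisible(paths)
}

#' Population allele frequencies from genotypes
#'
#' For each population and locus, the alternate-allele frequency
#' `p = (sum of alt dosages) / (non-missing allele copies)` and the number
#' `n` of observed allele copies (2 per called diploid genotype, 1 per
#' called pseudo-haploid call). `p` is missing exactly where `n = 0`.
#'
#' @param gt a [GenotypeTable].
#' @param popmap optional population map (see [readPopulationMap]); when
#'   omitted, `colData(gt)$population` is used.
#' @return A [FrequencyTable] with one column per population, in the order
#'   populations first appear in the map.
#' @export
alleleFrequencies <- function(gt, popmap = NULL) {
  if (!is.null(popmap)) gt <- attachPopulations(gt, popmap)
  pop <- colData(gt)$population
  if (is.null(pop)) stop("no population assignment; supply popmap")
  if (!is.null(popmap)) {
    empty <- setdiff(unique(popmap$population), pop)
    if (length(empty))
      stop("population(s) with zero samples: ", paste(empty, collapse = ", "))
  }
  pops <- unique(pop)
  d <- dosage(gt)
  pl <- colData(gt)$ploidy
  nl <- nrow(d)
  freq <- matrix(NA_real_, nl, length(pops), dimnames = list(rownames(d), pops))
  count <- matrix(0L, nl, length(pops), dimnames = list(rownames(d), pops))
  for (j in seq_along(pops)) {
    cols <- which(pop == pops[j])
    sub <- d[, cols, drop = FALSE]
    obs <- !is.na(sub)
    n <- as.integer(obs %*% pl[cols])
    altSum <- rowSums(sub, na.rm = TRUE)
    count[, j] <- n
    freq[, j] <- ifelse(n > 0, altSum / n, NA_real_)
  }
  makeFrequencyTable(loci(gt), freq, count)
}

#' Read BED intervals as GRanges
#'
#' BED coordinates are 0-based half-open on disk and are converted to the
#' 1-based inclusive convention used internally.
#'
#' @param path BED file (3+ columns).
#' @return A `GRanges`.
#' @export
readBedWindows <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Fixed-width tiling windows over given chromosome lengths
#'
#' @param chromLengths named integer vector of chromosome lengths (bp).
#' @param width window width in bp (default 50000).
#' @return A `GRanges` of non-overlapping tiles covering each chromosome.
#' @export
tileWindows <- function(chromLengths, width = 50000L) {
  grs <- lapply(names(chromLengths), function(ch) {
    len <- chromLengths[[ch]]
    starts <- seq(1L, len, by = width)
    GRanges(ch, IRanges(starts, pmin(starts + width - 1L, len)))
  })
  do.call(c, grs)
}
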