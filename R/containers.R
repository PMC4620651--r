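#' Construct a GenotypeTable
#'
#' @param dosage integer matrix, loci x samples: alternate-allele dosage
#'   (0..ploidy, `NA` missing).
#' @param chrom,pos,ref,alt per-locus chromosome, 1-based position and
#'   alleles.
#' @param sampleIds sample identifiers (defaults to `colnames(dosage)`).
#' @param ploidy per-sample ploidy, 2 (diploid, default) or 1
#'   (pseudo-haploid); recycled.
#' @return A [GenotypeTable] with loci sorted by (chrom, pos).
#' @examples
#' gt <- makeGenotypeTable(matrix(c(0, 1, 2, NA), 2, 2),
#'                         chrom = c("1", "1"), pos = c(100, 200),
#'                         ref = c("A", "C"), alt = c("G", "T"),
#'                         sampleIds = c("s1", "s2"))
#' dosage(gt)
#' @export
makeGenotypeTable <- function(dosage, chrom, pos, ref, alt,
                              sampleIds = colnames(dosage), ploidy = 2L) {
  dosage <- as.matrix(dosage)
  if (is.null(sampleIds))
    sampleIds <- paste0("sample", seq_len(ncol(dosage)))
  ploidy <- as.integer(rep_len(ploidy, ncol(dosage)))
  key <- paste(chrom, pos)
  if (anyDuplicated(key))
    stop("duplicated (chrom, pos) loci: ", paste(unique(key[duplicated(key)]), collapse = ", "))
  ord <- order(as.character(chrom), pos)
  rr <- GRanges(as.character(chrom)[ord], IRanges(pos[ord], width = 1L),
                ref = toupper(as.character(ref))[ord],
                alt = toupper(as.character(alt))[ord])
  names(rr) <- paste0(as.character(chrom), ":", pos)[ord]
  d <- dosage[ord, , drop = FALSE]
  storage.mode(d) <- "integer"
  dimnames(d) <- list(names(rr), sampleIds)
  se <- SummarizedExperiment(assays = list(dosage = d), rowRanges = rr,
    colData = DataFrame(ploidy = ploidy, row.names = sampleIds))
  new("GenotypeTable", se)
}

#' @describeIn makeGenotypeTable dosage matrix accessor.
#' @param x,object a `GenotypeTable`.
#' @export
dosage <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn makeGenotypeTable locus `GRanges` accessor.
#' @export
loci <- function(x) {
  if (is(x, "GenotypeTable")) rowRanges(x) else x@loci
}

#' @describeIn makeGenotypeTable sample identifier accessor.
#' @export
sampleIds <- function(x) colnames(x)

#' @describeIn makeGenotypeTable per-sample ploidy accessor.
#' @export
ploidy <- function(x) {
  stats::setNames(colData(x)$ploidy, colnames(x))
}

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", nrow(object), "loci x", ncol(object), "samples\n")
  pl <- table(colData(object)$ploidy)
  cat("  ploidy:", paste(sprintf("%s x %s", pl, names(pl)), collapse = ", "), "\n")
  if ("population" %in% colnames(colData(object)))
    cat("  populations:", length(unique(colData(object)$population)), "\n")
  cat("  missingness:",
      sprintf("%.2f%%", 100 * mean(is.na(dosage(object)))), "\n")
})

#' Attach population labels to a GenotypeTable
#'
#' @param gt a [GenotypeTable].
#' @param popmap a population map data.frame (see [readPopulationMap]) with
#'   columns `sample`, `population` and optionally `group`.
#' @return `gt` with `population` (and `group`) columns in its `colData`.
#' @export
attachPopulations <- function(gt, popmap) {
  validatePopulationMap(popmap)
  idx <- match(colnames(gt), popmap$sample)
  if (anyNA(idx))
    stop("samples missing from population map: ",
         paste(colnames(gt)[is.na(idx)], collapse = ", "))
  colData(gt)$population <- popmap$population[idx]
  if ("group" %in% names(popmap)) colData(gt)$group <- popmap$group[idx]
  gt
}

# ---------------------------------------------------------------------------

#' Construct a FrequencyTable
#'
#' @param loci `GRanges` with `ref`/`alt` metadata columns.
#' @param freq numeric matrix loci x populations of alternate-allele
#'   frequencies (`NA` where unobserved).
#' @param count matrix of observed allele-copy counts; must be 0 exactly
#'   where `freq` is `NA`.
#' @return A [FrequencyTable].
#' @export
makeFrequencyTable <- function(loci, freq, count) {
  freq <- as.matrix(freq); count <- as.matrix(count)
  storage.mode(count) <- "integer"
  rownames(freq) <- rownames(count) <- names(loci)
  if (is.null(colnames(count))) colnames(count) <- colnames(freq)
  new("FrequencyTable", loci = loci, freq = freq, count = count)
}

#' @describeIn makeFrequencyTable population labels.
#' @param x a `FrequencyTable`.
#' @export
populations <- function(x) colnames(x@freq)

#' @describeIn makeFrequencyTable frequency matrix (loci x populations).
#' @export
freqMatrix <- function(x) x@freq

#' @describeIn makeFrequencyTable allele-copy count matrix.
#' @export
countMatrix <- function(x) x@count

setMethod("show", "FrequencyTable", function(object) {
  cat("FrequencyTable:", nrow(object@freq), "loci x",
      ncol(object@freq), "populations\n")
  cat("  populations:", paste(utils::head(populations(object), 8), collapse = ", "),
      if (ncol(object@freq) > 8) "..." else "", "\n")
})

# ---------------------------------------------------------------------------

#' Construct a DiagnosticPanel
#'
#' @param chrom,pos locus coordinates (1-based).
#' @param endogenous single-base allele expected from the endogenous lineage.
#' @param contaminant character vector; one or more contaminant-lineage
#'   alleles per locus, comma-separated.
#' @param class `"transition"`/`"transversion"`; when `NULL` (default) the
#'   class is derived from the alleles (transversion only when every
#'   endogenous/contaminant pair is a transversion). A supplied class that
#'   contradicts the alleles is an error.
#' @param locusId locus identifiers; default `chrom:pos`.
#' @return A [DiagnosticPanel].
#' @export
makeDiagnosticPanel <- function(chrom, pos, endogenous, contaminant,
                                class = NULL,
                                locusId = paste0(chrom, ":", pos)) {
  endogenous <- toupper(endogenous)
  contaminant <- toupper(gsub(" ", "", contaminant))
  derived <- derivedMutationClass(endogenous, contaminant)
  if (is.null(class)) class <- derived
  gr <- GRanges(as.character(chrom), IRanges(as.integer(pos), width = 1L),
                endogenous = endogenous, contaminant = contaminant,
                class = as.character(class))
  names(gr) <- locusId
  new("DiagnosticPanel", loci = gr)
}

#' @describeIn makeDiagnosticPanel number of diagnostic loci.
#' @param x a `DiagnosticPanel`.
#' @export
panelSize <- function(x) length(x@loci)

#' @describeIn makeDiagnosticPanel the panel as a data.frame (one row per
#'   locus: locus, chrom, pos, endogenous, contaminant, class).
#' @export
panelTable <- function(x) {
  gr <- x@loci
  data.frame(locus = names(gr), chrom = as.character(seqnames(gr)),
             pos = start(gr), endogenous = mcols(gr)$endogenous,
             contaminant = mcols(gr)$contaminant, class = mcols(gr)$class,
             stringsAsFactors = FALSE, row.names = NULL)
}

setMethod("show", "DiagnosticPanel", function(object) {
  tab <- table(mcols(object@loci)$class)
  cat("DiagnosticPanel:", length(object@loci), "loci (",
      paste(sprintf("%d %s", tab, names(tab)), collapse = ", "), ")\n")
})

# ---------------------------------------------------------------------------

#' Construct a ReadObservationSet
#'
#' @param calls data.frame (`read`, `locus`, `allele`): per-read base calls
#'   at diagnostic loci.
#' @param lengths optional data.frame (`read`, `length`) of fragment lengths
#'   in bp, or a bare numeric vector of lengths.
#' @param mismatches optional data.frame (`read`, `end`, `pos`, `ref`, `obs`)
#'   of terminal reference/read base pairs (`end` in `"5p"`/`"3p"`, `pos`
#'   1-based distance from that end).
#' @return A [ReadObservationSet].
#' @export
makeReadObservationSet <- function(calls = NULL, lengths = NULL,
                                   mismatches = NULL) {
  if (is.null(calls))
    calls <- data.frame(read = character(), locus = character(),
                        allele = character())
  calls$allele <- toupper(calls$allele)
  if (is.null(lengths))
    lengths <- data.frame(read = character(), length = numeric())
  else if (!is.data.frame(lengths))
    lengths <- data.frame(read = paste0("frag", seq_along(lengths)),
                          length = as.numeric(lengths))
  if (is.null(mismatches))
    mismatches <- data.frame(read = character(), end = character(),
                             pos = integer(), ref = character(),
                             obs = character())
  new("ReadObservationSet", calls = calls, lengths = lengths,
      mismatches = mismatches)
}

#' @describeIn makeReadObservationSet number of distinct reads with calls.
#' @param x a `ReadObservationSet`.
#' @export
nReads <- function(x) length(unique(x@calls$read))

#' @describeIn makeReadObservationSet allele-call data.frame accessor.
#' @export
readCalls <- function(x) x@calls

#' @describeIn makeReadObservationSet fragment-length data.frame accessor.
#' @export
fragmentLengths <- function(x) x@lengths

#' @describeIn makeReadObservationSet terminal-mismatch data.frame accessor.
#' @export
terminalMismatches <- function(x) x@mismatches

setMethod("show", "ReadObservationSet", function(object) {
  cat("ReadObservationSet:", nReads(object), "reads with allele calls at",
      length(unique(object@calls$locus)), "loci;",
      nrow(object@lengths), "fragment lengths;",
      nrow(object@mismatches), "terminal base pairs\n")
})
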