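#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end granges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData colData<- rowRanges
NULL

TRANSITION_PAIRS <- list(c("A", "G"), c("C", "T"))

#' Is an allele pair a transition?
#'
#' A substitution is a transition when it exchanges the two purines (A/G)
#' or the two pyrimidines (C/T); every other single-base exchange is a
#' transversion. Post-mortem cytosine deamination inflates apparent
#' transitions in ancient DNA, which is why several analyses here offer a
#' transversion-only mode.
#'
#' @param a,b single-character alleles in `A`, `C`, `G`, `T`.
#' @return Logical vector, `TRUE` for transition pairs.
#' @examples
#' isTransition("A", "G")  # TRUE
#' isTransition("A", "T")  # FALSE
#' @export
isTransition <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  (a %in% c("A", "G") & b %in% c("A", "G") & a != b) |
    (a %in% c("C", "T") & b %in% c("C", "T") & a != b)
}

# ---------------------------------------------------------------------------
# GenotypeTable
# ---------------------------------------------------------------------------

#' GenotypeTable: samples x biallelic loci with allele dosages
#'
#' Extends [SummarizedExperiment::RangedSummarizedExperiment]. The single
#' assay `"dosage"` holds, per locus (row) and sample (column), the count of
#' alternate alleles: 0/1/2 for diploid samples, 0/1 for pseudo-haploid
#' samples, `NA` for missing. Row ranges carry `ref` and `alt` alleles;
#' `colData` carries per-sample `ploidy` and, optionally, `population` and
#' `group` labels.
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment].
#' @export
setClass("GenotypeTable", contains = "RangedSummarizedExperiment")

setValidity("GenotypeTable", function(object) {
  msgs <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'dosage' is required")
  rr <- rowRanges(object)
  mc <- mcols(rr)
  if (!all(c("ref", "alt") %in% colnames(mc)))
    msgs <- c(msgs, "rowRanges must carry 'ref' and 'alt' columns")
  else if (any(mc$ref == mc$alt))
    msgs <- c(msgs, "ref and alt alleles must differ at every locus")
  if (!"ploidy" %in% colnames(colData(object)))
    msgs <- c(msgs, "colData must carry a 'ploidy' column")
  if (length(msgs) == 0) {
    pl <- colData(object)$ploidy
    if (!all(pl %in% c(1L, 2L)))
      msgs <- c(msgs, "ploidy must be 1 (pseudo-haploid) or 2 (diploid)")
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- sweep(d, 2, pl, function(x, p) !is.na(x) & (x < 0 | x > p | x != round(x)))
    if (any(bad))
      msgs <- c(msgs, "dosages must be integers in 0..ploidy or NA")
    key <- paste(as.character(seqnames(rr)), start(rr))
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicated (chrom, pos) loci are not allowed")
    if (is.unsorted(order(as.character(seqnames(rr)), start(rr))) &&
        !identical(order(as.character(seqnames(rr)), start(rr)), seq_along(rr)))
      msgs <- c(msgs, "loci must be sorted by (chrom, pos)")
  }
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# FrequencyTable
# ---------------------------------------------------------------------------

#' FrequencyTable: per-population alternate-allele frequencies
#'
#' Holds, per locus x population, the alternate-allele frequency `p` and the
#' number `n` of observed (non-missing) allele copies it was computed from.
#' `p` is `NA` exactly where `n == 0`.
#'
#' @slot loci `GRanges` with `ref`/`alt` metadata columns, one per locus.
#' @slot freq numeric matrix, loci x populations, values in `[0, 1]` or `NA`.
#' @slot count integer matrix, loci x populations, observed allele copies.
#' @export
setClass("FrequencyTable",
  representation(loci = "GRanges", freq = "matrix", count = "matrix"))

setValidity("FrequencyTable", function(object) {
  msgs <- character()
  f <- object@freq; n <- object@count
  if (!identical(dim(f), dim(n)))
    msgs <- c(msgs, "freq and count must have identical dimensions")
  if (nrow(f) != length(object@loci))
    msgs <- c(msgs, "freq rows must match loci")
  if (is.null(colnames(f)) || anyDuplicated(colnames(f)))
    msgs <- c(msgs, "populations (colnames of freq) must be unique and named")
  if (length(msgs) == 0) {
    ok <- is.na(f) | (f >= 0 & f <= 1)
    if (!all(ok)) msgs <- c(msgs, "frequencies must lie in [0, 1] or be NA")
    if (any(is.na(f) != (n == 0)))
      msgs <- c(msgs, "p must be NA exactly where n == 0")
    if (any(n < 0)) msgs <- c(msgs, "allele-copy counts must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# DiagnosticPanel
# ---------------------------------------------------------------------------

#' DiagnosticPanel: loci discriminating endogenous from contaminant lineages
#'
#' Each locus carries the allele expected from the endogenous (ancient)
#' lineage, one or more alleles characteristic of potential contaminating
#' lineages, and a mutation class. A locus is classed `"transversion"` only
#' when every endogenous/contaminant allele pair is a transversion, so that
#' read classification at that locus cannot be confounded by deamination-
#' driven C>T / G>A artefacts; otherwise it is classed `"transition"`.
#'
#' @slot loci `GRanges`, one range per diagnostic site, with metadata columns
#'   `endogenous` (character), `contaminant` (comma-separated characters) and
#'   `class` (`"transition"` or `"transversion"`). Locus identifiers are the
#'   names of the ranges.
#' @export
setClass("DiagnosticPanel", representation(loci = "GRanges"))

derivedMutationClass <- function(endogenous, contaminant) {
  vapply(seq_along(endogenous), function(i) {
    cont <- strsplit(contaminant[i], ",", fixed = TRUE)[[1]]
    if (all(!isTransition(endogenous[i], cont))) "transversion" else "transition"
  }, character(1))
}

setValidity("DiagnosticPanel", function(object) {
  msgs <- character()
  mc <- mcols(object@loci)
  need <- c("endogenous", "contaminant", "class")
  if (!all(need %in% colnames(mc)))
    return(paste("loci must carry columns:", paste(need, collapse = ", ")))
  if (is.null(names(object@loci)) || anyDuplicated(names(object@loci)))
    msgs <- c(msgs, "loci must have unique names (locus identifiers)")
  cont <- strsplit(mc$contaminant, ",", fixed = TRUE)
  overlap <- mapply(function(e, cc) e %in% cc, mc$endogenous, cont)
  if (any(overlap))
    msgs <- c(msgs, "endogenous allele must not appear among contaminant alleles")
  if (!all(mc$class %in% c("transition", "transversion")))
    msgs <- c(msgs, "class must be 'transition' or 'transversion'")
  else {
    derived <- derivedMutationClass(mc$endogenous, mc$contaminant)
    if (any(mc$class != derived))
      msgs <- c(msgs, sprintf(
        "declared mutation class inconsistent with alleles at locus %s",
        paste(names(object@loci)[mc$class != derived], collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# ReadObservationSet
# ---------------------------------------------------------------------------

#' ReadObservationSet: per-read allele calls, lengths and terminal mismatches
#'
#' The read-level evidence consumed by the authenticity suite:
#' \describe{
#'   \item{calls}{data.frame with columns `read`, `locus`, `allele` — one row
#'     per (read, diagnostic locus) observation.}
#'   \item{lengths}{data.frame with columns `read`, `length` (bp), or a
#'     zero-row frame when fragment lengths were not recorded.}
#'   \item{mismatches}{data.frame with columns `read`, `end` (`"5p"`/`"3p"`),
#'     `pos` (1-based distance from that end), `ref`, `obs` — one row per
#'     (read, terminal position) with the reference and read base.}
#' }
#' @slot calls,lengths,mismatches data.frames as described above.
#' @export
setClass("ReadObservationSet",
  representation(calls = "data.frame", lengths = "data.frame",
                 mismatches = "data.frame"))

setValidity("ReadObservationSet", function(object) {
  msgs <- character()
  if (!all(c("read", "locus", "allele") %in% names(object@calls)))
    msgs <- c(msgs, "calls needs columns read, locus, allele")
  else if (nrow(object@calls) && !all(nchar(object@calls$allele) == 1L))
    msgs <- c(msgs, "observed alleles must be single bases")
  if (!all(c("read", "length") %in% names(object@lengths)))
    msgs <- c(msgs, "lengths needs columns read, length")
  else if (nrow(object@lengths) && any(object@lengths$length <= 0))
    msgs <- c(msgs, "fragment lengths must be positive")
  if (!all(c("read", "end", "pos", "ref", "obs") %in% names(object@mismatches)))
    msgs <- c(msgs, "mismatches needs columns read, end, pos, ref, obs")
  else if (nrow(object@mismatches) &&
           !all(object@mismatches$end %in% c("5p", "3p")))
    msgs <- c(msgs, "mismatch end must be '5p' or '3p'")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# Authenticity results
# ---------------------------------------------------------------------------

#' ContaminationEstimate: read-classification contamination estimate
#'
#' @slot informativeReads reads overlapping at least one diagnostic locus
#'   with a base matching either allele class.
#' @slot contaminantReads informative reads carrying a contaminant allele at
#'   any overlapped locus.
#' @slot estimatePct `100 * contaminantReads / informativeReads`.
#' @slot mode `"all_sites"` or `"transversions_only"`.
#' @slot lowerPct,upperPct optional Jeffreys binomial interval bounds
#'   (percent), `NA` when not requested.
#' @slot source label of the putative contaminating lineage (X-chromosome
#'   per-source estimates), `NA` otherwise.
#' @export
setClass("ContaminationEstimate",
  representation(informativeReads = "integer", contaminantReads = "integer",
                 estimatePct = "numeric", mode = "character",
                 lowerPct = "numeric", upperPct = "numeric",
                 source = "character"))

setValidity("ContaminationEstimate", function(object) {
  msgs <- character()
  ni <- object@informativeReads; nc <- object@contaminantReads
  if (nc < 0 || nc > ni)
    msgs <- c(msgs, "contaminantReads must lie in [0, informativeReads]")
  if (ni > 0 && abs(object@estimatePct - 100 * nc / ni) > 1e-9)
    msgs <- c(msgs, "estimatePct must equal 100 * contaminant / informative")
  if (!object@mode %in% c("all_sites", "transversions_only"))
    msgs <- c(msgs, "mode must be 'all_sites' or 'transversions_only'")
  iv <- c(object@lowerPct, object@upperPct)
  if (any(!is.na(iv) & (iv < 0 | iv > 100)))
    msgs <- c(msgs, "interval bounds must lie in [0, 100]")
  if (length(msgs)) msgs else TRUE
})

#' SexAssignment: sex call from the X/autosome depth ratio
#'
#' Mammalian males are hemizygous for the X, so X-mapped read depth of a male
#' is about half the autosomal depth while a female's is about equal.
#'
#' @slot xMeanDepth,autosomalMeanDepth fold coverages.
#' @slot ratio `xMeanDepth / autosomalMeanDepth`.
#' @slot call `"male"`, `"female"` or `"ambiguous"`.
#' @slot maleMax,femaleMin the thresholds used.
#' @export
setClass("SexAssignment",
  representation(xMeanDepth = "numeric", autosomalMeanDepth = "numeric",
                 ratio = "numeric", call = "character",
                 maleMax = "numeric", femaleMin = "numeric"))

setValidity("SexAssignment", function(object) {
  msgs <- character()
  if (object@ratio < 0) msgs <- c(msgs, "ratio must be >= 0")
  if (!object@call %in% c("male", "female", "ambiguous"))
    msgs <- c(msgs, "call must be male/female/ambiguous")
  if (length(msgs)) msgs else TRUE
})

#' FragmentLengthSummary: median and in-range fractions of fragment lengths
#'
#' @slot nFragments number of fragments summarised.
#' @slot medianBp lower median fragment length (bp; for even counts the lower
#'   of the two central order statistics, so the median is always an observed
#'   length).
#' @slot fractions data.frame with columns `lo`, `hi`, `fraction`: the
#'   inclusive proportion of fragments with `lo <= length <= hi`.
#' @export
setClass("FragmentLengthSummary",
  representation(nFragments = "integer", medianBp = "numeric",
                 fractions = "data.frame"))

setValidity("FragmentLengthSummary", function(object) {
  f <- object@fractions$fraction
  if (length(f) && any(f < 0 | f > 1)) "fractions must lie in [0, 1]" else TRUE
})

#' DamageProfile: terminal substitution rates by distance from read end
#'
#' For each read end (5'/3') and distance `pos = 1..k`, the rate of each
#' ref -> read substitution conditioned on the reference base, i.e.
#' `rate = n(ref = X, obs = Y at pos) / n(ref = X at pos)`. Rates are `NA`
#' (not 0) where the conditioning count is zero. Authentic ancient DNA shows
#' elevated C>T at 5' ends and G>A at 3' ends decaying with distance.
#'
#' @slot k number of terminal positions profiled per end.
#' @slot rates data.frame with columns `end`, `pos`, `ref`, `obs`, `nRef`,
#'   `nObs`, `rate` covering all 4 x 4 base pairs at each (end, pos).
#' @export
setClass("DamageProfile",
  representation(k = "integer", rates = "data.frame"))

setValidity("DamageProfile", function(object) {
  r <- object@rates$rate
  if (length(r) && any(!is.na(r) & (r < 0 | r > 1)))
    "rates must lie in [0, 1] or be NA" else TRUE
})

# ---------------------------------------------------------------------------
# Admixture results
# ---------------------------------------------------------------------------

#' DStatResult: ABBA/BABA D statistic with block-jackknife significance
#'
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)` over sites, for the population
#' topology `(((P1, P2), A), O)`. `D > 0` signals gene flow between A and P2,
#' `D < 0` between A and P1. The standard error comes from a weighted block
#' jackknife over contiguous SNP blocks.
#'
#' @slot d,se,z the statistic, jackknife SE and `d / se`.
#' @slot nSitesUsed sites with all four frequencies observed.
#' @slot nSitesSkipped sites dropped for missing frequencies (or, in
#'   polarized mode, a polymorphic outgroup).
#' @slot sumAbba,sumBaba the site sums.
#' @slot nBlocks jackknife blocks.
#' @slot populations named character vector (p1, p2, a, o).
#' @slot mode `"symmetric"` or `"polarized"`.
#' @export
setClass("DStatResult",
  representation(d = "numeric", se = "numeric", z = "numeric",
                 nSitesUsed = "integer", nSitesSkipped = "integer",
                 sumAbba = "numeric", sumBaba = "numeric",
                 nBlocks = "integer", populations = "character",
                 mode = "character"))

setValidity("DStatResult", function(object) {
  msgs <- character()
  if (!is.na(object@d) && abs(object@d) > 1 + 1e-12)
    msgs <- c(msgs, "|D| must be <= 1")
  if (!is.na(object@se) && !is.na(object@z) && object@se > 0 &&
      abs(object@z * object@se - object@d) > 1e-8 * max(1, abs(object@d)))
    msgs <- c(msgs, "z * se must equal D")
  if (length(msgs)) msgs else TRUE
})

#' F3Result: three-population admixture test statistic
#'
#' `f3(target; s1, s2) = mean over sites of (x - a)(x - b)` where `x`, `a`,
#' `b` are the target and source allele frequencies, optionally with the
#' finite-sample bias correction `- x(1 - x) / (n_x - 1)` per site. A
#' significantly negative value (z below about -3) indicates the target is
#' admixed between the two sources. Symmetric in the sources.
#'
#' @slot f3,se,z statistic, jackknife SE, `f3 / se`.
#' @slot nSitesUsed,nBlocks sites and jackknife blocks used.
#' @slot populations named character vector (target, source1, source2).
#' @slot biasCorrected logical.
#' @export
setClass("F3Result",
  representation(f3 = "numeric", se = "numeric", z = "numeric",
                 nSitesUsed = "integer", nBlocks = "integer",
                 populations = "character", biasCorrected = "logical"))
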