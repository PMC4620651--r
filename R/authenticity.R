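#' Estimate modern contamination from diagnostic-site reads
#'
#' Each read overlapping diagnostic loci is classified by the alleles it
#' carries: it is *informative* when it shows the endogenous or a
#' contaminant allele at one or more panel loci, *contaminant* when any
#' overlapped locus shows a contaminant-lineage allele, and discarded as
#' uninformative when it matches neither class anywhere (sequencing-error
#' third alleles). A read overlapping several loci counts once. The
#' estimate is `100 * contaminant / informative` percent — an upper bound on
#' modern contamination, since sequencing error also produces apparent
#' contaminant alleles. Transversion-only mode restricts the panel to loci
#' whose diagnostic allele pairs are all transversions, removing
#' deamination-driven C>T / G>A artefacts from the count.
#'
#' @param reads a [ReadObservationSet].
#' @param panel a [DiagnosticPanel].
#' @param transversionsOnly restrict to transversion-class loci.
#' @param interval `"none"` (default) or `"jeffreys"` for a Jeffreys
#'   binomial interval on the contaminant fraction.
#' @param conf confidence level for the interval.
#' @return A [ContaminationEstimate].
#' @examples
#' panel <- makeDiagnosticPanel("MT", 1:2, c("A", "C"), c("G", "A"))
#' reads <- makeReadObservationSet(data.frame(
#'   read = c("r1", "r2", "r3"), locus = c("MT:1", "MT:1", "MT:2"),
#'   allele = c("A", "G", "C")))
#' estimateContamination(reads, panel)  # 1 of 3 reads contaminant
#' @export
estimateContamination <- function(reads, panel,
                                  transversionsOnly = FALSE,
                                  interval = c("none", "jeffreys"),
                                  conf = 0.95) {
  interval <- match.arg(interval)
  tab <- panelTable(panel)
  if (transversionsOnly) {
    tab <- tab[tab$class == "transversion", , drop = FALSE]
    if (nrow(tab) == 0) stop("no informative loci: panel has no transversions")
  }
  cls <- classifyReads(readCalls(reads), tab)
  nInf <- sum(cls != "uninformative")
  nCont <- sum(cls == "contaminant")
  est <- if (nInf > 0) 100 * nCont / nInf else NA_real_
  lo <- hi <- NA_real_
  if (interval == "jeffreys" && nInf > 0) {
    a <- (1 - conf) / 2
    lo <- 100 * stats::qbeta(a, nCont + 0.5, nInf - nCont + 0.5)
    hi <- 100 * stats::qbeta(1 - a, nCont + 0.5, nInf - nCont + 0.5)
    if (nCont == 0) lo <- 0
    if (nCont == nInf) hi <- 100
  }
  new("ContaminationEstimate",
      informativeReads = as.integer(nInf), contaminantReads = as.integer(nCont),
      estimatePct = est,
      mode = if (transversionsOnly) "transversions_only" else "all_sites",
      lowerPct = lo, upperPct = hi, source = NA_character_)
}

# per-read classification: "endogenous", "contaminant" or "uninformative"
classifyReads <- function(calls, tab) {
  calls <- calls[calls$locus %in% tab$locus, , drop = FALSE]
  if (nrow(calls) == 0) return(character(0))
  i <- match(calls$locus, tab$locus)
  isEndo <- calls$allele == tab$endogenous[i]
  contList <- strsplit(tab$contaminant, ",", fixed = TRUE)
  isCont <- mapply(function(a, j) a %in% contList[[j]], calls$allele, i)
  status <- vapply(split(seq_len(nrow(calls)), calls$read), function(rows) {
    if (any(isCont[rows])) "contaminant"
    else if (any(isEndo[rows])) "endogenous"
    else "uninformative"
  }, character(1))
  status
}

#' X-chromosome contamination estimates for a hemizygous male
#'
#' A male is hemizygous for the X, so every authentic read at an
#' X-chromosomal diagnostic site must carry the sample's single allele;
#' reads carrying a different lineage-diagnostic allele measure
#' contamination from that lineage. One estimate is produced per putative
#' contaminating source, using the same read-counting contract as
#' [estimateContamination].
#'
#' @param reads a [ReadObservationSet] of X-chromosome diagnostic-site
#'   observations.
#' @param panels a named list of [DiagnosticPanel] objects, one per putative
#'   contaminating lineage (each with that lineage's alleles as
#'   contaminants).
#' @param sex a [SexAssignment]; the estimate is refused unless the call is
#'   male, because the hemizygosity argument does not hold otherwise.
#' @param ... passed to [estimateContamination].
#' @return A named list of [ContaminationEstimate] objects, one per source.
#' @export
estimateXContamination <- function(reads, panels, sex, ...) {
  if (!is(sex, "SexAssignment")) stop("sex must be a SexAssignment")
  if (sexCall(sex) != "male")
    stop("X-hemizygosity contamination estimate requires a male sample; ",
         "sex call is '", sexCall(sex), "' (ratio ", signif(sex@ratio, 3), ")")
  if (is(panels, "DiagnosticPanel")) panels <- list(source = panels)
  out <- lapply(names(panels), function(nm) {
    est <- estimateContamination(reads, panels[[nm]], ...)
    est@source <- nm
    est
  })
  stats::setNames(out, names(panels))
}

#' Infer sex from the X/autosome depth ratio
#'
#' @param depthByChrom named numeric vector (or 2-column data.frame
#'   `chrom`/`depth`) of mean fold-coverage per chromosome.
#' @param autosomes chromosome names to average for the autosomal depth;
#'   default: everything except `xName`.
#' @param xName name of the X chromosome (default `"X"`).
#' @param maleMax call male when ratio < `maleMax` (default 0.6).
#' @param femaleMin call female when ratio > `femaleMin` (default 0.8);
#'   ratios between the thresholds are ambiguous.
#' @return A [SexAssignment].
#' @export
inferSex <- function(depthByChrom, autosomes = NULL, xName = "X",
                     maleMax = 0.6, femaleMin = 0.8) {
  if (is.data.frame(depthByChrom))
    depthByChrom <- stats::setNames(depthByChrom$depth, depthByChrom$chrom)
  if (!xName %in% names(depthByChrom))
    stop("X chromosome '", xName, "' absent from depth table")
  if (is.null(autosomes)) autosomes <- setdiff(names(depthByChrom), xName)
  if (length(autosomes) < 1) stop("need at least one autosome")
  autoDepth <- mean(depthByChrom[autosomes])
  if (autoDepth == 0) stop("autosomal mean depth is zero")
  xDepth <- unname(depthByChrom[xName])
  ratio <- xDepth / autoDepth
  call <- if (ratio < maleMax) "male" else if (ratio > femaleMin) "female"
          else "ambiguous"
  new("SexAssignment", xMeanDepth = xDepth, autosomalMeanDepth = autoDepth,
      ratio = ratio, call = call, maleMax = maleMax, femaleMin = femaleMin)
}

#' @describeIn inferSex the sex call of a [SexAssignment].
#' @param x a `SexAssignment`.
#' @export
sexCall <- function(x) x@call

#' Summarise fragment lengths
#'
#' Ancient-DNA fragments are short (typically well under 200 bp); the median
#' length and the proportions within reference ranges are standard
#' authenticity descriptors. The median is the lower median for even counts,
#' so it is always an observed length.
#'
#' @param lengths numeric vector of fragment lengths (bp) or a
#'   [ReadObservationSet] with recorded lengths.
#' @param ranges list of `c(lo, hi)` pairs; fractions are inclusive on both
#'   ends. Default: 16–150 and 20–150 bp.
#' @return A [FragmentLengthSummary].
#' @export
summarizeFragmentLengths <- function(lengths,
                                     ranges = list(c(16, 150), c(20, 150))) {
  if (is(lengths, "ReadObservationSet")) lengths <- fragmentLengths(lengths)$length
  if (length(lengths) == 0) stop("no fragment lengths supplied")
  s <- sort(lengths)
  med <- s[(length(s) + 1L) %/% 2L]
  fr <- do.call(rbind, lapply(ranges, function(r) {
    data.frame(lo = r[1], hi = r[2],
               fraction = mean(lengths >= r[1] & lengths <= r[2]))
  }))
  new("FragmentLengthSummary", nFragments = length(lengths),
      medianBp = med, fractions = fr)
}

#' Empirical terminal damage profile
#'
#' Computes, for each read end and each distance `pos = 1..k` from that end,
#' the rate of every reference -> read base substitution conditioned on the
#' reference base (the conventional terminal-misincorporation plot).
#' Post-mortem cytosine deamination shows up as C>T inflation at 5' ends
#' and, on the complementary strand, G>A inflation at 3' ends, decaying
#' with distance into the read.
#'
#' @param reads a [ReadObservationSet] with terminal mismatch tracks.
#' @param k number of terminal positions to profile (default 25).
#' @return A [DamageProfile]; rates are `NA` where no read presented the
#'   conditioning reference base.
#' @export
damageProfile <- function(reads, k = 25L) {
  mm <- terminalMismatches(reads)
  if (nrow(mm) == 0) stop("no terminal mismatch observations present")
  k <- as.integer(k)
  mm <- mm[mm$pos >= 1L & mm$pos <= k, , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(end = c("5p", "3p"), pos = seq_len(k), ref = bases,
                      obs = bases, stringsAsFactors = FALSE)
  refCount <- stats::aggregate(list(nRef = mm$pos),
    by = list(end = mm$end, pos = mm$pos, ref = mm$ref), FUN = length)
  obsCount <- stats::aggregate(list(nObs = mm$pos),
    by = list(end = mm$end, pos = mm$pos, ref = mm$ref, obs = mm$obs),
    FUN = length)
  grid <- merge(grid, refCount, all.x = TRUE, by = c("end", "pos", "ref"))
  grid <- merge(grid, obsCount, all.x = TRUE,
                by = c("end", "pos", "ref", "obs"))
  grid$nRef[is.na(grid$nRef)] <- 0L
  grid$nObs[is.na(grid$nObs)] <- 0L
  grid$rate <- ifelse(grid$nRef > 0, grid$nObs / grid$nRef, NA_real_)
  grid <- grid[order(grid$end, grid$pos, grid$ref, grid$obs), ]
  rownames(grid) <- NULL
  new("DamageProfile", k = k, rates = grid)
}

#' @describeIn damageProfile the 5' C>T rate curve (length `k`, `NA` where
#'   unobserved).
#' @param x a `DamageProfile`.
#' @export
ctRate5p <- function(x) substitutionRate(x, "5p", "C", "T")

#' @describeIn damageProfile the 3' G>A rate curve.
#' @export
gaRate3p <- function(x) substitutionRate(x, "3p", "G", "A")

#' @describeIn damageProfile rate curve for an arbitrary end and base pair.
#' @param end `"5p"` or `"3p"`.
#' @param ref,obs reference and read base.
#' @export
substitutionRate <- function(x, end, ref, obs) {
  r <- x@rates
  sel <- r[r$end == end & r$ref == ref & r$obs == obs, ]
  stats::setNames(sel$rate[order(sel$pos)], seq_len(x@k))
}

#' @describeIn estimateContamination percentage estimate accessor.
#' @param x a `ContaminationEstimate`.
#' @export
contaminationPct <- function(x) x@estimatePct

#' @describeIn estimateContamination informative read count accessor.
#' @export
informativeReads <- function(x) x@informativeReads

#' @describeIn estimateContamination contaminant read count accessor.
#' @export
contaminantReads <- function(x) x@contaminantReads

setMethod("show", "ContaminationEstimate", function(object) {
  cat(sprintf("ContaminationEstimate (%s%s): %d/%d reads -> %.2f%%\n",
              object@mode,
              if (is.na(object@source)) "" else paste0(", source ", object@source),
              object@contaminantReads, object@informativeReads,
              object@estimatePct))
  if (!is.na(object@lowerPct))
    cat(sprintf("  interval: [%.2f%%, %.2f%%]\n", object@lowerPct,
                object@upperPct))
})

setMethod("show", "SexAssignment", function(object) {
  cat(sprintf("SexAssignment: X %.2fx / autosomes %.2fx = ratio %.3f -> %s\n",
              object@xMeanDepth, object@autosomalMeanDepth, object@ratio,
              object@call))
})

setMethod("show", "FragmentLengthSummary", function(object) {
  cat(sprintf("FragmentLengthSummary: n = %d, median %g bp\n",
              object@nFragments, object@medianBp))
  for (i in seq_len(nrow(object@fractions)))
    cat(sprintf("  %g-%g bp: %.2f%%\n", object@fractions$lo[i],
                object@fractions$hi[i], 100 * object@fractions$fraction[i]))
})

setMethod("show", "DamageProfile", function(object) {
  ct <- ctRate5p(object); ga <- gaRate3p(object)
  cat(sprintf("DamageProfile over %d terminal positions\n", object@k))
  cat(sprintf("  5' C>T at pos 1: %s; 3' G>A at pos 1: %s\n",
              format(ct[1], digits = 3), format(ga[1], digits = 3)))
})
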