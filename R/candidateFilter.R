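#' Cross-taxon fixation filter
#'
#' Retains loci where two taxon groups are near-fixed (allele frequency at
#' or above `threshold`) for *opposite* alleles and the ancient sample is
#' homozygous for group 2's major allele — the signature of a variant that
#' rose toward fixation in group 1 after the ancient lineage diverged.
#'
#' @param freqs a [FrequencyTable] containing both group frequency columns
#'   (e.g. built from per-group pooled samples).
#' @param group1,group2 population/group labels in `freqs`.
#' @param ancientDosage per-locus alternate-allele dosage of the ancient
#'   sample (0..ploidy, `NA` = uncalled), aligned with the loci of `freqs`.
#' @param ancientPloidy 2 (diploid calls, default) or 1 (pseudo-haploid; a
#'   single called allele is taken as the homozygous state).
#' @param threshold near-fixation frequency (default 0.95).
#' @return list with `loci` (integer indices of retained loci), `table`
#'   (data.frame locus, freqGroup1, freqGroup2, ancientDosage,
#'   group2MajorAllele), and `skippedMissing` (loci meeting the frequency
#'   criterion but lacking an ancient call).
#' @export
fixationFilter <- function(freqs, group1, group2, ancientDosage,
                           ancientPloidy = 2L, threshold = 0.95) {
  miss <- setdiff(c(group1, group2), populations(freqs))
  if (length(miss)) stop("group(s) absent: ", paste(miss, collapse = ", "))
  f <- freqMatrix(freqs)
  p1 <- f[, group1]; p2 <- f[, group2]
  if (length(ancientDosage) != nrow(f))
    stop("ancientDosage must align with the loci of freqs")
  # opposite near-fixed alleles; group2's major allele determines the
  # required ancient homozygous state
  altFixed1 <- !is.na(p1) & !is.na(p2) & p1 >= threshold & (1 - p2) >= threshold
  refFixed1 <- !is.na(p1) & !is.na(p2) & (1 - p1) >= threshold & p2 >= threshold
  freqPass <- altFixed1 | refFixed1
  homAlt <- !is.na(ancientDosage) & ancientDosage == ancientPloidy
  homRef <- !is.na(ancientDosage) & ancientDosage == 0L
  keep <- (altFixed1 & homRef) | (refFixed1 & homAlt)
  skipped <- sum(freqPass & is.na(ancientDosage))
  idx <- unname(which(keep))
  gr <- loci(freqs)
  tab <- data.frame(
    locus = if (!is.null(names(gr))) names(gr)[idx]
            else paste0(as.character(seqnames(gr))[idx], ":", start(gr)[idx]),
    chrom = as.character(seqnames(gr))[idx], pos = start(gr)[idx],
    freqGroup1 = p1[idx], freqGroup2 = p2[idx],
    ancientDosage = ancientDosage[idx],
    group2MajorAllele = ifelse(altFixed1[idx], "ref", "alt"),
    row.names = NULL)
  list(loci = idx, table = tab, skippedMissing = skipped)
}

#' Build gene models for region classification
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open, BED convention) and `strand` (`"+"`, `"-"`, or
#'   `"*"` for strandless).
#' @param features optional data.frame of sub-features with columns
#'   `gene_id`, `type` (`"exon"`, `"utr5"`, `"utr3"`), `start`, `end`
#'   (0-based half-open); must lie within their gene's bounds.
#' @return A list of class `GeneModels` holding `genes` and `features` as
#'   `GRanges` (1-based internally).
#' @export
makeGeneModels <- function(genes, features = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes)))
    stop("genes need columns: ", paste(need, collapse = ", "))
  if (any(genes$start >= genes$end)) stop("gene start must be < end")
  ord <- order(genes$chrom, genes$start)
  genes <- genes[ord, , drop = FALSE]
  gGr <- GRanges(genes$chrom, IRanges(genes$start + 1L, genes$end),
                 strand = genes$strand, gene_id = genes$gene_id)
  fGr <- GRanges()
  if (!is.null(features) && nrow(features)) {
    if (!all(features$type %in% c("exon", "utr5", "utr3")))
      stop("feature type must be exon, utr5 or utr3")
    gi <- match(features$gene_id, genes$gene_id)
    if (anyNA(gi)) stop("feature references unknown gene_id")
    chrom <- genes$chrom[gi]
    if (any(features$start < genes$start[gi] | features$end > genes$end[gi]))
      stop("sub-features must lie within gene bounds")
    fGr <- GRanges(chrom, IRanges(features$start + 1L, features$end),
                   gene_id = features$gene_id, type = features$type)
  }
  structure(list(genes = gGr, features = fGr), class = "GeneModels")
}

#' Read gene models from BED files
#'
#' @param genesBed BED6 file of gene bodies (name column = gene id).
#' @param featuresBed optional BED file of sub-features whose name column is
#'   `gene_id:type` with type in exon/utr5/utr3.
#' @return A `GeneModels` list (see [makeGeneModels]).
#' @export
readGeneModelsBed <- function(genesBed, featuresBed = NULL) {
  g <- rtracklayer::import(genesBed, format = "BED")
  genes <- data.frame(gene_id = g$name,
                      chrom = as.character(seqnames(g)),
                      start = start(g) - 1L, end = end(g),
                      strand = as.character(GenomicRanges::strand(g)))
  features <- NULL
  if (!is.null(featuresBed)) {
    f <- rtracklayer::import(featuresBed, format = "BED")
    parts <- strsplit(f$name, ":", fixed = TRUE)
    features <- data.frame(
      gene_id = vapply(parts, `[`, character(1), 1),
      type = vapply(parts, `[`, character(1), 2),
      start = start(f) - 1L, end = end(f))
  }
  makeGeneModels(genes, features)
}

#' Classify variant loci by gene-relative region
#'
#' The most specific class wins: UTR/exon within a gene beat intron, which
#' beats the 5 kb (default) upstream/downstream flanks, which beat
#' intergenic. Upstream/downstream follow the gene's strand (a strandless
#' gene falls back to coordinate order, with a warning). Genes without
#' annotated sub-features are treated as exonic over their whole body.
#' When several genes yield the same best class, the first gene in sorted
#' order is reported and the tie is flagged.
#'
#' @param lociGr `GRanges` of variant positions (width-1, 1-based).
#' @param genes a `GeneModels` object from [makeGeneModels].
#' @param flankBp flank distance in bp (default 5000); `0` disables flank
#'   classes.
#' @return data.frame with columns `locus`, `region`, `gene_id`, `tie`.
#' @export
regionClassify <- function(lociGr, genes, flankBp = 5000L) {
  gGr <- genes$genes; fGr <- genes$features
  hasFeat <- unique(as.character(mcols(fGr)$gene_id))
  strandless <- as.character(GenomicRanges::strand(gGr)) == "*"
  if (any(strandless) && flankBp > 0)
    warning("strandless gene model(s); upstream/downstream taken from ",
            "coordinate order")
  rank <- c(utr5 = 1, utr3 = 1, exon = 1, intron = 2, flank_up = 3,
            flank_down = 3, intergenic = 4)
  n <- length(lociGr)
  out <- data.frame(
    locus = if (!is.null(names(lociGr))) names(lociGr)
            else paste0(as.character(seqnames(lociGr)), ":", start(lociGr)),
    region = rep("intergenic", n), gene_id = NA_character_,
    tie = FALSE)
  if (length(gGr) == 0 || n == 0) return(out)
  ext <- GenomicRanges::resize(gGr, GenomicRanges::width(gGr) + 2L * flankBp,
                               fix = "center")
  ov <- GenomicRanges::findOverlaps(lociGr, ext, ignore.strand = TRUE)
  classify1 <- function(pos, chrom, gi) {
    g <- gGr[gi]
    gid <- mcols(g)$gene_id
    gs <- start(g); ge <- end(g)
    if (pos >= gs && pos <= ge) {
      if (gid %in% hasFeat) {
        feats <- fGr[mcols(fGr)$gene_id == gid]
        hit <- feats[start(feats) <= pos & end(feats) >= pos]
        if (length(hit)) {
          types <- mcols(hit)$type
          if ("utr5" %in% types) return("utr5")
          if ("utr3" %in% types) return("utr3")
          return("exon")
        }
        return("intron")
      }
      return("exon")
    }
    if (flankBp == 0) return("intergenic")
    std <- as.character(GenomicRanges::strand(g))
    before <- pos < gs   # 5' side in coordinate order
    if (std == "-") {
      if (before) "flank_down" else "flank_up"
    } else {
      if (before) "flank_up" else "flank_down"
    }
  }
  hitsByLocus <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  for (qi in names(hitsByLocus)) {
    i <- as.integer(qi)
    pos <- start(lociGr)[i]
    cls <- vapply(hitsByLocus[[qi]], function(gi)
      classify1(pos, NULL, gi), character(1))
    best <- min(rank[cls])
    sel <- which(rank[cls] == best)
    out$region[i] <- cls[sel[1]]
    out$gene_id[i] <- mcols(gGr)$gene_id[hitsByLocus[[qi]][sel[1]]]
    out$tie[i] <- length(sel) > 1
  }
  out
}

#' Assemble the candidate-variant report
#'
#' Joins fixation-filter survivors with their region classes and retains
#' only gene-associated classes (exon, UTRs, flanks), with per-class
#' counts.
#'
#' @param filtered result of [fixationFilter].
#' @param classes result of [regionClassify] on the survivor loci (matched
#'   by `locus`).
#' @param retainClasses region classes to keep.
#' @return list with `table` (retained candidates with region and gene) and
#'   `classCounts`.
#' @export
candidateReport <- function(filtered, classes,
                            retainClasses = c("exon", "utr5", "utr3",
                                              "flank_up", "flank_down")) {
  tab <- merge(filtered$table, classes, by = "locus", sort = FALSE)
  kept <- tab[tab$region %in% retainClasses, , drop = FALSE]
  rownames(kept) <- NULL
  counts <- table(factor(kept$region, levels = retainClasses))
  list(table = kept, classCounts = as.data.frame(counts,
       responseName = "count", stringsAsFactors = FALSE))
}
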