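#' Classify a variant by kind, mutation class and ancient genotype
#'
#' A variant is a SNP when both alleles are single bases, otherwise an
#' indel. SNPs are transitions when the alleles are A/G or C/T, else
#' transversions (indels have class `"not_applicable"`). The ancient
#' genotype is `"heterozygous"` when exactly one of the sample's two
#' alleles differs from the reference and `"homozygous"` when both do;
#' sites heterozygous for two non-reference alleles fall outside the
#' biallelic scope and classify as `NA`.
#'
#' @param ref,alt reference and alternate allele strings over A/C/G/T.
#' @param genotype the ancient sample's two alleles, e.g. `c("A", "G")`
#'   or `"A/G"`; `NULL` leaves the genotype `NA`.
#' @return list with `kind`, `class`, `genotype`.
#' @examples
#' classifyVariant("A", "G", c("A", "G"))
#' classifyVariant("AC", "A")
#' @export
classifyVariant <- function(ref, alt, genotype = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!nzchar(ref) || !nzchar(alt) ||
      grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt))
    stop("alleles must be non-empty strings over A/C/G/T")
  if (ref == alt) stop("ref and alt alleles are identical")
  kind <- if (nchar(ref) == 1L && nchar(alt) == 1L) "snp" else "indel"
  cls <- if (kind == "snp") {
    if (isTransition(ref, alt)) "transition" else "transversion"
  } else "not_applicable"
  gen <- NA_character_
  if (!is.null(genotype)) {
    if (is.character(genotype) && length(genotype) == 1L)
      genotype <- strsplit(genotype, "[/|]")[[1]]
    genotype <- toupper(genotype)
    nDiff <- sum(genotype != ref)
    gen <- if (nDiff == 2L && length(unique(genotype)) > 1L) NA_character_
           else if (nDiff == 2L) "homozygous"
           else if (nDiff == 1L) "heterozygous"
           else NA_character_
  }
  list(kind = kind, class = cls, genotype = gen)
}

#' Filter variants on depth and recalibrated LOD score
#'
#' Retains records with `depth >= minDepth` (inclusive) and
#' `lod > minLod` (exclusive).
#'
#' @param variants data.frame with columns `depth` and (unless `noLod`)
#'   `lod`.
#' @param minDepth minimum read depth (default 5).
#' @param minLod LOD threshold (default 2).
#' @param noLod skip the LOD criterion (for call sets without scores).
#' @return The retained rows, with attributes `nBefore`/`nAfter`.
#' @export
applyQualityFilter <- function(variants, minDepth = 5, minLod = 2,
                               noLod = FALSE) {
  if (!"depth" %in% names(variants)) stop("variants need a 'depth' column")
  keep <- variants$depth >= minDepth
  if (!noLod) {
    if (!"lod" %in% names(variants))
      stop("variants lack a 'lod' column; use noLod = TRUE to skip")
    keep <- keep & variants$lod > minLod
  }
  out <- variants[keep, , drop = FALSE]
  attr(out, "nBefore") <- nrow(variants)
  attr(out, "nAfter") <- nrow(out)
  out
}

#' Tabulate classified variants
#'
#' Builds the variant summary: one cell per (kind x ancient genotype x
#' mutation class) with its count and, when membership flags are present,
#' the percentage of the cell found in dbSNP and in the modern
#' re-sequencing panel. Records whose ancient genotype is not biallelic-
#' classifiable are dropped and counted as `untabulated`.
#'
#' @param variants data.frame with columns `ref`, `alt`, `genotype`
#'   (two-allele string like `"A/G"`), and optional logical `inDbsnp`,
#'   `inModernPanel`.
#' @return A list of class `VariantSummary`: `cells` (data.frame `kind`,
#'   `genotype`, `class`, `count`, `pctDbsnp`, `pctPanel`), `untabulated`
#'   count, plus per-kind summaries from [summarizeVariantCells].
#' @export
tabulateVariants <- function(variants) {
  if (nrow(variants) == 0)
    return(summarizeVariantCells(data.frame(
      kind = character(), genotype = character(), class = character(),
      count = integer(), pctDbsnp = numeric(), pctPanel = numeric()),
      untabulated = 0L))
  cl <- lapply(seq_len(nrow(variants)), function(i)
    classifyVariant(variants$ref[i], variants$alt[i], variants$genotype[i]))
  kind <- vapply(cl, `[[`, character(1), "kind")
  mcls <- vapply(cl, `[[`, character(1), "class")
  gen <- vapply(cl, `[[`, character(1), "genotype")
  ok <- !is.na(gen)
  df <- data.frame(kind = kind[ok], genotype = gen[ok], class = mcls[ok])
  hasDb <- "inDbsnp" %in% names(variants)
  hasPan <- "inModernPanel" %in% names(variants)
  if (hasDb) df$inDbsnp <- variants$inDbsnp[ok]
  if (hasPan) df$inModernPanel <- variants$inModernPanel[ok]
  cells <- stats::aggregate(list(count = rep(1L, nrow(df))),
    by = df[c("kind", "genotype", "class")], FUN = length)
  pct <- function(flagCol) {
    if (is.null(df[[flagCol]])) return(rep(NA_real_, nrow(cells)))
    agg <- stats::aggregate(list(p = df[[flagCol]]),
      by = df[c("kind", "genotype", "class")], FUN = function(v) 100 * mean(v))
    agg$p[match(interaction(cells$kind, cells$genotype, cells$class),
                interaction(agg$kind, agg$genotype, agg$class))]
  }
  cells$pctDbsnp <- pct("inDbsnp")
  cells$pctPanel <- pct("inModernPanel")
  summarizeVariantCells(cells, untabulated = sum(!ok))
}

#' Summaries (totals, fractions, weighted means) from summary cells
#'
#' Accepts the cell table directly — e.g. printed counts and percentages
#' from a published variant table — and computes per-kind totals,
#' homozygous fractions and count-weighted mean percentages
#' (`sum(count_i * pct_i) / sum(count_i)`).
#'
#' @param cells data.frame with columns `kind` (`"snp"`/`"indel"`),
#'   `genotype` (`"heterozygous"`/`"homozygous"`), `class`, `count`, and
#'   optional `pctDbsnp`, `pctPanel`.
#' @param untabulated count of records excluded from the cells.
#' @return list of class `VariantSummary` with elements `cells`,
#'   `untabulated`, and `byKind`: a data.frame per variant kind with
#'   `total`, `homozygousFraction` (percent), `wmeanDbsnp`, `wmeanPanel`.
#' @export
summarizeVariantCells <- function(cells, untabulated = 0L) {
  kinds <- unique(cells$kind)
  wmean <- function(counts, pcts) {
    if (all(is.na(pcts)) || sum(counts) == 0) return(NA_real_)
    sum(counts * pcts) / sum(counts)
  }
  byKind <- do.call(rbind, lapply(kinds, function(k) {
    sub <- cells[cells$kind == k, ]
    tot <- sum(sub$count)
    hom <- sum(sub$count[sub$genotype == "homozygous"])
    data.frame(kind = k, total = tot,
               homozygousFraction = if (tot > 0) 100 * hom / tot else NA_real_,
               wmeanDbsnp = wmean(sub$count, sub$pctDbsnp),
               wmeanPanel = wmean(sub$count, sub$pctPanel))
  }))
  structure(list(cells = cells, untabulated = as.integer(untabulated),
                 byKind = byKind),
            class = "VariantSummary")
}

#' @export
print.VariantSummary <- function(x, ...) {
  cat("VariantSummary\n")
  print(x$cells, row.names = FALSE)
  cat("untabulated:", x$untabulated, "\n")
  if (!is.null(x$byKind)) print(x$byKind, row.names = FALSE)
  invisible(x)
}

#' Transition/transversion ratio of a variant summary
#'
#' `(heterozygous + homozygous transitions) / (het + hom transversions)`
#' over the SNP cells.
#'
#' @param summary a `VariantSummary` from [tabulateVariants] or
#'   [summarizeVariantCells].
#' @return The ti/tv ratio.
#' @export
titvRatio <- function(summary) {
  snp <- summary$cells[summary$cells$kind == "snp", ]
  ti <- sum(snp$count[snp$class == "transition"])
  tv <- sum(snp$count[snp$class == "transversion"])
  if (tv == 0) stop("no transversions; ti/tv ratio undefined")
  ti / tv
}
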