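#' Per-window polymorphism and divergence counts
#'
#' For each window, counts over the assessed sites `L`: `S`, the sites
#' polymorphic within the ingroup, and `Dv`, the sites monomorphic in the
#' ingroup whose (fixed) allele differs from the outgroup allele. Sites
#' missing in the outgroup, heterozygous in a diploid outgroup (no single
#' callable allele, unless `outgroupMode = "pseudohaploid"`), or fully
#' missing in the ingroup are excluded from `L`.
#'
#' @param gt a [GenotypeTable].
#' @param ingroupSamples,outgroupSample sample identifiers.
#' @param windows `GRanges` of non-overlapping windows.
#' @param outgroupMode `"called"` (default; a heterozygous diploid outgroup
#'   site is excluded) or `"pseudohaploid"` (one outgroup allele sampled at
#'   random, suited to a single low-coverage outgroup genome).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `L`, `S`, `Dv`, `testable` (`L > 0`).
#' @export
windowCounts <- function(gt, ingroupSamples, outgroupSample, windows,
                         outgroupMode = c("called", "pseudohaploid")) {
  outgroupMode <- match.arg(outgroupMode)
  miss <- setdiff(c(ingroupSamples, outgroupSample), colnames(gt))
  if (length(miss)) stop("sample(s) absent: ", paste(miss, collapse = ", "))
  ov <- GenomicRanges::findOverlaps(loci(gt), windows)
  if (anyDuplicated(S4Vectors::queryHits(ov)))
    stop("windows overlap; a locus falls in more than one window")
  d <- dosage(gt)
  din <- d[, ingroupSamples, drop = FALSE]
  dout <- d[, outgroupSample]
  plOut <- ploidy(gt)[outgroupSample]
  # outgroup allele as alt dosage on {0, 1}: NA when uncallable
  outAllele <- if (plOut == 1L) dout else ifelse(
    dout == 0L, 0L, ifelse(dout == 2L, 1L, NA_integer_))
  if (outgroupMode == "pseudohaploid" && plOut == 2L) {
    het <- !is.na(dout) & dout == 1L
    outAllele[het] <- stats::rbinom(sum(het), 1L, 0.5)
  }
  nObs <- rowSums(!is.na(din))
  anyAlt <- rowSums(din > 0, na.rm = TRUE) > 0
  plIn <- ploidy(gt)[ingroupSamples]
  maxDose <- matrix(plIn, nrow(din), ncol(din), byrow = TRUE)
  anyRef <- rowSums(din < maxDose, na.rm = TRUE) > 0
  assessed <- !is.na(outAllele) & nObs > 0
  polymorphic <- assessed & anyAlt & anyRef
  mono <- assessed & !polymorphic
  inAllele <- ifelse(anyAlt, 1L, 0L)  # the fixed ingroup allele when mono
  divergent <- mono & inAllele != outAllele
  res <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(windows)),
    start = GenomicRanges::start(windows) - 1L,
    end = GenomicRanges::end(windows))
  tallyBy <- function(flag) {
    v <- integer(length(windows))
    t <- tapply(flag[S4Vectors::queryHits(ov)], S4Vectors::subjectHits(ov), sum)
    v[as.integer(names(t))] <- as.integer(t)
    v
  }
  res$L <- tallyBy(assessed)
  res$S <- tallyBy(polymorphic)
  res$Dv <- tallyBy(divergent)
  res$testable <- res$L > 0
  res
}

#' HKA-style selection scan over windows
#'
#' Under neutrality the ratio of within-ingroup polymorphism (`S`) to
#' ingroup–outgroup divergence (`Dv`) is constant across the genome; a
#' selective sweep locally depresses polymorphism relative to divergence.
#' For each testable window, expected counts are computed from the
#' genome-wide totals excluding that window's own counts (leave-one-out):
#' `E_S = (S + Dv) * S_tot / (S_tot + Dv_tot)` and similarly `E_Dv`; the
#' statistic is the 1-df chi-square `(S - E_S)^2/E_S + (Dv - E_Dv)^2/E_Dv`,
#' with a Fisher exact fallback on the 2x2 table when an expectation is
#' zero. P values are adjusted across testable windows with
#' Benjamini–Hochberg. When no adjusted value passes `alpha`, raw
#' `p <= alpha` windows should be read as suggestive only.
#'
#' @param counts data.frame from [windowCounts].
#' @return `counts` with added columns `E_S`, `E_Dv`, `stat`, `p`, `q`,
#'   `direction` (`"polymorphism_deficit"` — sweep-like — when `S < E_S`,
#'   else `"polymorphism_excess"`).
#' @export
hkaScan <- function(counts) {
  t <- counts$testable
  if (sum(t) < 2) stop("need at least 2 testable windows")
  Stot <- sum(counts$S[t]); Dtot <- sum(counts$Dv[t])
  if (Stot == 0 || Dtot == 0)
    stop("genome totals must be positive for both S and Dv")
  n <- nrow(counts)
  ES <- EDv <- stat <- p <- rep(NA_real_, n)
  for (i in which(t)) {
    Srest <- Stot - counts$S[i]; Drest <- Dtot - counts$Dv[i]
    tot <- counts$S[i] + counts$Dv[i]
    if (Srest + Drest == 0) next
    ES[i] <- tot * Srest / (Srest + Drest)
    EDv[i] <- tot * Drest / (Srest + Drest)
    if (tot == 0) { stat[i] <- 0; p[i] <- 1; next }
    if (ES[i] == 0 || EDv[i] == 0) {
      p[i] <- stats::fisher.test(matrix(c(counts$S[i], counts$Dv[i],
                                          Srest, Drest), 2))$p.value
    } else {
      stat[i] <- (counts$S[i] - ES[i])^2 / ES[i] +
                 (counts$Dv[i] - EDv[i])^2 / EDv[i]
      p[i] <- stats::pchisq(stat[i], df = 1, lower.tail = FALSE)
    }
  }
  counts$E_S <- ES
  counts$E_Dv <- EDv
  counts$stat <- stat
  counts$p <- p
  counts$q <- NA_real_
  ok <- !is.na(p)
  counts$q[ok] <- bhAdjust(p[ok])
  counts$direction <- ifelse(!is.na(ES) & counts$S < ES,
                             "polymorphism_deficit", "polymorphism_excess")
  counts$direction[!ok] <- NA_character_
  counts
}

#' Benjamini–Hochberg FDR adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`: step-up adjusted
#' values, capped at 1, monotone in p-value rank.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted q-values, same length/order as `p`.
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}
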