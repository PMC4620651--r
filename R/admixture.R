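#' Weighted block jackknife for a ratio / mean statistic
#'
#' Leave-one-block-out resampling over contiguous genomic blocks with
#' block weights `m_k` (informative sites per block), using the delete-m
#' weighted jackknife of Busing, Meijer & van der Leeden (1999) — the
#' estimator conventionally used for D and f statistics. With equal block
#' weights it reduces exactly to the unweighted delete-one jackknife.
#'
#' @param blockNum,blockDen per-block numerator and denominator sums of the
#'   statistic `theta = sum(num) / sum(den)` (for a plain mean, pass the
#'   per-block sums and block sizes).
#' @param blockWeights per-block weights `m_k`; defaults to `blockDen`.
#' @return list with `estimate` (full-data statistic), `se`, `z`,
#'   `nBlocks`.
#' @export
blockJackknife <- function(blockNum, blockDen, blockWeights = blockDen) {
  keep <- blockWeights > 0
  blockNum <- blockNum[keep]; blockDen <- blockDen[keep]
  m <- blockWeights[keep]
  g <- length(m)
  if (g < 2) stop("need at least 2 blocks with nonzero weight")
  n <- sum(m)
  totNum <- sum(blockNum); totDen <- sum(blockDen)
  if (totDen == 0) stop("zero denominator; statistic undefined")
  theta <- totNum / totDen
  thetaMinus <- (totNum - blockNum) / (totDen - blockDen)
  h <- n / m
  thetaJ <- g * theta - sum((1 - m / n) * thetaMinus)
  tau <- h * theta - (h - 1) * thetaMinus
  variance <- sum((tau - thetaJ)^2 / (h - 1)) / g
  se <- sqrt(variance)
  list(estimate = theta, se = se,
       z = if (se > 0) theta / se else ifelse(theta == 0, 0, sign(theta) * Inf),
       nBlocks = g)
}

#' Assign used sites to contiguous blocks
#'
#' @param nSites number of used sites, in genomic order.
#' @param blockSize sites per block (default 50); the final block absorbs
#'   any remainder shorter than half a block.
#' @return integer vector of block ids.
#' @export
makeBlocks <- function(nSites, blockSize = 50L) {
  if (nSites < 1) return(integer(0))
  b <- (seq_len(nSites) - 1L) %/% as.integer(blockSize) + 1L
  nb <- max(b)
  if (nb > 1 && sum(b == nb) < blockSize / 2) b[b == nb] <- nb - 1L
  b
}

dstatSiteTerms <- function(p1, p2, pa, po, polarize) {
  if (polarize) {
    abba <- (1 - p1) * p2 * pa * (1 - po)
    baba <- p1 * (1 - p2) * pa * (1 - po)
  } else {
    abba <- (1 - p1) * p2 * pa * (1 - po) + p1 * (1 - p2) * (1 - pa) * po
    baba <- p1 * (1 - p2) * pa * (1 - po) + (1 - p1) * p2 * (1 - pa) * po
  }
  list(abba = abba, baba = baba)
}

#' ABBA/BABA D statistic with block-jackknife significance
#'
#' For the topology `(((P1, P2), A), O)` with per-site alternate-allele
#' frequencies p1, p2, pA, pO, the default symmetric (polarization-free)
#' site weights are
#' `ABBA = (1-p1) p2 pA (1-pO) + p1 (1-p2) (1-pA) pO` and
#' `BABA = p1 (1-p2) pA (1-pO) + (1-p1) p2 (1-pA) pO`, and
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)`. Under the null of no gene
#' flow the ABBA and BABA patterns are equally frequent and D = 0;
#' `D > 0` indicates gene flow between A and P2, `D < 0` between A and P1.
#' Significance comes from a weighted block jackknife over blocks of
#' consecutive used SNPs.
#'
#' @param freqs a [FrequencyTable] containing the four populations.
#' @param p1,p2,a,o population labels (two test populations, the archaic
#'   source candidate, and the outgroup).
#' @param blockSize consecutive used SNPs per jackknife block (default 50).
#' @param blocks optional explicit block assignment for the used sites,
#'   overriding `blockSize`.
#' @param polarize use strict outgroup polarization: sites where the
#'   outgroup is polymorphic (`pO` not 0 or 1) are skipped and only the
#'   outgroup-ancestral terms are used.
#' @return A [DStatResult].
#' @export
dStatistic <- function(freqs, p1, p2, a, o, blockSize = 50L, blocks = NULL,
                       polarize = FALSE) {
  need <- c(p1, p2, a, o)
  miss <- setdiff(need, populations(freqs))
  if (length(miss)) stop("population(s) absent: ", paste(miss, collapse = ", "))
  f <- freqMatrix(freqs)[, need, drop = FALSE]
  complete <- stats::complete.cases(f)
  skipped <- sum(!complete)
  if (polarize) {
    polarizable <- complete & (f[, 4] == 0 | f[, 4] == 1)
    skipped <- sum(!polarizable)
    complete <- polarizable
  }
  f <- f[complete, , drop = FALSE]
  terms <- dstatSiteTerms(f[, 1], f[, 2], f[, 3], f[, 4], polarize)
  den <- terms$abba + terms$baba
  if (sum(den) == 0) stop("no informative sites")
  nUsed <- nrow(f)
  if (is.null(blocks)) blocks <- makeBlocks(nUsed, blockSize)
  num <- terms$abba - terms$baba
  bNum <- as.numeric(rowsum(num, blocks))
  bDen <- as.numeric(rowsum(den, blocks))
  bW <- as.numeric(rowsum(rep(1, nUsed), blocks))
  # blocks without any ABBA/BABA weight contribute nothing to D and leave
  # the delete-one estimate untouched; drop them from the resampling
  nz <- bDen > 0
  jk <- if (sum(nz) >= 2) blockJackknife(bNum[nz], bDen[nz], bW[nz])
        else list(estimate = sum(num) / sum(den), se = NA_real_,
                  z = NA_real_, nBlocks = sum(nz))
  new("DStatResult", d = jk$estimate, se = jk$se, z = jk$z,
      nSitesUsed = as.integer(nUsed), nSitesSkipped = as.integer(skipped),
      sumAbba = sum(terms$abba), sumBaba = sum(terms$baba),
      nBlocks = as.integer(jk$nBlocks),
      populations = c(p1 = p1, p2 = p2, a = a, o = o),
      mode = if (polarize) "polarized" else "symmetric")
}

#' @describeIn dStatistic the D estimate.
#' @param x a `DStatResult`.
#' @export
dValue <- function(x) x@d

#' @describeIn dStatistic the jackknife Z score.
#' @export
zScore <- function(x) x@z

#' @describeIn dStatistic the jackknife standard error.
#' @export
standardError <- function(x) x@se

#' Three-population (f3) admixture test
#'
#' `f3(target; s1, s2)` is the mean over sites of `(x - a)(x - b)` where
#' `x`, `a`, `b` are the alternate-allele frequencies of the target and the
#' two sources; with `biasCorrection` the finite-sample term
#' `x(1 - x)/(n_x - 1)` is subtracted per site (`n_x` = observed allele
#' copies in the target). A significantly negative z indicates the target
#' is admixed between populations related to the two sources. The statistic
#' is symmetric in the sources; significance uses the same weighted block
#' jackknife as [dStatistic].
#'
#' @param freqs a [FrequencyTable].
#' @param target,source1,source2 population labels.
#' @param blockSize consecutive used SNPs per jackknife block (default 50).
#' @param biasCorrection subtract the sampling-variance term (default
#'   `TRUE`); requires at least 2 observed allele copies in the target at
#'   every used site.
#' @return An [F3Result].
#' @export
f3Statistic <- function(freqs, target, source1, source2, blockSize = 50L,
                        biasCorrection = TRUE) {
  need <- c(target, source1, source2)
  miss <- setdiff(need, populations(freqs))
  if (length(miss)) stop("population(s) absent: ", paste(miss, collapse = ", "))
  f <- freqMatrix(freqs)[, need, drop = FALSE]
  nx <- countMatrix(freqs)[, target]
  complete <- stats::complete.cases(f)
  f <- f[complete, , drop = FALSE]
  nx <- nx[complete]
  if (nrow(f) == 0) stop("no informative sites")
  x <- f[, 1]; a <- f[, 2]; b <- f[, 3]
  term <- (x - a) * (x - b)
  if (biasCorrection) {
    if (any(nx < 2))
      stop("bias correction requires >= 2 allele copies in the target at ",
           "every used site")
    term <- term - x * (1 - x) / (nx - 1)
  }
  nUsed <- length(term)
  blocks <- makeBlocks(nUsed, blockSize)
  bNum <- as.numeric(rowsum(term, blocks))
  bSize <- as.numeric(rowsum(rep(1, nUsed), blocks))
  jk <- if (length(bSize) >= 2) blockJackknife(bNum, bSize, bSize)
        else list(estimate = mean(term), se = NA_real_, z = NA_real_,
                  nBlocks = 1L)
  new("F3Result", f3 = jk$estimate, se = jk$se, z = jk$z,
      nSitesUsed = as.integer(nUsed), nBlocks = as.integer(jk$nBlocks),
      populations = c(target = target, source1 = source1, source2 = source2),
      biasCorrected = biasCorrection)
}

#' @describeIn f3Statistic the f3 estimate.
#' @param x an `F3Result`.
#' @export
f3Value <- function(x) x@f3

#' Per-population mean D over a panel of P2 populations
#'
#' Runs [dStatistic] for every (P1, P2) pair and summarises each P1 by its
#' mean D over the P2 panel — the per-population table behind a
#' geographical admixture contour map.
#'
#' @param freqs a [FrequencyTable].
#' @param p1List character vector of P1 populations.
#' @param p2Panel character vector of P2 panel populations.
#' @param a,o archaic and outgroup population labels.
#' @param ... passed to [dStatistic].
#' @return list with `pairs` (data.frame p1, p2, d, se, z, nSites) and
#'   `meanD` (data.frame p1, meanD).
#' @export
populationMeanD <- function(freqs, p1List, p2Panel, a, o, ...) {
  if (length(p2Panel) == 0) stop("P2 panel is empty")
  rows <- list()
  for (x1 in p1List) for (x2 in p2Panel) {
    r <- dStatistic(freqs, x1, x2, a, o, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      p1 = x1, p2 = x2, d = dValue(r), se = standardError(r),
      z = zScore(r), nSites = r@nSitesUsed)
  }
  pairs <- do.call(rbind, rows)
  meanD <- stats::aggregate(list(meanD = pairs$d), by = list(p1 = pairs$p1),
                            FUN = mean)
  meanD <- meanD[match(p1List, meanD$p1), , drop = FALSE]
  rownames(meanD) <- NULL
  list(pairs = pairs, meanD = meanD)
}

setMethod("show", "DStatResult", function(object) {
  p <- object@populations
  cat(sprintf("D(((%s, %s), %s), %s) [%s]\n", p["p1"], p["p2"], p["a"],
              p["o"], object@mode))
  cat(sprintf("  D = %.4f  se = %.4f  z = %.2f\n", object@d, object@se,
              object@z))
  cat(sprintf("  sites used %d (skipped %d), blocks %d, sum ABBA %.2f, sum BABA %.2f\n",
              object@nSitesUsed, object@nSitesSkipped, object@nBlocks,
              object@sumAbba, object@sumBaba))
})

setMethod("show", "F3Result", function(object) {
  p <- object@populations
  cat(sprintf("f3(%s; %s, %s)%s\n", p["target"], p["source1"], p["source2"],
              if (object@biasCorrected) " [bias-corrected]" else ""))
  cat(sprintf("  f3 = %.5f  se = %.5f  z = %.2f  (%d sites, %d blocks)\n",
              object@f3, object@se, object@z, object@nSitesUsed,
              object@nBlocks))
})
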