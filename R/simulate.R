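#' Default demography for the synthetic four-population panel
#'
#' Study conditions for the simulated system: a fixed population tree
#' `(((P1, P2), A), O)` — two closely related test populations, a divergent
#' "ancient" lineage A, and a distant outgroup O — with Balding–Nichols
#' beta drift along each branch and an optional one-off introgression of a
#' fraction `f` of A-lineage ancestry into one test population. Ancestral
#' allele frequencies are Uniform(0.05, 0.95), emulating the ascertainment
#' of a genotyping array toward common variants. Drift intensities F (the
#' Balding–Nichols variance parameters) default to 0.02 on each terminal
#' test-population branch, 0.05 on their shared branch, 0.25 on the
#' ancient-lineage branch and 0.5 on the outgroup branch; sample sizes
#' default to 20 diploids per test population, a single pseudo-haploid
#' ancient sample and 2 diploid outgroup samples.
#'
#' @param nLoci number of loci.
#' @param f introgression fraction in `[0, 1]`.
#' @param introgressInto `"P1"` or `"P2"`.
#' @param drift named list of branch F values (`p1`, `p2`, `shared`,
#'   `ancient`, `outgroup`).
#' @param sampleSizes named vector of sample counts (`P1`, `P2`, `A`, `O`).
#' @param ancestralRange range of the uniform ancestral frequency.
#' @return A list of demography parameters for [simulatePanel].
#' @export
demographyParams <- function(nLoci = 10000L, f = 0, introgressInto = "P1",
                             drift = list(p1 = 0.02, p2 = 0.02,
                                          shared = 0.05, ancient = 0.25,
                                          outgroup = 0.5),
                             sampleSizes = c(P1 = 20L, P2 = 20L, A = 1L,
                                             O = 2L),
                             ancestralRange = c(0.05, 0.95)) {
  stopifnot(f >= 0, f <= 1, nLoci >= 1,
            introgressInto %in% c("P1", "P2"),
            all(unlist(drift) >= 0), all(sampleSizes >= 1))
  list(nLoci = as.integer(nLoci), f = f, introgressInto = introgressInto,
       drift = drift, sampleSizes = sampleSizes,
       ancestralRange = ancestralRange)
}

# Balding-Nichols beta transition: child frequency given parent p, drift F.
# F = 0 is the no-drift degenerate limit (frequency unchanged).
bnDrift <- function(p, F) {
  if (F == 0) return(p)
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  stats::rbeta(length(p), a, b)
}

# random alternate allele differing from ref, vectorized
randomAlt <- function(ref) {
  bases <- c("A", "C", "G", "T")
  bases[(match(ref, bases) - 1L + sample(1:3, length(ref), replace = TRUE)) %% 4L + 1L]
}

#' Simulate a four-population genotype panel with known truth
#'
#' Draws ancestral frequencies, evolves them along the fixed tree
#' `(((P1, P2), A), O)` by Balding–Nichols drift, applies introgression as
#' a frequency mixture `p_target <- (1 - f) p_target + f p_A` using the
#' A lineage frequency, and samples genotype dosages binomially per
#' sample. The ancient population A is emitted as pseudo-haploid samples
#' (one allele per locus) when its sample size is 1, mirroring a single
#' low-coverage ancient genome.
#'
#' @param params from [demographyParams].
#' @param chrom chromosome label for the emitted loci.
#' @return list: `gt` (a [GenotypeTable] with populations attached),
#'   `popmap` (data.frame), `truth` (latent per-population frequencies and
#'   all parameters).
#' @examples
#' sim <- simulatePanel(demographyParams(nLoci = 100))
#' sim$gt
#' @export
simulatePanel <- function(params = demographyParams(), chrom = "1") {
  nl <- params$nLoci
  p0 <- stats::runif(nl, params$ancestralRange[1], params$ancestralRange[2])
  dr <- params$drift
  pO <- bnDrift(p0, dr$outgroup)
  pA <- bnDrift(p0, dr$ancient)
  pShared <- bnDrift(p0, dr$shared)
  pP1 <- bnDrift(pShared, dr$p1)
  pP2 <- bnDrift(pShared, dr$p2)
  if (params$f > 0) {
    if (params$introgressInto == "P1")
      pP1 <- (1 - params$f) * pP1 + params$f * pA
    else
      pP2 <- (1 - params$f) * pP2 + params$f * pA
  }
  lat <- list(P1 = pP1, P2 = pP2, A = pA, O = pO)
  ss <- params$sampleSizes
  mats <- list(); ids <- character(); pops <- character(); plo <- integer()
  for (pop in names(ss)) {
    n <- ss[[pop]]
    pl <- if (pop == "A" && n == 1L) 1L else 2L
    m <- matrix(stats::rbinom(nl * n, pl, rep(lat[[pop]], n)), nl, n)
    mats[[pop]] <- m
    ids <- c(ids, sprintf("%s_%02d", pop, seq_len(n)))
    pops <- c(pops, rep(pop, n))
    plo <- c(plo, rep(pl, n))
  }
  d <- do.call(cbind, mats)
  ref <- sample(c("A", "C", "G", "T"), nl, replace = TRUE)
  alt <- randomAlt(ref)
  gt <- makeGenotypeTable(d, chrom = rep(chrom, nl),
                          pos = seq_len(nl) * 1000L, ref = ref, alt = alt,
                          sampleIds = ids, ploidy = plo)
  popmap <- data.frame(sample = ids, population = pops,
                       group = ifelse(pops %in% c("P1", "P2"), "test",
                                      tolower(pops)))
  gt <- attachPopulations(gt, popmap)
  list(gt = gt, popmap = popmap,
       truth = c(params, list(latentFreq = lat)))
}

#' Parameters of the synthetic ancient read model
#'
#' Study conditions for simulated ancient reads: fragment lengths are
#' log-normal with median 50 bp (`meanlog = log(50)`, `sdlog = 0.35`)
#' truncated at 16 bp; terminal deamination follows the exponential decay
#' `d(i) = dMax * lambda^(i - 1)` with `dMax = 0.3`, `lambda = 0.5`,
#' acting as C>T at 5' ends and G>A at 3' ends; the sequencing error rate
#' is 0.001 per base; the contamination fraction `c` defaults to 0.
#'
#' @param nReads number of reads.
#' @param c contamination fraction in `[0, 1]`.
#' @param meanlog,sdlog,minLength truncated log-normal fragment model (bp).
#' @param dMax,lambda damage model parameters.
#' @param e per-base sequencing error rate.
#' @param damageK terminal positions simulated per end (0 disables the
#'   mismatch tracks, for large allele-call-only simulations).
#' @param contaminantDamage apply the damage model to contaminant reads
#'   too (off by default: modern DNA is undamaged).
#' @return parameter list for [simulateAncientReads].
#' @export
ancientReadParams <- function(nReads = 10000L, c = 0,
                              meanlog = log(50), sdlog = 0.35,
                              minLength = 16, dMax = 0.3, lambda = 0.5,
                              e = 0.001, damageK = 10L,
                              contaminantDamage = FALSE) {
  stopifnot(c >= 0, c <= 1, dMax >= 0, dMax <= 1, e >= 0, e <= 1,
            lambda > 0, lambda < 1, nReads >= 1, damageK >= 0)
  list(nReads = as.integer(nReads), c = c, meanlog = meanlog, sdlog = sdlog,
       minLength = minLength, dMax = dMax, lambda = lambda, e = e,
       damageK = as.integer(damageK), contaminantDamage = contaminantDamage)
}

#' Simulate ancient reads over a diagnostic panel, with known truth
#'
#' Each read is contaminant with probability `c` and observes one panel
#' locus (loci are cycled so coverage is even). The observed base is the
#' corresponding haplotype's allele, replaced by a uniformly chosen other
#' base with probability `e`. Fragment lengths follow the truncated
#' log-normal model. Terminal mismatch tracks are generated for
#' `damageK` positions per end with iid uniform reference bases: a 5'
#' reference C is read as T with probability `d(i) + e'` and a 3'
#' reference G as A likewise (damage on endogenous reads only, unless
#' `contaminantDamage`), all other bases suffer only sequencing error.
#'
#' @param params from [ancientReadParams].
#' @param panel a [DiagnosticPanel].
#' @param endogenousHaplotype,contaminantHaplotype named allele vectors
#'   over the panel loci; defaults: the panel's endogenous allele and its
#'   first contaminant allele.
#' @return list: `reads` (a [ReadObservationSet]), `truth` (per-read
#'   contaminant flags and the parameters).
#' @export
simulateAncientReads <- function(params = ancientReadParams(), panel,
                                 endogenousHaplotype = NULL,
                                 contaminantHaplotype = NULL) {
  tab <- panelTable(panel)
  if (is.null(endogenousHaplotype))
    endogenousHaplotype <- stats::setNames(tab$endogenous, tab$locus)
  if (is.null(contaminantHaplotype))
    contaminantHaplotype <- stats::setNames(
      vapply(strsplit(tab$contaminant, ",", fixed = TRUE), `[`, character(1), 1),
      tab$locus)
  if (!all(tab$locus %in% names(endogenousHaplotype)) ||
      !all(tab$locus %in% names(contaminantHaplotype)))
    stop("haplotypes must define alleles at every panel locus")
  n <- params$nReads
  bases <- c("A", "C", "G", "T")
  isCont <- stats::runif(n) < params$c
  locus <- tab$locus[(seq_len(n) - 1L) %% nrow(tab) + 1L]
  allele <- ifelse(isCont, contaminantHaplotype[locus],
                   endogenousHaplotype[locus])
  err <- stats::runif(n) < params$e
  if (any(err))
    allele[err] <- vapply(allele[err], function(a)
      sample(setdiff(bases, a), 1), character(1))
  readId <- sprintf("read%06d", seq_len(n))
  calls <- data.frame(read = readId, locus = locus, allele = unname(allele))
  lens <- stats::rlnorm(n, params$meanlog, params$sdlog)
  while (any(lens < params$minLength)) {
    i <- lens < params$minLength
    lens[i] <- stats::rlnorm(sum(i), params$meanlog, params$sdlog)
  }
  lengths <- data.frame(read = readId, length = round(lens))
  k <- params$damageK
  dRate <- params$dMax * params$lambda^(seq_len(k) - 1)
  mkEnd <- function(end, damagedBase, damagedTo) {
    ref <- sample(bases, n * k, replace = TRUE)
    obs <- ref
    pos <- rep(seq_len(k), each = n)
    damAllowed <- if (params$contaminantDamage) rep(TRUE, n * k)
                  else rep(!isCont, times = k)
    isTargetRef <- ref == damagedBase
    pDam <- ifelse(isTargetRef & damAllowed, dRate[pos], 0)
    dam <- stats::runif(n * k) < pDam
    obs[dam] <- damagedTo
    err2 <- !dam & stats::runif(n * k) < params$e
    if (any(err2))
      obs[err2] <- vapply(obs[err2], function(b)
        sample(setdiff(bases, b), 1), character(1))
    data.frame(read = rep(readId, times = k), end = end, pos = pos,
               ref = ref, obs = obs)
  }
  mism <- if (k > 0) rbind(mkEnd("5p", "C", "T"), mkEnd("3p", "G", "A"))
          else NULL
  reads <- makeReadObservationSet(calls, lengths, mism)
  list(reads = reads,
       truth = c(params, list(isContaminant = stats::setNames(isCont, readId),
                              damageRate = dRate)))
}

#' Simulate a windowed sweep panel for the HKA scan, with known truth
#'
#' Neutral windows receive ingroup-polymorphic sites at rate `baseS` and
#' ingroup-fixed divergent sites at rate `baseD` (Poisson counts per
#' window); in sweep windows the polymorphism rate is divided by
#' `diversityReduction` while divergence is unchanged — the footprint of a
#' selective sweep, which prunes ingroup diversity without touching
#' divergence. Genotypes are emitted so that [windowCounts] recovers the
#' planted counts exactly: polymorphic sites carry one heterozygous
#' ingroup sample, divergent sites are ingroup-fixed reference with a
#' hom-alt outgroup.
#'
#' @param nWindows,nSweeps total and sweep window counts.
#' @param diversityReduction fold reduction of ingroup polymorphism in
#'   sweep windows (default 10).
#' @param windowSize window width in bp (default 50000).
#' @param nIngroup diploid ingroup samples (default 6).
#' @param baseS,baseD expected neutral per-window polymorphism and
#'   divergence counts (defaults 40 and 40).
#' @return list: `gt` (a [GenotypeTable] including the `outgroup` sample),
#'   `windows` (`GRanges`), `truth` (sweep window indices and parameters).
#' @export
simulateSweepPanel <- function(nWindows = 200L, nSweeps = 5L,
                               diversityReduction = 10, windowSize = 50000L,
                               nIngroup = 6L, baseS = 40, baseD = 40) {
  stopifnot(nSweeps <= nWindows, diversityReduction >= 1)
  sweepIdx <- sort(sample.int(nWindows, nSweeps))
  isSweep <- seq_len(nWindows) %in% sweepIdx
  rateS <- ifelse(isSweep, baseS / diversityReduction, baseS)
  nS <- stats::rpois(nWindows, rateS)
  nD <- stats::rpois(nWindows, baseD)
  rows <- list()
  for (w in seq_len(nWindows)) {
    tot <- nS[w] + nD[w]
    if (tot == 0) next
    posInWin <- sort(sample.int(windowSize - 1L, tot))
    pos <- (w - 1L) * windowSize + posInWin
    type <- sample(rep(c("S", "D"), c(nS[w], nD[w])))
    rows[[w]] <- data.frame(pos = pos, type = type)
  }
  sites <- do.call(rbind, rows)
  nSites <- nrow(sites)
  din <- matrix(0L, nSites, nIngroup)
  hetSample <- sample.int(nIngroup, nSites, replace = TRUE)
  isPoly <- sites$type == "S"
  din[cbind(which(isPoly), hetSample[isPoly])] <- 1L
  dout <- ifelse(isPoly, 0L, 2L)
  d <- cbind(din, dout)
  ids <- c(sprintf("in_%02d", seq_len(nIngroup)), "outgroup")
  ref <- sample(c("A", "C", "G", "T"), nSites, replace = TRUE)
  alt <- randomAlt(ref)
  gt <- makeGenotypeTable(d, chrom = rep("1", nSites), pos = sites$pos,
                          ref = ref, alt = alt, sampleIds = ids, ploidy = 2L)
  windows <- GRanges("1", IRanges(
    (seq_len(nWindows) - 1L) * windowSize + 1L,
    seq_len(nWindows) * windowSize))
  list(gt = gt, windows = windows,
       truth = list(sweepWindows = sweepIdx, nS = nS, nD = nD,
                    diversityReduction = diversityReduction,
                    windowSize = windowSize, baseS = baseS, baseD = baseD))
}
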