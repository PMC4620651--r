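#' Run the full synthetic end-to-end demonstration analysis
#'
#' Generates synthetic data with known truth and exercises every pipeline
#' stage in dependency order: (1) panel simulation, (2) allele
#' frequencies, (3) authenticity suite (contamination, sex, fragment
#' lengths, damage), (4) variant summary, (5) D statistic, (6) f3, (7) HKA
#' sweep scan and candidate fixation filter. Per-stage TSV/JSON outputs
#' and a JSON run manifest (seed, parameters, input checksums, outputs)
#' are written under `outDir`. Identical `seed` and parameters reproduce
#' identical outputs.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed governing all randomness.
#' @param nLoci panel size for the admixture stages.
#' @param f introgression fraction for the simulated panel.
#' @param nReads simulated ancient reads.
#' @param contamination injected contamination fraction.
#' @param nWindows,nSweeps sweep-scan design.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
runDemo <- function(outDir, seed = 1L, nLoci = 5000L, f = 0.1,
                    nReads = 20000L, contamination = 0.005,
                    nWindows = 100L, nSweeps = 3L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  stages <- list()
  outputs <- character()
  emit <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[name]] <<- p
    p
  }

  # 1. simulate panel
  sim <- simulatePanel(demographyParams(nLoci = nLoci, f = f,
                                        introgressInto = "P2"))
  writeGenotypeTsv(sim$gt, file.path(outDir, "panel_genotypes.tsv"))
  outputs[["panel_genotypes.tsv"]] <- file.path(outDir, "panel_genotypes.tsv")
  writePopulationMap(sim$popmap, file.path(outDir, "population_map.tsv"))
  outputs[["population_map.tsv"]] <- file.path(outDir, "population_map.tsv")
  stages$simulate <- list(nLoci = nLoci, f = f, introgressInto = "P2")

  # 2. frequencies
  ft <- alleleFrequencies(sim$gt)
  emit(data.frame(locus = names(loci(ft)), freqMatrix(ft),
                  check.names = FALSE), "allele_frequencies.tsv")
  stages$frequencies <- list(populations = populations(ft))

  # 3. authenticity
  panel <- makeDiagnosticPanel(
    chrom = rep("MT", 15), pos = seq(100, 1500, by = 100),
    endogenous = rep(c("A", "C", "G", "T", "A"), 3),
    contaminant = rep(c("G", "T", "A", "C", "C"), 3))
  ar <- simulateAncientReads(ancientReadParams(nReads = nReads,
                                               c = contamination), panel)
  cont <- estimateContamination(ar$reads, panel)
  contTv <- estimateContamination(ar$reads, panel, transversionsOnly = TRUE)
  fl <- summarizeFragmentLengths(ar$reads)
  dp <- damageProfile(ar$reads, k = 10)
  depths <- c(stats::setNames(stats::rnorm(5, 6.2, 0.1), as.character(1:5)),
              X = stats::rnorm(1, 3.1, 0.1))
  sx <- inferSex(depths)
  emit(data.frame(metric = c("contamination_pct", "contamination_tv_pct",
                             "median_fragment_bp", "x_autosome_ratio",
                             "sex_call"),
                  value = c(contaminationPct(cont), contaminationPct(contTv),
                            fl@medianBp, sx@ratio, sexCall(sx))),
       "authenticity.tsv")
  emit(dp@rates, "damage_profile.tsv")
  stages$authenticity <- list(contaminationPct = contaminationPct(cont),
                              sexCall = sexCall(sx),
                              medianFragment = fl@medianBp)

  # 4. variant summary on loci where the ancient sample differs from ref
  rr <- loci(sim$gt)
  aDos <- dosage(sim$gt)[, colData(sim$gt)$population == "A", drop = FALSE][, 1]
  varIdx <- which(!is.na(aDos) & aDos > 0)
  gtStr <- ifelse(aDos[varIdx] == ploidy(sim$gt)[colData(sim$gt)$population == "A"][1],
                  paste(mcols(rr)$alt[varIdx], mcols(rr)$alt[varIdx], sep = "/"),
                  paste(mcols(rr)$ref[varIdx], mcols(rr)$alt[varIdx], sep = "/"))
  vs <- tabulateVariants(data.frame(ref = mcols(rr)$ref[varIdx],
                                    alt = mcols(rr)$alt[varIdx],
                                    genotype = gtStr))
  emit(vs$cells, "variant_summary.tsv")
  stages$variants <- list(total = sum(vs$cells$count),
                          untabulated = vs$untabulated)

  # 5-6. admixture
  dres <- dStatistic(ft, "P1", "P2", "A", "O")
  f3res <- f3Statistic(ft, "P1", "A", "O", biasCorrection = FALSE)
  emit(data.frame(test = c("D(P1,P2;A,O)", "f3(P1;A,O)"),
                  estimate = c(dValue(dres), f3Value(f3res)),
                  se = c(dres@se, f3res@se), z = c(zScore(dres), f3res@z),
                  nSites = c(dres@nSitesUsed, f3res@nSitesUsed)),
       "admixture.tsv")
  stages$dstat <- list(d = dValue(dres), z = zScore(dres))
  stages$f3 <- list(f3 = f3Value(f3res), z = f3res@z)

  # 7. selection scan + candidates
  sw <- simulateSweepPanel(nWindows = nWindows, nSweeps = nSweeps)
  wc <- windowCounts(sw$gt, sprintf("in_%02d", 1:6), "outgroup", sw$windows)
  scan <- hkaScan(wc)
  emit(scan, "hka_scan.tsv")
  topIdx <- order(-scan$stat)[seq_len(nSweeps)]
  stages$hka <- list(plantedRecovered =
                       sum(sw$truth$sweepWindows %in% topIdx))
  cand <- fixationFilter(ft, "P1", "O",
                         dosage(sim$gt)[, colData(sim$gt)$population == "A", drop = FALSE][, 1],
                         ancientPloidy = 1L)
  stages$candidates <- list(nCandidates = length(cand$loci),
                            skippedMissing = cand$skippedMissing)

  manifest <- list(
    package = "ancientpop",
    version = as.character(utils::packageVersion("ancientpop")),
    seed = seed,
    parameters = list(nLoci = nLoci, f = f, nReads = nReads,
                      contamination = contamination, nWindows = nWindows,
                      nSweeps = nSweeps),
    stages = stages,
    outputs = as.list(stats::setNames(names(outputs), names(outputs))),
    checksums = as.list(tools::md5sum(unlist(outputs))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
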