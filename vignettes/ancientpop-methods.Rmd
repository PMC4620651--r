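---
title: "Methods and design of ancientpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of ancientpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancientpop)
```

# Scope and data model

`ancientpop` analyses a single ancient genome against modern population
panels: authenticity diagnostics, variant tabulation, frequency-based
admixture statistics, a windowed selection scan, and a cross-taxon
fixation filter, together with synthetic-data generators that provide
known ground truth for all of them. The central container is the
`GenotypeTable`, a `RangedSummarizedExperiment` whose single assay holds
alternate-allele dosages over biallelic loci (0/1/2 for diploid samples,
0/1 for pseudo-haploid ones, `NA` missing), with `ref`/`alt` alleles on
the row ranges and per-sample ploidy and population labels in `colData`.
All coordinates are 1-based inclusive internally; BED input is 0-based
half-open and converted on read.

A low-coverage ancient sample can enter either as diploid genotype calls
or pseudo-haploid (a single sampled allele per site, ploidy 1). Both modes
are supported throughout because genotype-calling rules for shallow
ancient data vary between studies; frequency computation simply counts a
pseudo-haploid call as one observed allele copy. Sites with a missing
frequency in any population required by a statistic are skipped for that
statistic and reported in a skipped-sites tally.

# Authenticity suite

**Contamination from diagnostic sites.** Given a panel of loci at which
the endogenous lineage and candidate contaminating lineages carry
different alleles, each read is classified by the alleles it shows. A read
is *informative* if it matches either allele class at one or more panel
loci, and *contaminant* if any overlapped locus shows a contaminant-class
allele; reads matching neither class anywhere (sequencing-error third
alleles) are discarded. A read spanning several loci counts once — the
unit of evidence is the DNA fragment, not the (read, locus) pair. The
estimate `100 × contaminant/informative` is an upper bound, since
sequencing error also produces apparent contaminant alleles. The
transversion-only mode restricts the panel to loci whose diagnostic pairs
are all transversions; deamination-driven C>T/G>A artefacts cannot mimic
those, at the price of far fewer informative reads. With several
contaminant alleles at a locus, the locus is classed a transversion only
when *every* endogenous/contaminant pair is a transversion — otherwise a
damaged base could still cross allele classes. An optional Jeffreys
binomial interval is available (off by default; point estimates are the
conventional report). X-chromosome contamination uses the same counting
contract per contaminating source and refuses to run unless the sample's
sex call is male, because the hemizygosity argument underpinning it fails
otherwise.

**Sex inference.** Males are hemizygous for X, so the ratio of X to
autosomal mean depth is near 0.5 for males and near 1 for females. The
call thresholds are ratio < 0.6 for male and > 0.8 for female, with an
ambiguous band between; the gap avoids brittle calls on noisy depth
estimates while being far wider than the depth noise of any genome-scale
data set.

**Fragment lengths and damage.** The fragment-length summary reports the
lower median (for even counts, the lower of the two central order
statistics — deterministic and always an observed length) and inclusive
in-range fractions, defaulting to the conventional 16–150 bp and
20–150 bp windows. The damage profile is the empirical terminal
misincorporation table: for each end and distance `d = 1..k` (default
k = 25), the rate of each ref→read substitution conditioned on the
reference base. Rates are reported `NA`, never 0, where the conditioning
base count is zero. No likelihood model or quality rescaling is fitted —
the empirical curves are the deliverable.

# Admixture statistics

The D statistic uses the symmetric (polarization-free) ABBA/BABA site
weights by default. This choice matters when the outgroup may itself be
polymorphic at ascertained sites (a distant outgroup species genotyped on
an array designed for the ingroup): strict polarization would discard or
mis-weight such sites. A strict outgroup-polarized mode
(`polarize = TRUE`) is provided, which skips sites where the outgroup
frequency is not 0 or 1. The ancient lineage enters as a population of
one sample; with pseudo-haploid calls its per-site frequency is 0/1, which
adds site-level noise but no bias, and the block jackknife absorbs it into
the standard error.

Significance comes from the delete-*m* weighted block jackknife (Busing et
al. 1999) over blocks of consecutive used SNPs, 50 per block by default —
the block length conventionally used with array-density data, applied
uniformly to both D and f3. With equal block weights the estimator reduces
exactly to the delete-one jackknife, which the test suite verifies to
1e-12 relative error. Blocks containing no ABBA/BABA weight are dropped
from the resampling (they change neither the estimate nor any leave-one-
out estimate); if fewer than two weighted blocks remain the SE is
reported `NA` rather than fabricated. |Z| ≥ 3 is the conventional
reporting flag.

The f3 test subtracts the finite-sample term `x(1−x)/(n_x−1)` by default,
and therefore requires at least two observed allele copies in the target;
the uncorrected statistic is available for frequency-level fixtures. f3 is
symmetric in its sources, and `populationMeanD` produces the per-P1
mean-D-over-panel table used for geographic contour summaries.

# Selection scan

Window counts classify each assessed site as ingroup-polymorphic (`S`) or,
if monomorphic in the ingroup, divergent (`Dv`) when the fixed ingroup
allele differs from the outgroup allele. Sites with no callable outgroup
allele (missing, or heterozygous in a diploid outgroup) are excluded from
the assessed total; an optional pseudo-haploid outgroup mode samples one
allele at heterozygous sites, suited to a single low-coverage outgroup
genome. Divergence is counted only at ingroup-monomorphic sites — the
conservative reading of "distance to an outgroup".

Expectations use leave-one-out genome totals: each window's expected
counts come from the totals *excluding that window*, so a strong sweep
window cannot drag the null toward itself. The effect is negligible
genome-wide and exact on small fixtures. The statistic is the 1-df
chi-square against those expectations, with a Fisher exact fallback when
an expectation is zero, and BH adjustment (`stats::p.adjust`) across
testable windows. Windows with no assessed sites are retained but flagged
untestable. When no adjusted q-value passes the threshold, raw p ≤ 0.05
windows should be reported as suggestive only. Window definitions come
from a BED file or fixed 50-kb tiling.

# Candidate fixation filter

"Near fixation for different alleles" is interpreted as *both* groups at
frequency ≥ 0.95 for opposite alleles — the phrase requires two-sided
fixation, not one group alone — and frequencies are allele-level (not
genotype-level), the natural scale for pooled shallow-coverage panels.
The ancient sample must be homozygous for group 2's major allele;
heterozygous or missing ancient calls exclude the locus (missing ones are
tallied). Region classification takes the most specific class
(UTR/exon > intron > 5-kb flank > intergenic), is strand-aware for
upstream/downstream labels (strandless models fall back to coordinate
order with a warning), and treats genes without annotated sub-features as
exonic over their whole body. Ties between overlapping genes report the
first gene in sorted order and set a tie flag. Codon-level consequence
prediction is out of scope.

# Variant summary

Genotype classes follow the convention for single-sample comparisons to a
reference: *heterozygous* means exactly one of the sample's alleles
differs from the reference, *homozygous* means both do; sites
heterozygous for two non-reference alleles fall outside the biallelic
scope and are counted as untabulated rather than silently dropped.
Quality filtering retains depth ≥ 5 (inclusive) and LOD > 2 (exclusive).
Weighted means are computed over unrounded cell percentages when raw
flags are available; when reconstructing a published table from printed
cells, the printed percentages are used as given. Note that published
tables sometimes truncate rather than round — a reconstructed fraction can
legitimately differ from print by up to one unit in the last digit.

# Synthetic data: what it emulates, and what it does not

The panel generator draws ancestral frequencies from Uniform(0.05, 0.95)
(emulating array ascertainment toward common variants) and evolves them
along the fixed tree `(((P1, P2), A), O)` with Balding–Nichols beta
transitions. Drift intensities default to F = 0.02 on each terminal test
branch, 0.05 on the shared branch, 0.25 on the ancient lineage and 0.5 on
the outgroup — closely related modern populations, a deeply diverged
pre-domestication wild lineage, and a species-level outgroup.
Introgression is a one-off frequency admixture
`p ← (1−f)·p + f·p_A` into one test population. Sample sizes default to
20 diploids per test population, one pseudo-haploid ancient sample and
two diploid outgroup samples. Beta-drift rather than coalescent
simulation is deliberate: it gives analytic control over the expected
sign and magnitude of D and f3 at desk scale. What it does *not* emulate:
linkage disequilibrium (loci are exchangeable, so the block jackknife is
exercised structurally but not against real autocorrelation), recurrent
migration, ascertainment interacting with drift, or genotyping error.
Passing calibration here shows the statistics are implemented correctly,
not that any particular real data set is clean.

The read generator emits one diagnostic-site call per read (contaminant
with probability c, sequencing error flips to a uniformly chosen other
base with probability e = 0.001), log-normal fragment lengths with median
50 bp (sdlog 0.35) truncated at 16 bp, and terminal mismatch tracks under
the exponential decay `d(i) = 0.3 · 0.5^(i−1)` applied to 5' C and 3' G
on endogenous reads only (modern contaminant DNA is undamaged by default).
Under the uniform-misread error model the null C>T rate is e/3, not e.
The sweep generator plants Poisson site counts per window (neutral rates
40 polymorphic + 40 divergent per 50-kb window; sweep windows divide the
polymorphism rate by the diversity-reduction factor) and emits genotypes
from which the window counts are recovered exactly.

All generators are deterministic under a fixed seed, and their outputs
round-trip through the package's own readers.

# Numerical and testing choices

Degenerate inputs are errors, not silent zeros: no informative D sites,
a single jackknife block (SE becomes `NA`), zero transversion loci in
transversion-only mode, zero autosomal depth, empty fragment-length
input. Test problem sizes were chosen to make the statistical assertions
sharp at desk scale: 500 replicates × 10,000 sites for the null
calibration of D (|Z| < 3 in ≥ 99 %, Z approximately standard normal),
100 replicates × 15,000 sites for introgression power at f = 0.1,
40 seeds × 10,000 sites for f3 recovery of a 50/50 admixed target,
100 seeds of 5 sweep windows among 200 for the HKA ranking study, and
100,000 reads for contamination parameter recovery within 3 binomial
standard deviations. The drift defaults above were fixed once so that
these calibration properties hold under the stated designs; they are the
package's study conditions and are not meant to be tuned per analysis.

# Known limitations

* The D/f3 machinery is frequency-based; genotype-likelihood input is not
  supported.
* The HKA scan implements the windowed chi-square contrast with
  leave-one-out expectations, not a multilocus maximum-likelihood HKA
  fit.
* Contamination estimates are upper bounds confounded with sequencing
  error at diagnostic sites; the transversion-only mode trades precision
  for robustness to damage, not to error.
* Region classification is interval-based only; it does not predict
  functional consequences.
* BAM/SAM extraction is out of scope: read-level evidence enters through
  the documented TSV schema.
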