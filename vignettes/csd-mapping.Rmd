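---
title: "Mapping complementary sex determination loci in clonal haplodiploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping complementary sex determination loci in clonal haplodiploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdmapr)
library(dplyr)
```

## The mapping problem

Haplodiploid insects cannot use sex chromosomes: males develop from haploid
eggs and females from diploid ones, so every allele must pass through both
sexes. Under *complementary sex determination* (CSD), the primary signal is
heterozygosity itself — a diploid heterozygous at a sex locus develops
female, while hemizygosity (haploids) or homozygosity (rare diploid males)
permits male development. In asexual ants that reproduce by central-fusion
automixis, diploid males are expected to arise when a rare crossover-
associated loss of heterozygosity (LOH) spans a CSD locus. This package
implements the resulting mapping strategy: within a clonal line, find the
genomic region at which every diploid female is heterozygous and as many
diploid males as possible are homozygous.

Standard association mapping does not work here — no particular allele is
associated with either sex; the *genotype class* (heterozygous versus
homozygous for either allele) is. The scan statistic is therefore the
**CSD index** of a SNP:

* 0 if any genotyped diploid female is homozygous;
* otherwise, the proportion of genotyped diploid males that are homozygous.

A perfect CSD locus has index 1; an index of 11/16 means 11 of 16 diploid
males are homozygous (for either allele) while all females are
heterozygous.

## Pipeline overview

`run_csd_pipeline()` chains the stages; each is exported on its own and
takes a data frame first, so stages compose with the pipe.

1. **Genotype QC** (`mask_low_depth()`, `filter_missingness()`,
   `filter_haploid_het_sites()`, `filter_allelic_depth()`,
   `restrict_to_biallelic_snps()`). Haploid males cannot be heterozygous,
   so any site with a heterozygous haploid call is a collapsed-repeat
   artifact and is removed genome-wide. Heterozygous diploid calls must
   show a proportionate minor allelic depth of at least 0.25 (computed
   over the two called alleles' depths), and homozygous calls must show
   zero reads for any non-called allele; a site failing either screen in
   any sample is removed. Calls supported by fewer than `min_call_dp = 8`
   reads are masked to missing first: a "homozygous" call drawn from six
   reads is indistinguishable from a heterozygote whose reads happened to
   sample one allele, and a single such call would zero the CSD index at
   that site.
2. **Ancestral heterozygosity** (`call_ancestral_het()`). All members of a
   clonal line descend from one diploid founder, so the informative sites
   are those plausibly heterozygous in that founder: at least one diploid
   heterozygous, and every other non-missing diploid either heterozygous
   for the same allele pair or homozygous for one of its alleles. Missing
   calls do not veto a site; at least two genotyped diploids are required.
3. **Scan** (`csd_scan()`). The CSD index per ancestrally heterozygous
   site, a permutation null, Benjamini–Hochberg q-values, windowed means
   (`windowed_mean()`, 50 kb windows, 15 kb step), and candidate intervals
   (`call_peak()`, `rank_candidates()`).
4. **LOH corroboration** (`loh_segments()`,
   `intersect_loh_across_males()`, `assign_allele()`,
   `depth_classify()`). Losses of heterozygosity are ancestrally
   heterozygous SNPs that became homozygous in a sample; maximal runs with
   at least `min_snps = 10` flagged SNPs and at most `max_err = 1`
   interrupting heterozygous site are segmented, intersected across
   diploid males under the constraint that all females stay heterozygous,
   and classified copy-neutral versus deletion from read depth normalized
   by each sample's genome-wide median.
5. **Diversity** (`windowed_pi()`, `haplotype_diff_windows()`,
   `peak_overlap_report()`). CSD loci are expected to evolve under
   balancing selection, so pooling diploid genotypes across clonal lines
   should reveal a nucleotide-diversity peak at the locus (5 kb windows,
   1 kb step; per-window haplotype differences in 100 bp windows).

## The permutation null

Colonies are clonal families: their members share the mother's LOH tracts,
so sites are correlated within colonies and a naive permutation of sex
labels across the whole cohort would be anti-conservative. The null is
therefore colony-stratified: in each permutation the sex labels of diploid
individuals are shuffled *within* their colony (per-colony sex counts
preserved), once per permutation and shared across all sites so that
between-site correlation of the null is retained. The per-site p-value is
the plain proportion of permutations with an index at least as large as
the observed one; `add_one = TRUE` switches to the (k+1)/(B+1) estimator
for users who require p-values bounded away from zero. With the plain
estimator a site can attain p = 0 at finite `n_perm`; this is the
estimator as published, so it is the default. `n_perm` defaults to 1,000;
the permutation count in the original analysis is unstated, which also
means the published FDR-corrected significance line (p = 0.002) cannot be
regenerated exactly — the BH-derived cutoff is recomputed from the data at
hand (`bh_p_cutoff()`).

`permutation_null(method = "exhaustive")` enumerates every distinct
within-colony label assignment; it is intended for small cohorts and as an
exactness check on the sampler.

## Candidate calling and ranking

Windows of mean p below the nominal 0.05 threshold are merged into
candidate runs; empty windows (no informative sites) neither extend nor
break a run. Two deliberate choices differ from the most literal reading
of a genome scan figure and deserve explanation:

* **Run formation uses the nominal threshold, not the BH cutoff.** At
  desk-scale permutation resolution the smallest attainable p is
  1/`n_perm`, so the BH cutoff lands near it; a 50 kb window holding a few
  dozen sites can then never pass once a single site is non-significant.
  The per-site q-values and the BH-derived p cutoff are still computed and
  reported — they answer "is the peak significant after FDR control",
  while run formation answers "where is the peak".
* **Runs are merged across pinholes and ranked by their index peak.** A
  single spurious homozygous call in one female zeroes the index at one
  site and lifts every window containing it above threshold, splitting
  one peak into two; candidates on the same chromosome separated by less
  than `merge_gap_bp` (100 kb, about the reach of the windows one site
  poisons) are therefore merged first — the window-level analogue of the
  `max_err` tolerance in LOH segmentation. Under central fusion every
  male LOH tract runs from its crossover breakpoint to the chromosome
  end, so the region distal to the last male breakpoint — which contains
  the CSD locus — is uniformly significant, and permutation p-values
  saturate at 0 along it. Among tied runs the biological discriminator is
  the CSD index itself: candidates are ordered by their maximum
  *windowed* mean index (windows with fewer than five informative sites
  are ignored — a near-empty window's mean is one site's noise), then by
  run support. This mirrors reading the index track and the significance
  track of a genome-scan figure together.

## The synthetic cohort generator

`simulate_cohort()` produces cohorts with the statistical structure the
analysis assumes, so that the whole pipeline is exercisable and testable
without any external data:

* a founder genome per clonal line with line-specific ancestral
  heterozygosity in ~100 kb blocks (fraction 0.6), over a shared SNP panel
  (2 SNPs/kb on a 1 Mb + 4 Mb genome);
* central-fusion automixis: Poisson crossovers (1.5 per chromosome per
  meiosis, uniform placement), reciprocal-chromatid co-inheritance with
  fidelity 0.85, and LOH tracts running from a failed crossover to the
  higher-coordinate chromosome end, homozygous for either maternal
  haplotype with equal probability;
* a planted CSD locus (46 kb on the 4 Mb chromosome, forced heterozygous
  in every founder — a homozygous founder would leave no female
  descendants), sex assigned from the true genotype; a haploid-male rate
  of 0.05 and a stochastic (non-genetic) diploid-male rate of 0.05;
* negative-binomial read depth (mean 25, size 20), per-read miscall
  probability 0.001, and collapsed-repeat regions in which haploids emit
  spurious heterozygous calls.

The geometry deliberately mirrors the *proportions* of the real study —
a locus of tens of kb on a chromosome two orders of magnitude longer —
rather than its absolute size. On a short chromosome with a
proportionally huge locus, crossover breakpoints crowd against the locus
and female LOH tracts routinely truncate it, artifacts the real design
does not exhibit. The per-meiosis LOH and male rates are scaled up from
realistic values so that a cohort of ~60 offspring contains a usable
number of diploid males; they are chosen to keep diploid males on the
order seen in colony surveys (a fifth to a half of males) without being
calibrated to any published count.

What the generator does *not* emulate: multi-generation mutation
accumulation, genetic maps (crossovers are uniform), gene conversion
(all LOH is crossover-associated and telomere-directed), segmental
deletions (all simulated LOH is copy-neutral), and read-level artifacts
beyond symmetric miscalls. Passing tests on simulated cohorts therefore
demonstrate the statistical machinery, not robustness to every real-data
pathology.

## Numerical choices and degenerate inputs

* Coordinates: VCF 1-based positions internally; all emitted intervals
  0-based half-open (BED-compatible). Segment intervals span the first to
  last homozygous SNP — no LOH is claimed beyond observed markers.
* LOH segmentation is a transparent run-length rule (`min_snps`,
  `max_err`) rather than a hidden Markov model; parameters are exposed and
  boundaries are reproducible. Called segment boundaries may differ at the
  SNP level from an HMM's output.
* The male-segment intersection resolves support over the elementary
  intervals defined by segment endpoints, excludes subregions containing a
  female-homozygous site, and breaks ties leftmost.
* Allele identity within a candidate interval is assigned against an
  explicit reference haploid (the first haploid of the mapping line unless
  overridden): homozygous calls matching it are `allele1`, others
  `allele2`; a sample needs 90% agreement across its homozygous sites for
  a one-allele class, is `heterozygous` with no homozygous site, and
  `mixed` otherwise.
* Windowed diversity divides by window width in bp; windows with no
  segregating sites report 0 rather than missing. Haplotype-difference
  windows skip `N` and gap-gap columns and count gap-vs-base as a
  difference by default (`gap = "skip"` to ignore indels).
* Depth classes use a copy-neutral band of 0.8–1.2 and a deletion band of
  0.3–0.7 on median-normalized depth; fewer than five depth observations
  give `ambiguous`.
* Degenerate inputs fail loudly and early: empty VCFs, lines without
  diploids, loci containing no SNPs, missing colony labels, and a missing
  AD field each raise a specific error rather than propagating silently.

## Reported worked values

The package's tests and `scripts/acceptance.R` recompute, from scratch,
the quantities a user should expect: the fixture locus yields 19
heterozygous diploid females and a 5/2/9 split of diploid males
(heterozygous / homozygous for the reference-haploid allele / homozygous
for the alternate), a CSD index of 11/16 = 0.6875; the per-site mean
pairwise difference for allele counts (2, 2) is 2/3; and the 2×2 male
ploidy-by-line table (22, 92; 0, 78) gives a Pearson chi-square of 17.0
(15.2 with Yates correction, df = 1) — the published value of 15.4 for
these counts matches neither standard formula, so `cohort_contingency()`
reports both alongside the Fisher exact p rather than reproducing the
printed statistic.

Problem sizes in tests are chosen for a laptop-class machine: simulated
genomes of a few Mb, cohorts of ~60 offspring, 200–1,000 permutations,
and 25–50 replicate cohorts for the recovery and calibration suites.

## Known limitations

* Permutation resolution is bounded by `n_perm`; genome-wide FDR control
  at the published stringency requires far more permutations than the
  defaults.
* The ancestral-heterozygosity rule can admit sites where all carriers of
  one allele are missing by chance, and loses power when a line contains
  very few sequenced diploids.
* With tracts running breakpoint-to-telomere, everything distal of the
  locus up to the first female breakpoint is statistically equivalent to
  the locus; the reported candidate interval is therefore an upper bound
  on the locus, exactly as in the underlying mapping logic, and shrinks
  as more recombinant individuals are added.
* `filter_allelic_depth()` applies across all loaded samples; per-line
  application can be obtained by subsetting first.
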