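# csdmapr

Homozygosity mapping of complementary sex determination (CSD) loci in
clonal, haplodiploid insects.

## The problem

In haplodiploids, males are haploid and females diploid, which rules out
sex chromosomes. Under **complementary sex determination**, heterozygosity
at a sex locus triggers female development; hemizygosity (haploids) or
homozygosity (rare diploid males) permits male development. In ants that
reproduce asexually by **central-fusion automixis**, heterozygosity is
inherited almost intact, but a crossover whose reciprocal products are not
co-inherited leaves a copy-neutral **loss of heterozygosity (LOH)** tract
from the breakpoint to the chromosome end. Diploid males are then expected
to be individuals whose LOH tract spans the CSD locus.

`csdmapr` maps such loci from multi-sample genotype data (VCF + sample
metadata). Because no single allele is associated with sex, association
tests on alleles fail; the package instead scans the **CSD index** of each
ancestrally heterozygous SNP:

```
index(s) = 0                                  if any diploid female is homozygous at s
         = (# homozygous diploid males) / (# genotyped diploid males)   otherwise
```

Significance comes from a colony-stratified permutation null (sex labels
shuffled within colonies, preserving clonal family structure), with
Benjamini–Hochberg FDR control, windowed summaries (50 kb / 15 kb), and
candidate-locus calling. The scan is corroborated by rule-based LOH
segmentation, the intersection of male LOH segments restricted to sites at
which all females are heterozygous, copy-number classification from
median-normalized read depth, and windowed nucleotide diversity
(5 kb / 1 kb) across clonal lines — CSD loci evolve under balancing
selection and should sit under a diversity peak.

A forward simulator of central-fusion automixis with a planted CSD locus
(`simulate_cohort()`) generates complete cohorts — VCF, metadata, and
machine-readable truth — so the entire pipeline is testable without any
external data.

## Worked example

Simulate a cohort under the default study-style conditions (one clonal
line, four colonies, a 46 kb CSD locus planted at chr2:3,000,000–3,046,000)
and run the whole pipeline:

```r
library(csdmapr)
report <- run_csd_pipeline(sim_config = cohort_config(), seed = 11,
                           n_perm = 400)
report
```

```
CSD mapping report (line A)
  ancestrally het sites: 1994 
  candidate loci: 1 
  top: chr2:810000-3305000 (mean p 0)
  locus genotype classes:
    sex        class  n
 female      allele1  1
 female      allele2  2
 female heterozygous 45
   male      allele1  3
   male      allele2  1
   male heterozygous  4
   male        mixed  3
```

The top candidate interval contains the planted locus
(chr2:3,000,000–3,046,000). Its width is an honest upper bound: under
central fusion every male LOH tract runs from its breakpoint to the
chromosome end, so the whole region between the last male breakpoint and
the first female breakpoint is genotypically equivalent to the locus, and
the interval tightens as recombinant individuals accumulate. The class
table is computed over that broad interval against a reference haploid
male: most diploid females are heterozygous throughout, while the
heterozygous diploid males are the simulator's non-genetic diploid males
(5% of locus-heterozygous diploids develop male regardless of genotype),
and the handful of homozygous or mixed classifications reflect
individuals whose own LOH tracts enter the flanks of the broad interval.
With `stochastic_male_rate = 0` in `csd_model()` every diploid male's
tract covers the planted locus and the class table collapses to the
textbook pattern (all females heterozygous, all males homozygous for one
allele or the other).

Per-site and windowed results are ordinary tibbles:

```r
tidy(report$scan)          # chrom, pos, index, p, q per SNP
glance(report$scan)        # scan summary
report$candidates          # ranked candidate loci
report$segments            # per-male LOH segments with depth classes
autoplot(report$scan, fdr_threshold = report$fdr_cutoff,
         highlight = report$candidates)
```

A thin command-line wrapper covers the same stages
(`exec/csdscan`; subcommands `simulate`, `filter`, `anchet`, `scan`,
`loh`, `pi`, `all`, `figures`):

```sh
Rscript exec/csdscan all --simulate --seed 11 --out results/
```

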