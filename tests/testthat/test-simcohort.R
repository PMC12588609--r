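test_that("founder simulation honours boundary fractions and determinism", {
  f1 <- simulate_founder(c(chr1 = 1e5), 1e-3, 1, seed = 3)
  expect_true(all(f1$sites$anc_het))
  expect_true(all(f1$h1 != f1$h2))

  f0 <- simulate_founder(c(chr1 = 1e5), 1e-3, 0, seed = 3)
  expect_false(any(f0$sites$anc_het))
  expect_true(all(f0$h1 == f0$h2))

  fa <- simulate_founder(c(chr1 = 1e6), 1e-3, 0.5, seed = 11)
  fb <- simulate_founder(c(chr1 = 1e6), 1e-3, 0.5, seed = 11)
  expect_identical(fa$sites, fb$sites)
  expect_true(all(diff(fa$sites$pos) > 0))

  expect_error(simulate_founder(numeric(), 1e-3, 0.5, seed = 1), "chrom")
  expect_error(simulate_founder(c(chr1 = 0), 1e-3, 0.5, seed = 1), "chrom")
})

test_that("a scan on a line with no ancestral heterozygosity reports no informative sites", {
  cfg <- small_sim_config(anc_het_fraction = 0)
  cfg$csd <- csd_model(tibble::tibble(chrom = "chrB", start = 6e5, end = 6.5e5),
                       "single", 0)
  # force_het is not applied here: build the founder directly without the locus
  f <- simulate_founder(cfg$chrom_lengths, cfg$snp_density, 0, seed = 5)
  ind <- list(h1 = f$h1, h2 = f$h2, ploidy = 2L)
  g <- emit_genotype_calls(list(s1 = ind, s2 = ind), f,
                           read_model(base_error = 0), seed = 5)
  meta <- make_meta(c("s1", "s2"), c("female", "male"), c(2, 2))
  mask <- call_ancestral_het(g, meta, "A")
  expect_equal(sum(mask$anc_het), 0)
  expect_error(csd_scan(g, meta, mask = mask), "no informative sites")
})

test_that("central fusion without heterozygosity loss restores the maternal genotype", {
  f <- simulate_founder(c(chr1 = 2e5), 1e-3, 0.7, seed = 21)
  mother <- list(h1 = f$h1, h2 = f$h2, ploidy = 2L)

  off0 <- reproduce_central_fusion(mother, f, meiosis_params(
    crossover_rate = 0, coinheritance_fidelity = 0, haploid_male_rate = 0),
    seed = 2)
  expect_equal(off0$individual$h1, mother$h1)
  expect_equal(off0$individual$h2, mother$h2)
  expect_equal(nrow(off0$tracts), 0)

  off1 <- reproduce_central_fusion(mother, f, meiosis_params(
    crossover_rate = 5, coinheritance_fidelity = 1, haploid_male_rate = 0),
    seed = 2)
  expect_equal(nrow(off1$tracts), 0)
  het <- f$sites$anc_het
  expect_true(all((off1$individual$h1 != off1$individual$h2)[het]))

  expect_error(
    reproduce_central_fusion(list(h1 = f$h1, h2 = NULL, ploidy = 1L), f,
                             meiosis_params(), seed = 1),
    "diploid")
})

test_that("a single unfaithful crossover yields one tract to the chromosome end", {
  # enumeration of the single-crossover tetrad: fusing the recombinant with
  # either non-recombinant chromatid leaves heterozygosity proximal to the
  # breakpoint and fixes one maternal haplotype distal to it
  f <- simulate_founder(c(chr1 = 1e5), 2e-3, 1, seed = 8)
  mother <- list(h1 = f$h1, h2 = f$h2, ploidy = 2L)
  x <- 40000L
  for (s in 1:20) {
    off <- reproduce_central_fusion(mother, f, meiosis_params(
      crossover_rate = 1, coinheritance_fidelity = 0, haploid_male_rate = 0),
      seed = s, forced_breakpoints = list(chr1 = x))
    expect_equal(nrow(off$tracts), 1)
    expect_equal(off$tracts$start, x)
    expect_equal(off$tracts$end, 1e5)
    distal <- f$sites$pos > x
    src <- if (off$tracts$maternal_hap == 1) mother$h1 else mother$h2
    expect_equal(off$individual$h1[distal], src[distal])
    expect_equal(off$individual$h2[distal], src[distal])
    # proximal heterozygosity untouched
    expect_true(all((off$individual$h1 != off$individual$h2)[!distal]))
  }
})

test_that("LOH tracts fix either maternal haplotype with equal probability", {
  f <- simulate_founder(c(chr1 = 1e5), 1e-3, 1, seed = 30)
  mother <- list(h1 = f$h1, h2 = f$h2, ploidy = 2L)
  mp <- meiosis_params(crossover_rate = 2, coinheritance_fidelity = 0,
                       haploid_male_rate = 0)
  haps <- integer()
  s <- 0
  while (length(haps) < 250) {
    s <- s + 1
    off <- reproduce_central_fusion(mother, f, mp, seed = s)
    haps <- c(haps, off$tracts$maternal_hap)
  }
  bt <- stats::binom.test(sum(haps == 1), length(haps), 0.5)
  expect_gt(bt$p.value, 1e-4)
})

test_that("sex assignment follows the CSD rules", {
  f <- simulate_founder(c(chr1 = 1e5, chr2 = 1e5), 1e-3, 1, seed = 4)
  model1 <- csd_model(tibble::tibble(chrom = "chr1", start = 2e4, end = 5e4),
                      "single", 0)
  hap <- list(h1 = f$h1, ploidy = 1L)
  expect_equal(assign_sex(hap, f, model1), "male")

  dip_het <- list(h1 = f$h1, h2 = f$h2, ploidy = 2L)
  expect_equal(assign_sex(dip_het, f, model1), "female")

  dip_hom <- list(h1 = f$h1, h2 = f$h1, ploidy = 2L)
  expect_equal(assign_sex(dip_hom, f, model1), "male")

  # multi-locus rule: heterozygosity at any one locus suffices
  model2 <- csd_model(tibble::tibble(chrom = c("chr1", "chr2"),
                                     start = c(2e4, 2e4), end = c(5e4, 5e4)),
                      "multi", 0)
  in_a <- f$sites$chrom == "chr1" & f$sites$pos > 2e4 & f$sites$pos <= 5e4
  mixed <- list(h1 = f$h1, h2 = ifelse(in_a, f$h1, f$h2), ploidy = 2L)
  expect_equal(assign_sex(mixed, f, model2), "female")
  expect_equal(assign_sex(dip_hom, f, model2), "male")

  bad <- csd_model(tibble::tibble(chrom = "chr1", start = 0, end = 5),
                   "single", 0)
  expect_error(assign_sex(dip_het, f, bad), "no SNPs")
})

test_that("noiseless read emission reproduces true genotypes", {
  f <- simulate_founder(c(chr1 = 1e5), 1e-3, 0.6, seed = 12)
  dip <- list(h1 = f$h1, h2 = f$h2, ploidy = 2L)
  hap <- list(h1 = f$h2, ploidy = 1L)
  g <- emit_genotype_calls(list(d = dip, h = hap), f,
                           read_model(mean_depth = 60, base_error = 0),
                           seed = 7)
  gd <- g[g$sample_id == "d" & g$dp >= 2, ]
  truth_het <- f$sites$anc_het[match(gd$pos, f$sites$pos)]
  called_het <- gd$a1 != gd$a2
  expect_equal(called_het, truth_het)
  hom <- !truth_het
  expect_equal(gd$a1[hom], f$h1[match(gd$pos[hom], f$sites$pos)])
})

test_that("haploids inside collapsed regions emit heterozygous calls", {
  f <- simulate_founder(c(chr1 = 5e4), 2e-3, 0, seed = 13)
  hap <- list(h1 = f$h1, ploidy = 1L)
  rm_ <- read_model(mean_depth = 50, base_error = 0,
                    collapsed_regions = tibble::tibble(chrom = "chr1",
                                                       start = 0, end = 2e4))
  g <- emit_genotype_calls(list(h = hap), f, rm_, seed = 3)
  inside <- g$pos <= 2e4 & g$dp >= 2
  outside <- g$pos > 2e4 & g$dp >= 1
  expect_true(all((!is.na(g$a2) & g$a1 != g$a2)[inside]))
  expect_true(all(is.na(g$a2[outside])))
})

test_that("zero depth yields only missing calls", {
  f <- simulate_founder(c(chr1 = 5e4), 1e-3, 0.5, seed = 14)
  g <- emit_genotype_calls(list(d = list(h1 = f$h1, h2 = f$h2, ploidy = 2L)),
                           f, read_model(mean_depth = 0), seed = 1)
  expect_true(all(is.na(g$a1)))
  expect_true(all(g$dp == 0))
})

test_that("cohort simulation is reproducible and writes a byte-identical VCF", {
  cfg <- small_sim_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_cohort(cfg, seed = 5, out_dir = d1)
  s2 <- simulate_cohort(cfg, seed = 5, out_dir = d2)
  expect_identical(readLines(s1$paths$vcf), readLines(s2$paths$vcf))
  expect_identical(s1$meta, s2$meta)
  expect_identical(s1$truth$loh_tracts, s2$truth$loh_tracts)
  expect_true(all(file.exists(unlist(s1$paths))))
})

test_that("every diploid male's truth covers the planted locus when sex is genetic", {
  sim <- cached_small_sim()
  locus <- sim$truth$planted_loci[1, ]
  dip_males <- sim$meta$sample_id[sim$meta$sex == "male" & sim$meta$ploidy == 2L]
  expect_gt(length(dip_males), 0)
  for (s in dip_males) {
    tr <- sim$truth$loh_tracts[sim$truth$loh_tracts$sample_id == s &
                                 sim$truth$loh_tracts$chrom == locus$chrom, ]
    covers <- any(tr$start <= locus$start & tr$end >= locus$end)
    expect_true(covers, info = s)
  }
  # and no female tract covers it
  fems <- sim$meta$sample_id[sim$meta$sex == "female"]
  for (s in fems) {
    tr <- sim$truth$loh_tracts[sim$truth$loh_tracts$sample_id == s &
                                 sim$truth$loh_tracts$chrom == locus$chrom, ]
    expect_false(any(tr$start <= locus$start & tr$end >= locus$end), info = s)
  }
})

test_that("truth tracts are disjoint within a chromosome and bounded by chromosome ends", {
  sim <- cached_small_sim()
  cfg <- small_sim_config()
  tr <- sim$truth$loh_tracts
  expect_true(all(tr$end <= cfg$chrom_lengths[tr$chrom]))
  expect_true(all(tr$start >= 0))
  by_sc <- split(tr, paste(tr$sample_id, tr$chrom))
  for (g in by_sc) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
})
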