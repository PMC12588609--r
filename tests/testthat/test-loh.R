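loh_setup <- function() {
  meta <- make_meta(c("d1", "d2", "h1"), c("female", "male", "male"),
                    c(2, 2, 1))
  mask <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L),
                         anc_het = TRUE, a_lo = 0L, a_hi = 1L)
  g <- make_geno(tibble::tibble(
    chrom = "chr1", pos = rep(c(10L, 20L, 30L), each = 2),
    sample_id = rep(c("d2", "h1"), 3),
    # d2: hom ancestral / het / hom third allele
    a1 = c(0L, 0L, 0L, 0L, 2L, 0L),
    a2 = c(0L, NA, 1L, NA, 2L, NA)))
  g$alt <- "T,G"
  list(meta = meta, mask = mask, geno = g)
}

test_that("the LOH mask flags ancestral-allele homozygosity only", {
  s <- loh_setup()
  m <- loh_mask(s$geno, s$meta, s$mask, "d2")
  expect_equal(m$loh, c(TRUE, FALSE, FALSE))
  expect_equal(m$artifact, c(FALSE, FALSE, TRUE))
  expect_error(loh_mask(s$geno, s$meta, s$mask, "h1"), "haploid")
})

test_that("run segmentation honours min_snps, max_err and the interval convention", {
  mk <- function(flags, pos = seq_along(flags) * 10L) {
    tibble::tibble(chrom = "chr1", pos = pos, loh = flags)
  }
  expect_equal(nrow(segment_runs(mk(rep(FALSE, 20)))), 0)

  seg <- segment_runs(mk(rep(TRUE, 10)), min_snps = 5, max_err = 0)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_snps, 10)
  expect_equal(seg$start, 9)   # first SNP at pos 10, 0-based
  expect_equal(seg$end, 100)   # half-open at the last SNP

  pat <- c(rep(TRUE, 6), FALSE, rep(TRUE, 6))
  merged <- segment_runs(mk(pat), min_snps = 5, max_err = 1)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_snps, 12)
  split_ <- segment_runs(mk(pat), min_snps = 5, max_err = 0)
  expect_equal(nrow(split_), 2)
  expect_equal(split_$n_snps, c(6, 6))

  # missing sites neither break nor extend
  flags <- c(rep(TRUE, 4), NA, rep(TRUE, 4))
  seg <- segment_runs(mk(flags), min_snps = 8, max_err = 0)
  expect_equal(seg$n_snps, 8)
})

test_that("the male-intersection matches interval examples and the SNP oracle", {
  segs <- tibble::tibble(sample_id = c("m1", "m2"), chrom = "chr1",
                         start = c(100, 300), end = c(500, 900))
  r <- intersect_loh_across_males(segs)
  expect_equal(r$start, 300)
  expect_equal(r$end, 500)
  expect_equal(r$support, 2)
  expect_equal(r$males[[1]], c("m1", "m2"))

  # disjoint segments: max support 1, leftmost region returned
  segs2 <- tibble::tibble(sample_id = c("m1", "m2"), chrom = "chr1",
                          start = c(100, 700), end = c(300, 900))
  r2 <- intersect_loh_across_males(segs2)
  expect_equal(r2$support, 1)
  expect_equal(r2$start, 100)

  # female-homozygous site inside the overlap splits/excludes it
  r3 <- intersect_loh_across_males(
    segs, female_hom_sites = tibble::tibble(chrom = "chr1", pos = 400L))
  expect_equal(r3$support, 2)
  expect_true(r3$end <= 399 || r3$start >= 400)

  # randomized instances against the per-SNP counting oracle; SNPs at every
  # bp so that interval support and SNP support coincide
  set.seed(21)
  for (i in 1:25) {
    n_m <- sample(2:5, 1)
    segs <- purrr::map_dfr(seq_len(n_m), function(m) {
      st <- sample.int(150, 1)
      tibble::tibble(sample_id = paste0("m", m), chrom = "chr1",
                     start = st, end = min(st + sample(20:120, 1), 200))
    })
    snp_pos <- 1:200
    fh <- sort(sample(snp_pos, 3))
    got <- tryCatch(
      intersect_loh_across_males(
        segs, female_hom_sites = tibble::tibble(chrom = "chr1", pos = fh)),
      error = function(e) NULL)
    want <- oracle_max_support_run(segs, snp_pos, fh)
    if (is.null(want)) {
      expect_null(got)
      next
    }
    expect_equal(got$support, want$support)
    expect_true(all(want$pos > got$start & want$pos <= got$end))
  }
})

test_that("allele assignment against the reference haploid classifies samples", {
  ids <- c("ref_h", "s_match", "s_opp", "s_het", "s_mix")
  meta <- make_meta(ids, c("male", "male", "male", "female", "male"),
                    c(1, 2, 2, 2, 2))
  pos <- seq(10L, 100L, 10L)
  g <- purrr::map_dfr(ids, function(s) {
    a <- switch(s,
      ref_h = list(a1 = rep(0L, 10), a2 = rep(NA_integer_, 10)),
      s_match = list(a1 = rep(0L, 10), a2 = rep(0L, 10)),
      s_opp = list(a1 = rep(1L, 10), a2 = rep(1L, 10)),
      s_het = list(a1 = rep(0L, 10), a2 = rep(1L, 10)),
      s_mix = list(a1 = c(rep(0L, 6), rep(1L, 4)), a2 = c(rep(0L, 6), rep(1L, 4))))
    make_geno(tibble::tibble(chrom = "chr1", pos = pos, sample_id = s,
                             a1 = a$a1, a2 = a$a2))
  })
  iv <- list(chrom = "chr1", start = 0, end = 200)
  expect_equal(assign_allele(g, iv, "s_match", "ref_h"), "allele1")
  expect_equal(assign_allele(g, iv, "s_opp", "ref_h"), "allele2")
  expect_equal(assign_allele(g, iv, "s_het", "ref_h"), "heterozygous")
  expect_equal(assign_allele(g, iv, "s_mix", "ref_h"), "mixed")
  expect_error(assign_allele(g, list(chrom = "chr2", start = 0, end = 10),
                             "s_het", "ref_h"), "reference haploid")
})

test_that("depth classification separates copy-neutral LOH from deletions", {
  pos <- seq(10L, 500L, 10L)
  dt <- tibble::tibble(chrom = "chr1", pos = pos, sample_id = "m1",
                       depth = 30, norm_depth = 1.02)
  seg <- tibble::tibble(sample_id = "m1", chrom = "chr1", start = 0, end = 500)
  expect_equal(depth_classify(dt, seg)$depth_class, "copy_neutral")
  dt$norm_depth <- 0.49
  expect_equal(depth_classify(dt, seg)$depth_class, "deletion")
  dt$norm_depth <- 0.75
  expect_equal(depth_classify(dt, seg)$depth_class, "ambiguous")
  expect_equal(depth_classify(dt[1:3, ], seg)$depth_class, "ambiguous")
})

test_that("depth normalization divides by each sample's genome-wide median", {
  sim <- cached_small_sim()
  dt <- depth_track(sim$geno)
  med <- tapply(dt$depth, dt$sample_id, median)
  expect_equal(dt$norm_depth, dt$depth / as.numeric(med[dt$sample_id]))
})

test_that("ordinal coordinates rank flagged SNPs bijectively per chromosome", {
  mask <- tibble::tibble(chrom = rep(c("chr1", "chr2"), c(25, 10)),
                         pos = c(sort(sample.int(5000, 25)),
                                 sort(sample.int(5000, 10))),
                         anc_het = TRUE)
  o <- ordinalize_sites(mask)
  expect_equal(o$ord[o$chrom == "chr1"], 1:25)
  expect_equal(o$ord[o$chrom == "chr2"], 1:10)

  p <- o$pos[o$chrom == "chr1"]
  seg <- tibble::tibble(chrom = "chr1", start = p[10] - 1, end = p[20])
  os <- ordinalize_segments(seg, mask)
  expect_equal(os$ord_start, 10L)
  expect_equal(os$ord_end, 21L)

  empty <- mask[0, ]
  expect_equal(nrow(ordinalize_sites(empty)), 0)
})

test_that("noiseless segmentation recovers true tracts exactly in SNP space", {
  # one generation bred directly from a fully heterozygous founder, so every
  # called segment corresponds to a tract from the sampled meiosis itself
  f <- simulate_founder(c(chr1 = 5e5), 1e-3, 1, seed = 31)
  mp <- meiosis_params(crossover_rate = 2, coinheritance_fidelity = 0.5,
                       haploid_male_rate = 0)
  mother <- list(h1 = f$h1, h2 = f$h2, ploidy = 2L)
  offs <- lapply(1:12, function(i) reproduce_central_fusion(mother, f, mp, seed = 100 + i))
  inds <- setNames(lapply(offs, `[[`, "individual"), sprintf("o%02d", 1:12))
  geno <- emit_genotype_calls(inds, f, read_model(mean_depth = 40, base_error = 0),
                              seed = 3)
  meta <- make_meta(names(inds), "female", 2, colony = "c1")
  mask <- call_ancestral_het(geno, meta, "A")
  segs <- loh_segments(geno, meta, mask, min_snps = 10, max_err = 0)
  anc <- mask[mask$anc_het, ]
  merge_adjacent <- function(tr) {
    # adjacent tracts fixing different haplotypes are one homozygous region
    tr <- tr[order(tr$chrom, tr$start), ]
    out <- tr[0, c("chrom", "start", "end")]
    for (j in seq_len(nrow(tr))) {
      k <- nrow(out)
      if (k > 0 && out$chrom[k] == tr$chrom[j] && out$end[k] >= tr$start[j]) {
        out$end[k] <- max(out$end[k], tr$end[j])
      } else {
        out <- dplyr::bind_rows(out, tr[j, c("chrom", "start", "end")])
      }
    }
    out
  }
  checked <- 0
  for (i in seq_along(offs)) {
    tr_all <- merge_adjacent(offs[[i]]$tracts)
    sid <- names(inds)[i]
    for (j in seq_len(nrow(tr_all))) {
      tr <- tr_all[j, ]
      true_sites <- anc$pos[anc$chrom == tr$chrom & anc$pos > tr$start &
                              anc$pos <= tr$end]
      if (length(true_sites) < 10) next
      ss <- segs[segs$sample_id == sid & segs$chrom == tr$chrom, ]
      jac <- vapply(seq_len(nrow(ss)), function(k) {
        called <- anc$pos[anc$chrom == tr$chrom & anc$pos > ss$start[k] &
                            anc$pos <= ss$end[k]]
        length(intersect(true_sites, called)) /
          length(union(true_sites, called))
      }, 0)
      expect_gte(max(c(jac, 0)), 0.99)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 3)
})
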