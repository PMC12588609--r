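#' Per-site loss-of-heterozygosity mask for one sample
#'
#' Losses of heterozygosity are ancestrally heterozygous SNPs that have
#' become homozygous in a given sample. A site is flagged `TRUE` where the
#' sample's non-missing diploid call is homozygous for one of the two
#' ancestral alleles, `FALSE` where heterozygous, `NA` where missing.
#' Homozygosity for a third allele does not count as LOH and is flagged
#' separately as a putative genotyping artifact.
#'
#' @param geno Long genotype tibble.
#' @param meta Sample metadata (used to reject haploid samples).
#' @param mask Ancestral-heterozygosity mask from [call_ancestral_het()]
#'   (from the sample's clonal line).
#' @param sample Sample id (must be diploid).
#' @return Tibble `chrom`, `pos`, `loh`, `artifact` over flagged mask sites.
#' @export
loh_mask <- function(geno, meta, mask, sample) {
  check_meta(meta)
  pl <- meta$ploidy[match(sample, meta$sample_id)]
  if (is.na(pl)) abort(paste0("unknown sample: ", sample))
  if (pl != 2L) abort(paste0("sample ", sample, " is haploid; LOH is defined for diploids"))
  anc <- mask[mask$anc_het, c("chrom", "pos", "a_lo", "a_hi")]
  g <- geno[geno$sample_id == sample, c("chrom", "pos", "a1", "a2")]
  d <- left_join(anc, g, by = c("chrom", "pos"))
  hom <- !is.na(d$a1) & !is.na(d$a2) & d$a1 == d$a2
  anc_allele <- hom & (d$a1 == d$a_lo | d$a1 == d$a_hi)
  tibble(chrom = d$chrom, pos = d$pos,
         loh = ifelse(is.na(d$a1) | is.na(d$a2), NA, hom & anc_allele),
         artifact = hom & !anc_allele)
}

#' Segment a homozygosity mask into runs
#'
#' Rule-based run segmentation: maximal runs of LOH-flagged SNPs containing
#' at least `min_snps` flagged sites and interrupted by at most `max_err`
#' heterozygous sites per run. Sites with missing calls are skipped (they
#' neither extend nor break a run). The reported interval spans the first to
#' the last homozygous SNP of the run, 0-based half-open.
#'
#' @param loh Per-site mask from [loh_mask()] (`chrom`, `pos`, `loh`).
#' @param min_snps Minimum flagged SNPs per segment (default 10).
#' @param max_err Maximum interrupting heterozygous sites (default 1).
#' @return Tibble `chrom`, `start`, `end`, `n_snps`.
#' @export
segment_runs <- function(loh, min_snps = 10L, max_err = 1L) {
  stopifnot(min_snps >= 1, max_err >= 0)
  out <- list()
  for (cr in unique(loh$chrom)) {
    d <- loh[loh$chrom == cr & !is.na(loh$loh), ]
    d <- d[order(d$pos), ]
    v <- d$loh
    n <- length(v)
    i <- 1L
    while (i <= n) {
      if (!v[i]) { i <- i + 1L; next }
      err <- 0L
      last_true <- i
      n_true <- 1L
      k <- i + 1L
      while (k <= n) {
        if (v[k]) {
          last_true <- k
          n_true <- n_true + 1L
          k <- k + 1L
        } else if (err < max_err) {
          err <- err + 1L
          k <- k + 1L
        } else {
          break
        }
      }
      if (n_true >= min_snps) {
        out[[length(out) + 1L]] <- tibble(
          chrom = cr, start = d$pos[i] - 1, end = as.double(d$pos[last_true]),
          n_snps = n_true)
      }
      i <- last_true + 1L
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  n_snps = integer()))
  }
  bind_rows(out)
}

#' Call LOH segments for a set of diploid samples
#'
#' Convenience wrapper running [loh_mask()] + [segment_runs()] per sample.
#'
#' @inheritParams loh_mask
#' @param samples Sample ids (default: all diploids in `meta`).
#' @inheritParams segment_runs
#' @return Tibble `sample_id`, `chrom`, `start`, `end`, `n_snps`.
#' @export
loh_segments <- function(geno, meta, mask, samples = NULL, min_snps = 10L,
                         max_err = 1L) {
  if (is.null(samples)) samples <- meta$sample_id[meta$ploidy == 2L]
  purrr::map_dfr(samples, function(s) {
    seg <- segment_runs(loh_mask(geno, meta, mask, s), min_snps, max_err)
    if (nrow(seg)) mutate(seg, sample_id = s, .before = 1) else seg
  })
}

#' Maximal-support intersection of LOH segments across diploid males
#'
#' Finds the genomic region covered by LOH segments in the greatest number
#' of diploid males, restricted to sites at which every genotyped female is
#' heterozygous: subregions containing a female-homozygous site are
#' excluded. Coverage is resolved over the elementary intervals defined by
#' all segment endpoints (plus excluded sites); the returned interval is the
#' maximal contiguous run at peak support, ties broken leftmost.
#'
#' @param segments Segment tibble (`sample_id`, `chrom`, `start`, `end`),
#'   typically from [loh_segments()] on the diploid males.
#' @param female_hom_sites Optional tibble `chrom`, `pos` of sites at which
#'   some female is homozygous (these positions are excluded from the
#'   candidate region).
#' @return One-row tibble `chrom`, `start`, `end`, `support`, `males`
#'   (list-column of supporting sample ids).
#' @export
intersect_loh_across_males <- function(segments, female_hom_sites = NULL) {
  if (!nrow(segments)) abort("no LOH segments supplied")
  best <- NULL
  for (cr in unique(segments$chrom)) {
    seg <- segments[segments$chrom == cr, ]
    excl <- if (is.null(female_hom_sites)) numeric() else {
      female_hom_sites$pos[female_hom_sites$chrom == cr]
    }
    # elementary breakpoints: segment ends plus one-bp exclusion windows
    bp <- sort(unique(c(seg$start, seg$end, excl - 1, excl)))
    if (length(bp) < 2) next
    starts <- bp[-length(bp)]
    ends <- bp[-1]
    sup <- vapply(seq_along(starts), function(i) {
      covered <- seg$start <= starts[i] & seg$end >= ends[i]
      length(unique(seg$sample_id[covered]))
    }, 0L)
    has_excl <- vapply(seq_along(starts), function(i) {
      any(excl - 1 >= starts[i] & excl <= ends[i])
    }, TRUE)
    sup[has_excl] <- -1L
    if (all(sup < 1)) next
    mx <- max(sup)
    at_max <- which(sup == mx)
    # maximal contiguous runs at peak support
    runs <- split(at_max, cumsum(c(TRUE, diff(at_max) != 1 |
                                     starts[at_max][-1] != ends[at_max][-length(at_max)])))
    r <- runs[[1]]  # leftmost
    cand <- tibble(chrom = cr, start = starts[min(r)], end = ends[max(r)],
                   support = mx)
    if (is.null(best) || cand$support > best$support) best <- cand
  }
  if (is.null(best)) abort("no supported region outside female-homozygous sites")
  seg <- segments[segments$chrom == best$chrom, ]
  ov <- seg$start < best$end & seg$end > best$start
  best$males <- list(sort(unique(seg$sample_id[ov])))
  best
}

#' Assign allelic identity within an interval against a reference haploid
#'
#' Following the mapping convention of using a reference haploid male as the
#' allele-1 carrier: each homozygous call of the focal sample at an
#' ancestrally heterozygous site in the interval is labelled `allele1` if it
#' matches the reference haploid's allele there and `allele2` otherwise. The
#' sample-level class is `heterozygous` when the sample has no homozygous
#' call in the interval, otherwise the majority label when it reaches at
#' least `agreement` of homozygous sites, else `mixed`.
#'
#' @param geno Long genotype tibble.
#' @param interval One-row tibble/list with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param sample Focal sample id.
#' @param reference_haploid Reference haploid sample id (must have
#'   non-missing calls in the interval).
#' @param mask Optional ancestral-heterozygosity mask restricting the sites
#'   used.
#' @param agreement Majority threshold (default 0.9).
#' @return One of `"allele1"`, `"allele2"`, `"heterozygous"`, `"mixed"`.
#' @export
assign_allele <- function(geno, interval, sample, reference_haploid,
                          mask = NULL, agreement = 0.9) {
  in_iv <- geno$chrom == interval$chrom & geno$pos > interval$start &
    geno$pos <= interval$end
  g <- geno[in_iv, ]
  if (!is.null(mask)) {
    g <- inner_join(g, mask[mask$anc_het, c("chrom", "pos")],
                    by = c("chrom", "pos"))
  }
  ref <- g[g$sample_id == reference_haploid & !is.na(g$a1), ]
  ref <- ref[is.na(ref$a2) | ref$a1 == ref$a2, ]
  if (!nrow(ref)) {
    abort(paste0("reference haploid ", reference_haploid,
                 " has no usable calls in the interval"))
  }
  foc <- g[g$sample_id == sample & !is.na(g$a1) & !is.na(g$a2), ]
  foc <- inner_join(foc, select(ref, "chrom", "pos", ref_allele = "a1"),
                    by = c("chrom", "pos"))
  if (!nrow(foc)) return("mixed")
  hom <- foc$a1 == foc$a2
  if (!any(hom)) return("heterozygous")
  n1 <- sum(foc$a1[hom] == foc$ref_allele[hom])
  n2 <- sum(hom) - n1
  f1 <- n1 / (n1 + n2)
  if (f1 >= agreement) "allele1" else if (f1 <= 1 - agreement) "allele2" else "mixed"
}

#' Per-sample genotype classes over a candidate locus
#'
#' Applies [assign_allele()] to every diploid sample, yielding the class
#' table whose sex-by-class counts mirror the headline locus summary
#' (females heterozygous; diploid males split between heterozygous and the
#' two homozygous classes).
#'
#' @inheritParams assign_allele
#' @param meta Sample metadata.
#' @param samples Samples to classify (default: all diploids).
#' @return Tibble `sample_id`, `sex`, `class`.
#' @export
locus_genotype_classes <- function(geno, meta, interval, reference_haploid,
                                   mask = NULL, samples = NULL,
                                   agreement = 0.9) {
  check_meta(meta)
  if (is.null(samples)) samples <- meta$sample_id[meta$ploidy == 2L]
  tibble(sample_id = samples,
         sex = meta$sex[match(samples, meta$sample_id)],
         class = vapply(samples, function(s) {
           assign_allele(geno, interval, s, reference_haploid, mask = mask,
                         agreement = agreement)
         }, ""))
}

#' Normalized per-site read depth
#'
#' Normalizes each sample's per-site depth by its genome-wide median depth
#' over the supplied (filter-passing) sites.
#'
#' @param geno Long genotype tibble (uses the `dp` column), or a tibble
#'   `chrom`, `pos`, `sample_id`, `depth` as read by [read_depth_tsv()].
#' @return Tibble `chrom`, `pos`, `sample_id`, `depth`, `norm_depth`.
#' @export
depth_track <- function(geno) {
  d <- if ("depth" %in% names(geno)) {
    geno[, c("chrom", "pos", "sample_id", "depth")]
  } else {
    check_geno(geno)
    tibble(chrom = geno$chrom, pos = geno$pos, sample_id = geno$sample_id,
           depth = as.double(geno$dp))
  }
  d %>%
    group_by(.data$sample_id) %>%
    mutate(.med = median(.data$depth, na.rm = TRUE)) %>%
    ungroup() %>%
    mutate(norm_depth = ifelse(.data$.med > 0, .data$depth / .data$.med,
                               NA_real_)) %>%
    select(-".med")
}

#' Classify segments as copy-neutral or deletion from normalized depth
#'
#' The mean normalized depth of the segment's sample inside the segment is
#' classified: within `neutral_band` copy-neutral, within `deletion_band` a
#' (hemizygous) deletion, otherwise ambiguous. Segments with fewer than
#' `min_sites` depth observations are classified ambiguous.
#'
#' @param depth Depth track from [depth_track()].
#' @param segments Segment tibble with `sample_id`, `chrom`, `start`, `end`.
#' @param neutral_band,deletion_band Inclusive normalized-depth bands.
#' @param min_sites Minimum sites with depth inside the segment (default 5).
#' @return `segments` with `mean_normalized_depth`, `n_depth_sites`,
#'   `depth_class` appended.
#' @export
depth_classify <- function(depth, segments, neutral_band = c(0.8, 1.2),
                           deletion_band = c(0.3, 0.7), min_sites = 5L) {
  res <- purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    d <- depth[depth$sample_id == s$sample_id & depth$chrom == s$chrom &
                 depth$pos > s$start & depth$pos <= s$end &
                 !is.na(depth$norm_depth), ]
    mu <- if (nrow(d)) mean(d$norm_depth) else NA_real_
    cls <- if (nrow(d) < min_sites || is.na(mu)) {
      "ambiguous"
    } else if (mu >= neutral_band[1] && mu <= neutral_band[2]) {
      "copy_neutral"
    } else if (mu >= deletion_band[1] && mu <= deletion_band[2]) {
      "deletion"
    } else {
      "ambiguous"
    }
    tibble(mean_normalized_depth = mu, n_depth_sites = nrow(d),
           depth_class = cls)
  })
  bind_cols(segments, res)
}

#' Ordinal SNP coordinates
#'
#' Maps each ancestrally heterozygous SNP to its rank along its chromosome
#' (1..K), the coordinate frame used for stacked LOH displays in which
#' physical SNP density does not distort segment widths.
#'
#' @param mask Ancestral-heterozygosity mask.
#' @return Tibble `chrom`, `pos`, `ord`.
#' @export
ordinalize_sites <- function(mask) {
  mask[mask$anc_het, c("chrom", "pos")] %>%
    arrange(.data$chrom, .data$pos) %>%
    group_by(.data$chrom) %>%
    mutate(ord = row_number()) %>%
    ungroup()
}

#' Re-express segments in ordinal SNP coordinates
#'
#' A segment covering SNPs of rank a..b becomes the ordinal interval
#' `[a, b + 1)`. Segments containing no flagged SNP are dropped.
#'
#' @param segments Segment tibble (`chrom`, `start`, `end`, other columns
#'   carried through).
#' @param mask Ancestral-heterozygosity mask.
#' @return `segments` with `ord_start`, `ord_end` appended.
#' @export
ordinalize_segments <- function(segments, mask) {
  ords <- ordinalize_sites(mask)
  purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    o <- ords[ords$chrom == s$chrom & ords$pos > s$start & ords$pos <= s$end, ]
    if (!nrow(o)) return(tibble())
    bind_cols(s, tibble(ord_start = min(o$ord), ord_end = max(o$ord) + 1L))
  })
}
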