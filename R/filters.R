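add_filter_report <- function(geno, name, removed) {
  rep_old <- attr(geno, "filter_report")
  entry <- tibble(filter = name, sites_removed = as.integer(removed))
  attr(geno, "filter_report") <- bind_rows(rep_old, entry)
  geno
}

#' Filter attrition report
#'
#' Returns the per-filter count of removed sites accumulated by the
#' site-level filters applied to a genotype table.
#'
#' @param geno A genotype tibble that has passed through one or more filters.
#' @return Tibble with `filter` and `sites_removed`.
#' @export
filter_report <- function(geno) {
  attr(geno, "filter_report") %||%
    tibble(filter = character(), sites_removed = integer())
}

drop_sites <- function(geno, bad_key, name) {
  key <- site_key(geno$chrom, geno$pos)
  out <- geno[!key %in% bad_key, , drop = FALSE]
  attr(out, "filter_report") <- attr(geno, "filter_report")
  add_filter_report(out, name, length(bad_key))
}

#' Remove sites heterozygous in any haploid male
#'
#' Sites at which a haploid sample carries a heterozygous call are artifacts
#' of falsely collapsed repeats in the reference assembly (a haploid genome
#' cannot be heterozygous) and are removed genome-wide. With no haploid
#' samples present the input is returned unchanged with a warning.
#'
#' @param geno Long genotype tibble.
#' @param meta Sample metadata.
#' @return Filtered genotype tibble; removed-site counts are recorded in
#'   [filter_report()].
#' @export
filter_haploid_het_sites <- function(geno, meta) {
  check_geno(geno); check_meta(meta)
  haploids <- meta$sample_id[meta$ploidy == 1L]
  if (!length(haploids)) {
    warn("no haploid samples: haploid-heterozygosity filter is a no-op")
    return(add_filter_report(geno, "haploid_het", 0L))
  }
  hap <- geno[geno$sample_id %in% haploids, ]
  het <- !is.na(hap$a1) & !is.na(hap$a2) & hap$a1 != hap$a2
  bad <- unique(site_key(hap$chrom[het], hap$pos[het]))
  drop_sites(geno, bad, "haploid_het")
}

#' Remove sites failing the allelic-depth screens
#'
#' A site is removed if any heterozygous-called sample has a proportionate
#' minor allelic depth below `min_het_minor_fraction` (minor depth over the
#' sum of the two called alleles' depths), or if any homozygous-called sample
#' has a nonzero read depth for any non-called allele. Samples with missing
#' calls are ignored.
#'
#' @param geno Long genotype tibble with AD present.
#' @param min_het_minor_fraction Threshold, default 0.25.
#' @return Filtered genotype tibble.
#' @export
filter_allelic_depth <- function(geno, min_het_minor_fraction = 0.25) {
  check_geno(geno)
  called <- !is.na(geno$a1)
  if (any(vapply(geno$ad[called], is.null, TRUE))) {
    abort("AD is absent for called genotypes: allelic-depth filter refused")
  }
  sub <- geno[called, ]
  het <- !is.na(sub$a2) & sub$a1 != sub$a2
  bad_row <- logical(nrow(sub))
  if (any(het)) {
    hi <- which(het)
    frac <- vapply(hi, function(i) {
      ad <- sub$ad[[i]]
      d <- ad[c(sub$a1[i], sub$a2[i]) + 1L]
      s <- sum(d)
      if (s <= 0) 0 else min(d) / s
    }, 0)
    bad_row[hi] <- frac < min_het_minor_fraction
  }
  hom <- !het
  if (any(hom)) {
    oi <- which(hom)
    bad_row[oi] <- vapply(oi, function(i) {
      ad <- sub$ad[[i]]
      sum(ad[-(sub$a1[i] + 1L)]) > 0
    }, TRUE)
  }
  bad <- unique(site_key(sub$chrom[bad_row], sub$pos[bad_row]))
  drop_sites(geno, bad, "allelic_depth")
}

#' Keep only biallelic SNP sites
#'
#' Retains sites whose REF and ALT are single bases (one ALT allele) and at
#' which at most two distinct alleles are observed across retained samples.
#'
#' @param geno Long genotype tibble.
#' @return Filtered genotype tibble.
#' @export
restrict_to_biallelic_snps <- function(geno) {
  check_geno(geno)
  sites <- geno_sites(geno)
  snp <- nchar(sites$ref) == 1L & nchar(sites$alt) == 1L &
    !grepl(",", sites$alt, fixed = TRUE) &
    sites$ref %in% c("A", "C", "G", "T") & sites$alt %in% c("A", "C", "G", "T")
  bad <- site_key(sites$chrom[snp == FALSE], sites$pos[snp == FALSE])
  # multiallelic by observation: more than two distinct called alleles
  obs <- geno %>%
    filter(!is.na(.data$a1)) %>%
    tidyr::pivot_longer(c("a1", "a2"), values_to = "allele") %>%
    filter(!is.na(.data$allele)) %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(n_alleles = n_distinct(.data$allele), .groups = "drop")
  bad2 <- site_key(obs$chrom[obs$n_alleles > 2], obs$pos[obs$n_alleles > 2])
  drop_sites(geno, unique(c(bad, bad2)), "biallelic_snp")
}

#' Mask genotype calls with insufficient read depth
#'
#' A homozygous call supported by a handful of reads is indistinguishable
#' from a heterozygote whose reads happened to sample one allele, so calls
#' with fewer than `min_dp` reads are set to missing (standard minimum-depth
#' genotype masking). Site-level filters and the CSD index then ignore them.
#'
#' @param geno Long genotype tibble.
#' @param min_dp Minimum reads for a usable call (default 8).
#' @return Genotype tibble with low-depth calls set missing.
#' @export
mask_low_depth <- function(geno, min_dp = 8L) {
  check_geno(geno)
  low <- !is.na(geno$dp) & geno$dp < min_dp
  geno$a1[low] <- NA_integer_
  geno$a2[low] <- NA_integer_
  geno
}

#' Remove sites with excessive missingness
#'
#' Drops sites at which more than `max_missing` of the samples have missing
#' genotype calls.
#'
#' @param geno Long genotype tibble.
#' @param max_missing Maximum tolerated missing fraction, default 0.2.
#' @return Filtered genotype tibble.
#' @export
filter_missingness <- function(geno, max_missing = 0.2) {
  check_geno(geno)
  miss <- geno %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(f = mean(is.na(.data$a1)), .groups = "drop")
  bad <- site_key(miss$chrom[miss$f > max_missing], miss$pos[miss$f > max_missing])
  drop_sites(geno, bad, "missingness")
}
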