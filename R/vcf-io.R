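#' Write a cohort genotype table as VCF v4.2
#'
#' Emits a plain-text VCF with per-sample `GT:AD:DP`, contigs declared in the
#' header, and samples ordered as in `meta`. Diploid calls are written
#' unphased (`a/b`), haploid single-allele calls as a bare allele, and
#' spurious heterozygous calls in haploids (collapsed repeats) as `0/1`.
#' Output is byte-identical for identical inputs.
#'
#' @param geno Long genotype tibble (see [emit_genotype_calls()]).
#' @param meta Sample metadata tibble.
#' @param path Output file path.
#' @param chrom_lengths Optional named contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(geno, meta, path, chrom_lengths = NULL) {
  check_geno(geno); check_meta(meta)
  sites <- geno_sites(geno)
  samples <- meta$sample_id
  ploidy <- setNames(meta$ploidy, meta$sample_id)
  n_sites <- nrow(sites)
  skey <- site_key(sites$chrom, sites$pos)
  gi <- match(site_key(geno$chrom, geno$pos), skey)
  sj <- match(geno$sample_id, samples)
  if (anyNA(sj)) {
    abort(paste0("genotype table contains samples absent from metadata: ",
                 paste(unique(geno$sample_id[is.na(sj)]), collapse = ", ")))
  }
  pl <- ploidy[geno$sample_id]
  gt <- ifelse(
    is.na(geno$a1) & is.na(geno$a2),
    ifelse(pl == 2L, "./.", "."),
    ifelse(is.na(geno$a2), as.character(geno$a1),
           paste0(pmin(geno$a1, geno$a2), "/", pmax(geno$a1, geno$a2))))
  ad_str <- vapply(geno$ad, function(x) {
    if (is.null(x) || !length(x)) "." else paste(x, collapse = ",")
  }, "")
  field <- paste0(gt, ":", ad_str, ":", geno$dp)
  m <- matrix(".", nrow = n_sites, ncol = length(samples))
  m[cbind(gi, sj)] <- field
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=csdmapr",
    if (!is.null(chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
              as.integer(chrom_lengths))
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "GT:AD:DP",
                apply(m, 1, paste, collapse = "\t"), sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

parse_allele_pair <- function(gt) {
  a1 <- rep(NA_integer_, length(gt))
  a2 <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & gt != "." & gt != "./." & gt != ".|."
  parts <- stringr::str_split_fixed(gt[ok], "[/|]", 2)
  p1 <- suppressWarnings(as.integer(parts[, 1]))
  p2 <- suppressWarnings(as.integer(parts[, 2]))
  a1[ok] <- p1
  a2[ok] <- p2
  list(a1 = a1, a2 = a2)
}

#' Load a multi-sample VCF into a long genotype table
#'
#' Reads `GT` (required) plus `AD` and `DP` (optional; their absence disables
#' the depth filters with a warning) from a VCF v4.x file (plain or
#' bgzipped), checks the sample set against the metadata table, and returns
#' one row per site per sample. Haploid samples whose genotypes are
#' diploid-coded as homozygous pairs (e.g. `0/0`) are collapsed to a single
#' allele; heterozygous calls in haploids are retained as such (they are the
#' collapsed-repeat artifact the haploid-heterozygosity filter targets).
#'
#' @param path VCF file path.
#' @param meta Sample metadata tibble (`sample_id`, `sex`, `ploidy`, `colony`,
#'   `clonal_line`); every VCF sample must have exactly one row.
#' @return Long genotype tibble with `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `a1`, `a2`, `dp`, `ad`, sites in file order.
#' @export
load_vcf <- function(path, meta) {
  check_meta(meta)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt_m <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_m)
  missing_meta <- setdiff(samples, meta$sample_id)
  if (length(missing_meta)) {
    abort(paste0("VCF samples absent from metadata: ",
                 paste(missing_meta, collapse = ", ")))
  }
  has_ad <- "AD" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID
  has_dp <- "DP" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID
  ad_m <- if (has_ad) vcfR::extract.gt(vcf, element = "AD") else NULL
  dp_m <- if (has_dp) {
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  } else NULL
  if (!has_ad) {
    warn("VCF has no AD field: allelic-depth filters will be unavailable")
  }
  n_sites <- nrow(fix)
  ploidy <- setNames(meta$ploidy, meta$sample_id)
  out <- purrr::map_dfr(seq_along(samples), function(j) {
    sid <- samples[j]
    al <- parse_allele_pair(gt_m[, j])
    if (ploidy[sid] == 1L) {
      hom <- !is.na(al$a1) & !is.na(al$a2) & al$a1 == al$a2
      al$a2[hom] <- NA_integer_
    }
    ad <- if (has_ad) {
      lapply(ad_m[, j], function(x) {
        if (is.na(x)) NULL else suppressWarnings(as.integer(strsplit(x, ",")[[1]]))
      })
    } else {
      rep(list(NULL), n_sites)
    }
    dp <- if (has_dp) {
      as.integer(dp_m[, j])
    } else if (has_ad) {
      vapply(ad, function(x) if (is.null(x)) NA_integer_ else sum(x), 0L)
    } else {
      rep(NA_integer_, n_sites)
    }
    tibble(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
           alt = fix$ALT, sample_id = sid, a1 = al$a1, a2 = al$a2,
           dp = dp, ad = unname(ad))
  })
  out
}

#' Read a sample-metadata TSV
#'
#' Expects columns `sample_id`, `sex` (`female`/`male`), `ploidy` (1/2),
#' `colony`, `clonal_line`.
#'
#' @param path TSV file path.
#' @return Metadata tibble.
#' @export
read_meta_tsv <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            sample_id = "c", sex = "c", ploidy = "i",
                            colony = "c", clonal_line = "c"))
  check_meta(meta)
  meta
}

#' Read a per-site depth table
#'
#' Accepts the `chrom pos sample depth` layout produced by standard per-base
#' depth tools (whitespace- or tab-separated, no header required).
#'
#' @param path File path.
#' @return Tibble with `chrom`, `pos`, `sample_id`, `depth`.
#' @export
read_depth_tsv <- function(path) {
  x <- readr::read_table(path, col_names = c("chrom", "pos", "sample_id", "depth"),
                         show_col_types = FALSE)
  mutate(x, pos = as.integer(.data$pos), depth = as.double(.data$depth))
}
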