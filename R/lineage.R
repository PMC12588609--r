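#' Call putatively ancestrally heterozygous SNPs within a clonal line
#'
#' Every member of a clonal line descends asexually from a single diploid
#' founder, so a site heterozygous in that founder should today be either
#' heterozygous for the same two alleles or — after a loss of heterozygosity —
#' homozygous for one of them. A site is flagged ancestrally heterozygous
#' when (a) at least one non-missing diploid of the line is heterozygous and
#' (b) every other non-missing diploid is heterozygous for the same allele
#' pair or homozygous for one of its two alleles. Haploid samples are
#' excluded (they carry one allele by construction) and samples with missing
#' calls at a site do not veto it.
#'
#' @param geno Long genotype tibble.
#' @param meta Sample metadata.
#' @param clonal_line Line id to analyse.
#' @param min_diploids Minimum non-missing diploid genotypes required at a
#'   site (default 2).
#' @return Tibble with one row per site: `chrom`, `pos`, `ref`, `alt`,
#'   `anc_het` flag, ancestral allele indices `a_lo`, `a_hi` and bases
#'   `allele1`, `allele2` (NA where not flagged), plus counts of genotyped
#'   (`n_diploid`) and heterozygous (`n_het`) diploids at the site.
#'   The line id is attached as attribute `clonal_line`.
#' @export
call_ancestral_het <- function(geno, meta, clonal_line, min_diploids = 2L) {
  check_geno(geno); check_meta(meta)
  dips <- meta$sample_id[meta$ploidy == 2L & meta$clonal_line == clonal_line]
  if (!length(dips)) {
    abort(paste0("clonal line '", clonal_line, "' has no diploid samples"))
  }
  sites <- geno_sites(geno)
  d <- geno %>%
    filter(.data$sample_id %in% dips, !is.na(.data$a1), !is.na(.data$a2)) %>%
    mutate(lo = pmin(.data$a1, .data$a2), hi = pmax(.data$a1, .data$a2),
           het = .data$lo != .data$hi)
  st <- d %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(
      n_diploid = n(),
      n_het = sum(.data$het),
      pair_ok = n_distinct(paste(.data$lo[.data$het], .data$hi[.data$het])) <= 1,
      p_lo = if (any(.data$het)) .data$lo[.data$het][1] else NA_integer_,
      p_hi = if (any(.data$het)) .data$hi[.data$het][1] else NA_integer_,
      hom_ok = all(.data$lo[!.data$het] %in%
                     c(.data$lo[.data$het][1], .data$hi[.data$het][1])),
      .groups = "drop") %>%
    mutate(anc_het = .data$n_diploid >= min_diploids & .data$n_het >= 1L &
             .data$pair_ok & .data$hom_ok)
  out <- sites %>%
    left_join(st, by = c("chrom", "pos")) %>%
    mutate(anc_het = !is.na(.data$anc_het) & .data$anc_het,
           n_diploid = dplyr::coalesce(.data$n_diploid, 0L),
           n_het = dplyr::coalesce(.data$n_het, 0L),
           a_lo = ifelse(.data$anc_het, .data$p_lo, NA_integer_),
           a_hi = ifelse(.data$anc_het, .data$p_hi, NA_integer_)) %>%
    select("chrom", "pos", "ref", "alt", "anc_het", "a_lo", "a_hi",
           "n_diploid", "n_het")
  alleles <- purrr::pmap(list(out$ref, out$alt), function(r, a) {
    c(r, strsplit(a, ",", fixed = TRUE)[[1]])
  })
  out <- out %>%
    mutate(
      allele1 = purrr::map2_chr(alleles, .data$a_lo, function(al, i) {
        if (is.na(i)) NA_character_ else al[i + 1L]
      }),
      allele2 = purrr::map2_chr(alleles, .data$a_hi, function(al, i) {
        if (is.na(i)) NA_character_ else al[i + 1L]
      }))
  attr(out, "clonal_line") <- clonal_line
  out
}

#' Count flagged sites in sliding windows
#'
#' @param mask Ancestral-heterozygosity mask from [call_ancestral_het()].
#' @param window_bp,step_bp Window width and step in bp
#'   (`window_bp >= step_bp > 0`).
#' @param chrom_lengths Optional named chromosome lengths; defaults to the
#'   maximum flagged position per chromosome.
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `n_sites`.
#' @export
windowed_site_counts <- function(mask, window_bp, step_bp,
                                 chrom_lengths = NULL) {
  stopifnot(window_bp >= step_bp, step_bp > 0)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- mask %>%
      group_by(.data$chrom) %>%
      summarise(len = max(.data$pos), .groups = "drop") %>%
      tibble::deframe()
  }
  flagged <- mask[mask$anc_het, ]
  w <- sliding_windows(chrom_lengths, window_bp, step_bp)
  w$n_sites <- purrr::map_int(seq_len(nrow(w)), function(i) {
    sum(flagged$chrom == w$chrom[i] & flagged$pos > w$start[i] &
          flagged$pos <= w$end[i])
  })
  w
}
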