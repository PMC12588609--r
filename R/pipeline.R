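#' Run the full CSD mapping pipeline
#'
#' Orchestrates the whole analysis: load (or simulate) genotypes, apply the
#' site filters, call ancestral heterozygosity in the mapping line, run the
#' permutation CSD index scan, window it, call candidate loci, segment and
#' intersect losses of heterozygosity across diploid males, classify segment
#' copy number from normalized depth, and compute windowed nucleotide
#' diversity with a peak-overlap report. Stage-level input/output site
#' counts are logged; every stage's result is returned in the report bundle.
#'
#' @param vcf Path to a multi-sample VCF (ignored when `geno` or
#'   `sim_config` is given).
#' @param meta Sample metadata tibble or TSV path.
#' @param geno Optional pre-loaded long genotype tibble.
#' @param sim_config Optional [cohort_config()]; when given the cohort is
#'   simulated instead of loaded.
#' @param seed Integer master seed (simulation and permutation sub-streams
#'   derive from it).
#' @param clonal_line Mapping line; defaults to the first line containing
#'   diploid males.
#' @param n_perm Permutations for the scan (default 1000).
#' @param window_bp,step_bp Scan windows (defaults 50 kb / 15 kb).
#' @param alpha Nominal significance threshold on mean window p used for
#'   candidate run formation (default 0.05).
#' @param fdr_alpha FDR level for the reported BH-derived p cutoff
#'   (default 0.05); at desk-scale permutation resolution this cutoff is not
#'   used for run formation because a window mean cannot fall below it once
#'   a single site is non-significant.
#' @param min_snps,max_err LOH segmentation parameters.
#' @param pi_window_bp,pi_step_bp Diversity windows (defaults 5 kb / 1 kb).
#' @param reference_haploid Reference haploid sample for allele assignment;
#'   defaults to the first haploid of the mapping line.
#' @param min_het_minor_fraction,max_missing,min_call_dp Filter parameters
#'   (allelic-depth fraction, per-site missingness cap, minimum-depth
#'   genotype mask).
#' @param chrom_lengths Optional named chromosome lengths.
#' @param out_dir Optional output directory for TSV/BED exports.
#' @return A `csd_report` list: `meta`, `filter_report`, `mask`, `scan`,
#'   `track`, `threshold`, `candidates`, `classes`, `class_counts`,
#'   `segments`, `intersection`, `pi`, `pi_report`, `params`.
#' @export
run_csd_pipeline <- function(vcf = NULL, meta = NULL, geno = NULL,
                             sim_config = NULL, seed = 1L,
                             clonal_line = NULL, n_perm = 1000L,
                             window_bp = 50000, step_bp = 15000,
                             alpha = 0.05, fdr_alpha = 0.05,
                             min_snps = 10L, max_err = 1L,
                             pi_window_bp = 5000, pi_step_bp = 1000,
                             reference_haploid = NULL,
                             min_het_minor_fraction = 0.25,
                             max_missing = 0.2, min_call_dp = 8L,
                             chrom_lengths = NULL,
                             out_dir = NULL) {
  if (is.character(meta)) meta <- read_meta_tsv(meta)
  if (!is.null(sim_config)) {
    inform("stage simulate: generating synthetic cohort")
    sim <- simulate_cohort(sim_config, seed = derive_seed(seed, "sim"))
    geno <- sim$geno
    meta <- sim$meta
    chrom_lengths <- chrom_lengths %||% sim_config$chrom_lengths
  } else if (is.null(geno)) {
    if (is.null(vcf)) abort("provide vcf, geno or sim_config")
    inform(paste0("stage load: reading ", vcf))
    geno <- load_vcf(vcf, meta)
  }
  check_meta(meta)
  n0 <- nrow(geno_sites(geno))
  inform(paste0("stage load: ", n0, " sites, ", length(unique(geno$sample_id)),
                " samples"))
  if (n0 == 0) abort("no sites after filtering: input VCF is empty")
  has_ad <- !all(vapply(geno$ad, is.null, TRUE))
  geno <- mask_low_depth(geno, min_dp = min_call_dp)
  geno <- filter_missingness(geno, max_missing = max_missing)
  geno <- filter_haploid_het_sites(geno, meta)
  if (has_ad) {
    geno <- filter_allelic_depth(geno, min_het_minor_fraction)
  } else {
    warn("AD absent: skipping allelic-depth filter")
  }
  geno <- restrict_to_biallelic_snps(geno)
  frep <- filter_report(geno)
  n1 <- nrow(geno_sites(geno))
  inform(paste0("stage filter: ", n1, " sites retained (",
                n0 - n1, " removed)"))
  if (n1 == 0) abort("no sites after filtering")
  if (is.null(clonal_line)) {
    with_males <- meta %>%
      filter(.data$ploidy == 2L, .data$sex == "male") %>%
      pull(.data$clonal_line)
    clonal_line <- if (length(with_males)) with_males[1] else meta$clonal_line[1]
  }
  mask <- call_ancestral_het(geno, meta, clonal_line)
  n_anc <- sum(mask$anc_het)
  inform(paste0("stage anchet: ", n_anc, " ancestrally heterozygous sites in line ",
                clonal_line))
  if (n_anc == 0) abort("no informative sites: no ancestral heterozygosity found")
  scan <- csd_scan(geno, meta, clonal_line = clonal_line, mask = mask,
                   n_perm = n_perm, seed = derive_seed(seed, "perm"))
  track <- windowed_mean(scan, window_bp = window_bp, step_bp = step_bp,
                         statistic = "pvalue", chrom_lengths = chrom_lengths)
  fdr_cutoff <- bh_p_cutoff(scan$sites$p, scan$sites$q, fdr_alpha)
  thr <- alpha
  candidates <- rank_candidates(call_peak(track, thr), scan)
  inform(paste0("stage scan: ", nrow(candidates), " candidate locus/loci"))
  dip_males <- meta$sample_id[meta$ploidy == 2L & meta$sex == "male" &
                                meta$clonal_line == clonal_line]
  segments <- if (length(dip_males)) {
    loh_segments(geno, meta, mask, samples = dip_males, min_snps = min_snps,
                 max_err = max_err)
  } else {
    tibble(sample_id = character(), chrom = character(), start = double(),
           end = double(), n_snps = integer())
  }
  inform(paste0("stage loh: ", nrow(segments), " segments across ",
                length(dip_males), " diploid males"))
  fem <- meta$sample_id[meta$ploidy == 2L & meta$sex == "female" &
                          meta$clonal_line == clonal_line]
  fh <- geno %>%
    filter(.data$sample_id %in% fem, !is.na(.data$a1), !is.na(.data$a2),
           .data$a1 == .data$a2) %>%
    distinct(.data$chrom, .data$pos) %>%
    inner_join(mask[mask$anc_het, c("chrom", "pos")], by = c("chrom", "pos"))
  intersection <- if (nrow(segments)) {
    tryCatch(intersect_loh_across_males(segments, female_hom_sites = fh),
             error = function(e) NULL)
  } else NULL
  depth <- depth_track(geno)
  if (nrow(segments)) segments <- depth_classify(depth, segments)
  haploids <- meta$sample_id[meta$ploidy == 1L &
                               meta$clonal_line == clonal_line]
  if (is.null(reference_haploid) && length(haploids)) {
    reference_haploid <- haploids[1]
  }
  top <- if (nrow(candidates)) candidates[1, ] else NULL
  classes <- NULL
  class_counts <- NULL
  if (!is.null(top) && !is.null(reference_haploid)) {
    line_dips <- meta$sample_id[meta$ploidy == 2L &
                                  meta$clonal_line == clonal_line]
    classes <- tryCatch(
      locus_genotype_classes(geno, meta, top, reference_haploid, mask = mask,
                             samples = line_dips),
      error = function(e) NULL)
    if (!is.null(classes)) {
      class_counts <- classes %>% count(.data$sex, .data$class)
    }
  }
  pi_track <- windowed_pi(geno, meta, window_bp = pi_window_bp,
                          step_bp = pi_step_bp, chrom_lengths = chrom_lengths)
  pi_report <- if (!is.null(top)) peak_overlap_report(pi_track, top) else NULL
  report <- structure(list(
    meta = meta, filter_report = frep, mask = mask, scan = scan,
    track = track, threshold = thr, fdr_cutoff = fdr_cutoff,
    candidates = candidates,
    classes = classes, class_counts = class_counts, segments = segments,
    intersection = intersection, pi = pi_track, pi_report = pi_report,
    clonal_line = clonal_line,
    params = list(seed = seed, n_perm = n_perm, window_bp = window_bp,
                  step_bp = step_bp, alpha = alpha, fdr_alpha = fdr_alpha,
                  min_snps = min_snps, max_err = max_err,
                  pi_window_bp = pi_window_bp, pi_step_bp = pi_step_bp,
                  reference_haploid = reference_haploid)),
    class = "csd_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.csd_report <- function(x, ...) {
  cat("CSD mapping report (line ", x$clonal_line, ")\n", sep = "")
  cat("  ancestrally het sites:", sum(x$mask$anc_het), "\n")
  cat("  candidate loci:", nrow(x$candidates), "\n")
  if (nrow(x$candidates)) {
    top <- x$candidates[1, ]
    cat(sprintf("  top: %s:%d-%d (mean p %.4g)\n", top$chrom,
                as.integer(top$start), as.integer(top$end), top$peak_value))
  }
  if (!is.null(x$class_counts)) {
    cat("  locus genotype classes:\n")
    print(as.data.frame(x$class_counts), row.names = FALSE)
  }
  invisible(x)
}

#' Write the report bundle to disk
#'
#' Exports the per-site scan, windowed tracks (BEDGRAPH), candidate loci
#' (BED), genotype-class table, LOH segments (TSV + BED), ordinal track,
#' diversity track and a run manifest into `out_dir` with fixed names.
#'
#' @param report A `csd_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(report$filter_report, p("filter_report.tsv"))
  readr::write_tsv(
    report$mask %>% filter(.data$anc_het) %>%
      select("chrom", "pos", "allele1", "allele2"),
    p("ancestral_het_sites.tsv"))
  readr::write_tsv(tidy(report$scan), p("scan_sites.tsv"))
  readr::write_tsv(report$track %>%
                     select("chrom", "start", "end", "value"),
                   p("scan_windows.bedgraph"), col_names = FALSE)
  if (nrow(report$candidates)) {
    readr::write_tsv(report$candidates %>%
                       mutate(name = paste0("candidate_", row_number())) %>%
                       select("chrom", "start", "end", "name"),
                     p("candidate_loci.bed"), col_names = FALSE)
  }
  if (!is.null(report$classes)) {
    readr::write_tsv(report$classes, p("locus_classes.tsv"))
  }
  if (nrow(report$segments)) {
    readr::write_tsv(report$segments, p("loh_segments.tsv"))
    readr::write_tsv(report$segments %>%
                       select("chrom", "start", "end", name = "sample_id"),
                     p("loh_segments.bed"), col_names = FALSE)
    ord <- ordinalize_segments(report$segments, report$mask)
    if (nrow(ord)) readr::write_tsv(ord, p("loh_segments_ordinal.tsv"))
  }
  readr::write_tsv(report$pi %>% select("chrom", "start", "end", "pi"),
                   p("pi_windows.bedgraph"), col_names = FALSE)
  manifest <- c(
    sprintf("csdmapr_version=%s", as.character(utils::packageVersion("csdmapr"))),
    sprintf("clonal_line=%s", report$clonal_line),
    sprintf("threshold=%g", report$threshold),
    vapply(names(report$params), function(k) {
      sprintf("%s=%s", k, paste(format(report$params[[k]]), collapse = ","))
    }, ""))
  writeLines(manifest, p("manifest.txt"))
  invisible(out_dir)
}
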