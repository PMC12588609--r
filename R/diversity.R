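#' Per-site mean pairwise difference
#'
#' Unbiased per-site nucleotide diversity from allele counts:
#' `D = n / (n - 1) * (1 - sum(p_i^2))` with `n` called allele copies and
#' `p_i` the allele frequencies — the average difference over all `C(n, 2)`
#' pairs of sampled haplotypes.
#'
#' @param allele_counts Nonnegative numeric vector of per-allele copy counts
#'   (`sum >= 2`).
#' @return `D` in `[0, 1]`; 0 for a monoallelic site.
#' @export
site_diversity <- function(allele_counts) {
  n <- sum(allele_counts)
  if (n < 2) abort("site diversity needs at least two called allele copies")
  p <- allele_counts / n
  n / (n - 1) * (1 - sum(p^2))
}

per_site_diversity <- function(geno, samples) {
  d <- geno %>%
    filter(.data$sample_id %in% samples, !is.na(.data$a1), !is.na(.data$a2)) %>%
    select("chrom", "pos", "a1", "a2") %>%
    tidyr::pivot_longer(c("a1", "a2"), values_to = "allele")
  d %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(n = n(),
              sumsq = sum((table(.data$allele) / n())^2),
              .groups = "drop") %>%
    filter(.data$n >= 2) %>%
    mutate(D = .data$n / (.data$n - 1) * (1 - .data$sumsq)) %>%
    select("chrom", "pos", "n", "D")
}

#' Windowed nucleotide diversity across clonal lines
#'
#' Allele counts are pooled per site over the diploid genotypes of the
#' included lines (each diploid contributes two copies; missing calls are
#' excluded per site), the per-site mean pairwise difference is computed,
#' and windowed pi is the sum of per-site values over the window divided by
#' the window width in bp. Windows with no segregating sites have pi 0.
#'
#' @param geno Long genotype tibble (filtered variant sites).
#' @param meta Sample metadata.
#' @param lines Clonal lines to pool (default: all lines in `meta`).
#' @param window_bp,step_bp Window and step in bp (defaults 5 kb / 1 kb).
#' @param chrom_lengths Optional named chromosome lengths.
#' @return Tibble `chrom`, `start`, `end`, `n_sites`, `pi`.
#' @export
windowed_pi <- function(geno, meta, lines = NULL, window_bp = 5000,
                        step_bp = 1000, chrom_lengths = NULL) {
  check_geno(geno); check_meta(meta)
  if (is.null(lines)) lines <- unique(meta$clonal_line)
  samples <- meta$sample_id[meta$ploidy == 2L & meta$clonal_line %in% lines]
  if (!length(samples)) abort("no diploid samples in the requested lines")
  ps <- per_site_diversity(geno, samples)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- geno %>%
      group_by(.data$chrom) %>%
      summarise(len = max(.data$pos), .groups = "drop") %>%
      tibble::deframe()
  }
  w <- sliding_windows(chrom_lengths, window_bp, step_bp)
  w$n_sites <- purrr::map_int(seq_len(nrow(w)), function(i) {
    sum(ps$chrom == w$chrom[i] & ps$pos > w$start[i] & ps$pos <= w$end[i] &
          ps$D > 0)
  })
  w$pi <- purrr::map_dbl(seq_len(nrow(w)), function(i) {
    sel <- ps$chrom == w$chrom[i] & ps$pos > w$start[i] & ps$pos <= w$end[i]
    sum(ps$D[sel]) / window_bp
  })
  w
}

#' Per-window difference counts between aligned haplotypes and a reference
#'
#' For each non-overlapping window along the alignment, counts the positions
#' at which each haplotype differs from the named reference haplotype.
#' Positions with `N` in either sequence are skipped; gap-vs-gap columns are
#' skipped; gap-vs-base columns count as differences under the default
#' policy (`gap = "difference"`) or are skipped with `gap = "skip"`.
#'
#' @param haps Named character vector of equal-length aligned sequences over
#'   `A,C,G,T,N,-` (case-insensitive), or a tibble with `name` and `seq`.
#' @param reference_name Name of the reference haplotype.
#' @param window_bp Non-overlapping window width (default 100).
#' @param gap Gap policy: `"difference"` or `"skip"`.
#' @return Tibble `haplotype`, `start`, `end`, `n_diff` (0-based half-open
#'   windows in alignment coordinates).
#' @export
haplotype_diff_windows <- function(haps, reference_name, window_bp = 100,
                                   gap = c("difference", "skip")) {
  gap <- match.arg(gap)
  if (is.data.frame(haps)) haps <- setNames(haps$seq, haps$name)
  haps <- toupper(unlist(haps))
  if (length(unique(nchar(haps))) != 1) abort("haplotypes must be equal length")
  if (!reference_name %in% names(haps)) {
    abort(paste0("reference haplotype '", reference_name, "' not found"))
  }
  L <- nchar(haps[[1]])
  refc <- strsplit(haps[[reference_name]], "")[[1]]
  starts <- seq(0, L - 1, by = window_bp)
  ends <- pmin(starts + window_bp, L)
  win_of <- findInterval(seq_len(L) - 1, starts)
  others <- setdiff(names(haps), reference_name)
  purrr::map_dfr(others, function(h) {
    hc <- strsplit(haps[[h]], "")[[1]]
    skip <- refc == "N" | hc == "N" | (refc == "-" & hc == "-")
    diffp <- refc != hc & !skip
    if (gap == "skip") diffp <- diffp & refc != "-" & hc != "-"
    counts <- vapply(seq_along(starts), function(w) {
      sum(diffp[win_of == w])
    }, 0L)
    tibble(haplotype = h, start = starts, end = ends, n_diff = counts)
  })
}

#' Diversity-peak versus candidate-locus report
#'
#' Reports the argmax-pi window of a diversity track, whether it intersects
#' a candidate interval, and the contiguous run of windows around the argmax
#' whose pi exceeds a genome-wide quantile threshold.
#'
#' @param div_track Output of [windowed_pi()].
#' @param candidate_interval One-row tibble/list `chrom`, `start`, `end`.
#' @param quantile Genome-wide pi quantile defining "elevated" windows
#'   (default 0.999).
#' @return One-row tibble: `peak_chrom`, `peak_start`, `peak_end`, `peak_pi`,
#'   `overlaps_candidate`, `elevated_start`, `elevated_end`, `threshold`.
#' @export
peak_overlap_report <- function(div_track, candidate_interval,
                                quantile = 0.999) {
  thr <- stats::quantile(div_track$pi, quantile, na.rm = TRUE, names = FALSE)
  if (all(div_track$pi <= 0)) {
    return(tibble(peak_chrom = NA_character_, peak_start = NA_real_,
                  peak_end = NA_real_, peak_pi = 0,
                  overlaps_candidate = FALSE, elevated_start = NA_real_,
                  elevated_end = NA_real_, threshold = thr))
  }
  i <- which.max(div_track$pi)
  pk <- div_track[i, ]
  ov <- identical(pk$chrom, candidate_interval$chrom) &&
    pk$start < candidate_interval$end && pk$end > candidate_interval$start
  same <- div_track$chrom == pk$chrom & div_track$pi >= thr
  ord <- which(div_track$chrom == pk$chrom)
  above <- div_track[same, ]
  # contiguous run of elevated windows containing the argmax
  above <- above[order(above$start), ]
  if (nrow(above)) {
    j <- which(above$start == pk$start)
    step <- if (nrow(div_track) > 1) {
      min(diff(sort(unique(div_track$start[div_track$chrom == pk$chrom]))))
    } else Inf
    brk <- c(0, which(diff(above$start) > step), nrow(above))
    seg <- findInterval(j, brk + 1)
    lo <- brk[seg] + 1
    hi <- brk[seg + 1]
    el_start <- above$start[lo]
    el_end <- above$end[hi]
  } else {
    el_start <- el_end <- NA_real_
  }
  tibble(peak_chrom = pk$chrom, peak_start = pk$start, peak_end = pk$end,
         peak_pi = pk$pi, overlaps_candidate = ov,
         elevated_start = el_start, elevated_end = el_end, threshold = thr)
}
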