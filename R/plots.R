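#' Genome-scan plot of the windowed CSD index p-value
#'
#' Karyogram-style panel per chromosome showing -log10 of the mean window
#' p-value, with the nominal and (when supplied) FDR-derived thresholds.
#'
#' @param object A `csd_scan` object.
#' @param window_bp,step_bp Window and step (defaults 50 kb / 15 kb).
#' @param alpha Nominal threshold line (default 0.05).
#' @param fdr_threshold Optional BH-derived p cutoff (see [bh_p_cutoff()]).
#' @param highlight Optional candidate-locus tibble (`chrom`, `start`,
#'   `end`) drawn as shaded intervals.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csd_scan <- function(object, window_bp = 50000, step_bp = 15000,
                              alpha = 0.05, fdr_threshold = NULL,
                              highlight = NULL, ...) {
  track <- windowed_mean(object, window_bp = window_bp, step_bp = step_bp,
                         statistic = "pvalue")
  track <- track[!is.na(track$value), ]
  floor_p <- 1 / (2 * object$n_perm)
  gg <- ggplot2::ggplot(track, ggplot2::aes(
    x = (.data$start + .data$end) / 2, y = -log10(pmax(.data$value, floor_p)))) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::geom_hline(yintercept = -log10(alpha), colour = "goldenrod") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = expression(-log[10] ~ "mean window p"),
                  title = "CSD index permutation scan") +
    ggplot2::theme_minimal()
  if (!is.null(fdr_threshold) && fdr_threshold > 0) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(fdr_threshold),
                                   colour = "brown")
  }
  if (!is.null(highlight) && nrow(highlight)) {
    gg <- gg + ggplot2::geom_rect(
      data = highlight,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "darkgreen", alpha = 0.2)
  }
  gg
}

#' Stacked LOH matrix in ordinal SNP coordinates
#'
#' One horizontal bar per sample along the ordered ancestrally heterozygous
#' SNPs of a chromosome; retained heterozygosity is grey, LOH segments
#' black.
#'
#' @param segments Segment tibble (`sample_id`, `chrom`, `start`, `end`).
#' @param mask Ancestral-heterozygosity mask.
#' @param chrom Chromosome to draw.
#' @param samples Sample order (default: samples in `segments` plus any in
#'   `samples`).
#' @return A ggplot object.
#' @export
plot_loh_matrix <- function(segments, mask, chrom, samples = NULL) {
  ords <- ordinalize_sites(mask)
  k <- sum(ords$chrom == chrom)
  if (is.null(samples)) samples <- sort(unique(segments$sample_id))
  bg <- tibble(sample_id = samples)
  seg <- segments[segments$chrom == chrom, ]
  seg <- if (nrow(seg)) ordinalize_segments(seg, mask) else seg
  gg <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = bg, ggplot2::aes(ymin = match(.data$sample_id, samples) - 0.4,
                                               ymax = match(.data$sample_id, samples) + 0.4),
                       xmin = 1, xmax = k + 1, fill = "grey80") +
    ggplot2::scale_y_continuous(breaks = seq_along(samples), labels = samples) +
    ggplot2::labs(x = paste0("ordinal SNP position (", chrom, ")"), y = NULL,
                  title = "Losses of heterozygosity") +
    ggplot2::theme_minimal()
  if (nrow(seg)) {
    gg <- gg + ggplot2::geom_rect(
      data = seg,
      ggplot2::aes(xmin = .data$ord_start, xmax = .data$ord_end,
                   ymin = match(.data$sample_id, samples) - 0.4,
                   ymax = match(.data$sample_id, samples) + 0.4),
      fill = "black")
  }
  gg
}

#' Windowed nucleotide diversity track
#'
#' @param div_track Output of [windowed_pi()].
#' @param candidate Optional candidate interval(s) shaded green.
#' @return A ggplot object.
#' @export
plot_pi_track <- function(div_track, candidate = NULL) {
  gg <- ggplot2::ggplot(div_track, ggplot2::aes(
    x = (.data$start + .data$end) / 2, y = .data$pi)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(pi),
                  title = "Windowed nucleotide diversity") +
    ggplot2::theme_minimal()
  if (!is.null(candidate) && nrow(as_tibble(candidate))) {
    gg <- gg + ggplot2::geom_rect(
      data = as_tibble(candidate),
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "darkgreen", alpha = 0.2)
  }
  gg
}

#' Write the standard figures for a report bundle
#'
#' Renders the genome-scan plot, the ordinal LOH matrix (for the top
#' candidate's chromosome) and the diversity track to files. Plotting never
#' affects numeric outputs.
#'
#' @param report A `csd_report`.
#' @param out_dir Output directory.
#' @param device File extension (default `"pdf"`).
#' @return Character vector of file paths, invisibly.
#' @export
make_figures <- function(report, out_dir, device = "pdf") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()
  f1 <- file.path(out_dir, paste0("scan", ".", device))
  ggplot2::ggsave(f1, autoplot(report$scan,
                               window_bp = report$params$window_bp,
                               step_bp = report$params$step_bp,
                               alpha = report$params$alpha,
                               fdr_threshold = report$fdr_cutoff,
                               highlight = report$candidates),
                  width = 8, height = 6)
  paths <- c(paths, f1)
  chrom <- if (nrow(report$candidates)) {
    report$candidates$chrom[1]
  } else if (nrow(report$segments)) {
    report$segments$chrom[1]
  } else {
    report$mask$chrom[1]
  }
  f2 <- file.path(out_dir, paste0("loh_matrix", ".", device))
  males <- report$meta$sample_id[report$meta$ploidy == 2L &
                                   report$meta$sex == "male" &
                                   report$meta$clonal_line == report$clonal_line]
  ggplot2::ggsave(f2, plot_loh_matrix(report$segments, report$mask, chrom,
                                      samples = males),
                  width = 8, height = 6)
  paths <- c(paths, f2)
  f3 <- file.path(out_dir, paste0("pi", ".", device))
  ggplot2::ggsave(f3, plot_pi_track(report$pi, candidate = if (nrow(report$candidates)) report$candidates[1, ] else NULL),
                  width = 8, height = 6)
  paths <- c(paths, f3)
  invisible(paths)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
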