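# sites x samples homozygosity matrix over diploid samples:
# 1 = homozygous, 0 = heterozygous, NA = missing call
hom_matrix <- function(geno, samples, sites) {
  skey <- site_key(sites$chrom, sites$pos)
  sub <- geno[geno$sample_id %in% samples, ]
  gi <- match(site_key(sub$chrom, sub$pos), skey)
  keep <- !is.na(gi)
  sub <- sub[keep, ]; gi <- gi[keep]
  sj <- match(sub$sample_id, samples)
  H <- matrix(NA_real_, nrow = nrow(sites), ncol = length(samples),
              dimnames = list(skey, samples))
  val <- ifelse(is.na(sub$a1) | is.na(sub$a2), NA_real_,
                as.double(sub$a1 == sub$a2))
  H[cbind(gi, sj)] <- val
  H
}

csd_index_from_matrix <- function(H, is_female) {
  fem <- H[, is_female, drop = FALSE]
  mal <- H[, !is_female, drop = FALSE]
  n_f <- rowSums(!is.na(fem))
  n_m <- rowSums(!is.na(mal))
  any_fem_hom <- rowSums(fem == 1, na.rm = TRUE) > 0
  idx <- ifelse(n_f == 0 | n_m == 0, NA_real_,
                ifelse(any_fem_hom, 0,
                       rowSums(mal, na.rm = TRUE) / n_m))
  list(index = unname(idx), n_f = unname(n_f), n_m = unname(n_m))
}

#' Per-SNP CSD index
#'
#' The CSD (complementary sex determination) index of a site is 0 if any
#' non-missing diploid female is homozygous there; if all genotyped females
#' are heterozygous it equals the proportion of genotyped diploid males that
#' are homozygous. Sites with no genotyped diploid male or female are
#' reported as `NA` (skipped, with a logged count).
#'
#' @param geno Long genotype tibble (typically restricted to ancestrally
#'   heterozygous sites of the mapping line).
#' @param meta Sample metadata; only diploid samples enter the index.
#' @param clonal_line Optional line id to restrict samples to.
#' @return Tibble `chrom`, `pos`, `index`, `n_female`, `n_male`.
#' @export
csd_index <- function(geno, meta, clonal_line = NULL) {
  check_geno(geno); check_meta(meta)
  m <- meta[meta$ploidy == 2L, ]
  if (!is.null(clonal_line)) m <- m[m$clonal_line == clonal_line, ]
  if (!any(m$sex == "female") || !any(m$sex == "male")) {
    abort("need at least one diploid female and one diploid male")
  }
  sites <- geno_sites(geno)
  H <- hom_matrix(geno, m$sample_id, sites)
  r <- csd_index_from_matrix(H, m$sex == "female")
  n_skip <- sum(is.na(r$index))
  if (n_skip > 0) {
    inform(paste0(n_skip, " site(s) lacked genotyped males or females and were skipped"))
  }
  tibble(chrom = sites$chrom, pos = sites$pos, index = r$index,
         n_female = r$n_f, n_male = r$n_m)
}

# one within-colony shuffle of the sex labels (females stay females in count)
shuffle_within_colony <- function(sex, colony) {
  out <- sex
  for (cl in unique(colony)) {
    i <- which(colony == cl)
    out[i] <- sex[i][sample.int(length(i))]
  }
  out
}

# enumerate all distinct within-colony sex-label assignments
enumerate_labelings <- function(sex, colony, max_n = 250000L) {
  per_colony <- lapply(unique(colony), function(cl) {
    i <- which(colony == cl)
    k <- sum(sex[i] == "female")
    if (k == 0L || k == length(i)) {
      list(list(i = i, fem = if (k) list(i) else list(integer())))
    } else {
      ch <- utils::combn(i, k, simplify = FALSE)
      list(list(i = i, fem = ch))
    }
  })
  counts <- vapply(per_colony, function(x) length(x[[1]]$fem), 0)
  if (prod(counts) > max_n) {
    abort("exhaustive enumeration too large; use method = 'sample'")
  }
  grid <- expand.grid(lapply(counts, seq_len))
  lapply(seq_len(nrow(grid)), function(r) {
    lab <- rep("male", length(sex))
    for (ci in seq_along(per_colony)) {
      pc <- per_colony[[ci]][[1]]
      lab[pc$fem[[grid[r, ci]]]] <- "female"
    }
    lab
  })
}

#' Colony-stratified permutation null for the CSD index
#'
#' Sex labels of diploid individuals are shuffled uniformly within each
#' colony (per-colony sex counts preserved; the underlying colony genetic
#' structure is retained), once per permutation and shared across sites. The
#' per-site p-value is the proportion of permutations whose CSD index is
#' greater than or equal to the observed index. The optional add-one
#' estimator `(k + 1) / (n_perm + 1)` bounds p away from zero.
#' `method = "exhaustive"` replaces sampling by complete enumeration of all
#' distinct within-colony label assignments (small cohorts only).
#'
#' @param geno Long genotype tibble (scan sites).
#' @param meta Sample metadata with colony labels for all diploids.
#' @param clonal_line Optional line restriction.
#' @param n_perm Number of permutations (ignored for exhaustive).
#' @param seed Integer seed.
#' @param add_one Use the add-one p estimator (default `FALSE`, the plain
#'   proportion).
#' @param method `"sample"` (default) or `"exhaustive"`.
#' @return Tibble `chrom`, `pos`, `index`, `p`, `n_female`, `n_male`.
#' @export
permutation_null <- function(geno, meta, clonal_line = NULL, n_perm = 1000L,
                             seed = 1L, add_one = FALSE,
                             method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  check_geno(geno); check_meta(meta)
  m <- meta[meta$ploidy == 2L, ]
  if (!is.null(clonal_line)) m <- m[m$clonal_line == clonal_line, ]
  if (any(is.na(m$colony) | m$colony == "")) {
    abort("colony labels are required for all diploid samples")
  }
  if (method == "sample") stopifnot(n_perm >= 1)
  sites <- geno_sites(geno)
  H <- hom_matrix(geno, m$sample_id, sites)
  obs <- csd_index_from_matrix(H, m$sex == "female")
  labelings <- if (method == "exhaustive") {
    enumerate_labelings(m$sex, m$colony)
  } else {
    with_seed(seed, {
      lapply(seq_len(n_perm), function(b) shuffle_within_colony(m$sex, m$colony))
    })
  }
  k <- rep(0, nrow(sites))
  for (lab in labelings) {
    perm <- csd_index_from_matrix(H, lab == "female")$index
    k <- k + as.double(!is.na(perm) & !is.na(obs$index) & perm >= obs$index)
  }
  B <- length(labelings)
  p <- if (add_one) (k + 1) / (B + 1) else k / B
  p[is.na(obs$index)] <- NA_real_
  tibble(chrom = sites$chrom, pos = sites$pos, index = obs$index, p = p,
         n_female = obs$n_f, n_male = obs$n_m)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Standard step-up BH adjustment with enforced monotonicity; the order of
#' the input is preserved and `NA` p-values stay `NA` without entering the
#' correction.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Vector of q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  q <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  q[ok] <- p.adjust(pvalues[ok], method = "BH")
  q
}

#' Run the full CSD index scan
#'
#' Computes the observed per-site CSD index, its colony-stratified
#' permutation p-values and BH q-values over the ancestrally heterozygous
#' sites of the mapping line, returning a `csd_scan` object with
#' [tidy()]/[glance()]/[ggplot2::autoplot()] methods.
#'
#' @inheritParams permutation_null
#' @param mask Optional ancestral-heterozygosity mask from
#'   [call_ancestral_het()]; when given the scan is restricted to flagged
#'   sites.
#' @return A `csd_scan` object.
#' @export
csd_scan <- function(geno, meta, clonal_line = NULL, mask = NULL,
                     n_perm = 1000L, seed = 1L, add_one = FALSE) {
  if (!is.null(mask)) {
    flagged <- mask[mask$anc_het, c("chrom", "pos")]
    geno <- inner_join(geno, flagged, by = c("chrom", "pos"))
    if (is.null(clonal_line)) clonal_line <- attr(mask, "clonal_line")
  }
  if (nrow(geno) == 0) {
    abort("no informative sites: scan input is empty")
  }
  res <- permutation_null(geno, meta, clonal_line = clonal_line,
                          n_perm = n_perm, seed = seed, add_one = add_one)
  res$q <- bh_fdr(res$p)
  structure(list(sites = res, n_perm = as.integer(n_perm),
                 clonal_line = clonal_line, seed = seed, add_one = add_one),
            class = "csd_scan")
}

#' @export
print.csd_scan <- function(x, ...) {
  cat("CSD index scan", if (!is.null(x$clonal_line))
    paste0("(line ", x$clonal_line, ")"), "\n")
  cat("  sites:", nrow(x$sites), " permutations:", x$n_perm, "\n")
  cat("  min p:", format(min(x$sites$p, na.rm = TRUE)),
      " min q:", format(min(x$sites$q, na.rm = TRUE)), "\n")
  invisible(x)
}

#' @rdname csd_scan
#' @param x A `csd_scan` object.
#' @param ... Unused.
#' @export
tidy.csd_scan <- function(x, ...) x$sites

#' @rdname csd_scan
#' @export
glance.csd_scan <- function(x, ...) {
  tibble(n_sites = nrow(x$sites),
         n_informative = sum(!is.na(x$sites$index)),
         n_perm = x$n_perm,
         max_index = max(x$sites$index, na.rm = TRUE),
         min_p = min(x$sites$p, na.rm = TRUE),
         min_q = min(x$sites$q, na.rm = TRUE))
}

#' Mean of a per-site scan statistic in sliding windows
#'
#' @param scan A `csd_scan` object or a tidy per-site tibble with `chrom`,
#'   `pos` and the statistic columns.
#' @param window_bp,step_bp Window and step in bp (defaults 50 kb / 15 kb).
#' @param statistic One of `"pvalue"`, `"index"`, `"qvalue"`.
#' @param chrom_lengths Optional named chromosome lengths for tiling;
#'   defaults to the maximum site position per chromosome.
#' @return Tibble `chrom`, `start`, `end`, `n_sites`, `value` (NA where a
#'   window contains no informative sites); the statistic name is attached
#'   as attribute `statistic`.
#' @export
windowed_mean <- function(scan, window_bp = 50000, step_bp = 15000,
                          statistic = c("pvalue", "index", "qvalue"),
                          chrom_lengths = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(window_bp >= step_bp)
  sites <- if (inherits(scan, "csd_scan")) scan$sites else as_tibble(scan)
  col <- switch(statistic, pvalue = "p", index = "index", qvalue = "q")
  if (!col %in% names(sites)) {
    abort(paste0("scan input has no '", col, "' column"))
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- sites %>%
      group_by(.data$chrom) %>%
      summarise(len = max(.data$pos), .groups = "drop") %>%
      tibble::deframe()
  }
  w <- sliding_windows(chrom_lengths, window_bp, step_bp)
  out <- window_stat(w, sites$chrom, sites$pos, sites[[col]])
  attr(out, "statistic") <- statistic
  out
}

#' Call candidate loci from a windowed track
#'
#' Merges maximal runs of consecutive windows whose value lies below
#' `threshold` into candidate intervals (one interval per run, spanning the
#' union of its windows). Windows with no sites (`NA` value) carry no
#' evidence either way: by default they neither extend nor break a run
#' (`bridge_empty = TRUE`); set `bridge_empty = FALSE` to have them break
#' runs. Candidates are ranked by their strongest window, ties by run
#' support (number of significant windows), then position.
#'
#' @param track Windowed track from [windowed_mean()].
#' @param threshold Numeric cutoff; windows with `value < threshold` are
#'   significant. For the headline analysis this is either the nominal alpha
#'   (0.05) on mean p-values or the BH-derived p cutoff (see
#'   [bh_p_cutoff()]).
#' @param bridge_empty Should empty (`NA`) windows be bridged? Default `TRUE`.
#' @return Tibble of candidate loci: `chrom`, `start`, `end`, `n_windows`,
#'   `peak_value` (minimum window value in the run).
#' @export
call_peak <- function(track, threshold, bridge_empty = TRUE) {
  sig <- !is.na(track$value) & track$value < threshold
  if (!any(sig)) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  n_windows = integer(), peak_value = double()))
  }
  runs <- track %>%
    mutate(.sig = sig) %>%
    arrange(.data$chrom, .data$start)
  if (bridge_empty) runs <- runs[runs$.sig | !is.na(runs$value), ]
  out <- list()
  cur <- NULL
  prev_chrom <- ""
  for (i in seq_len(nrow(runs))) {
    if (runs$.sig[i]) {
      consecutive <- identical(runs$chrom[i], prev_chrom) && !is.null(cur)
      if (consecutive) {
        cur$end <- max(cur$end, runs$end[i])
        cur$n_windows <- cur$n_windows + 1L
        cur$peak_value <- min(cur$peak_value, runs$value[i])
      } else {
        if (!is.null(cur)) out[[length(out) + 1L]] <- cur
        cur <- list(chrom = runs$chrom[i], start = runs$start[i],
                    end = runs$end[i], n_windows = 1L,
                    peak_value = runs$value[i])
      }
      prev_chrom <- runs$chrom[i]
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- NULL
      prev_chrom <- runs$chrom[i]
    }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- cur
  bind_rows(lapply(out, as_tibble)) %>%
    arrange(.data$peak_value, dplyr::desc(.data$n_windows), .data$chrom,
            .data$start)
}

#' Rank candidate loci by their windowed CSD index peak
#'
#' Significant windows identify where the null is rejected; the candidate
#' CSD locus among them is where the index itself peaks (heterozygous
#' females, homozygous diploid males). Candidates are ranked by the maximum
#' windowed mean CSD index inside their interval — does this run contain
#' the index peak? — with ties broken by run support (number of significant
#' windows), the strongest window, then position. Window-level means are
#' used rather than single-site maxima because an isolated site whose few
#' genotyped males happen to be homozygous reaches an index of 1 anywhere
#' in the genome; a full window of such sites occurs only at the peak.
#'
#' @param candidates Output of [call_peak()].
#' @param scan A `csd_scan` object or tidy per-site tibble with `index`.
#' @param window_bp,step_bp Window geometry for the index track (defaults
#'   match the scan windows, 50 kb / 15 kb).
#' @param min_sites Windows with fewer informative sites than this do not
#'   enter the peak statistic (default 5) — a near-empty window's mean is a
#'   single site's noise.
#' @param merge_gap_bp Candidates on the same chromosome closer than this
#'   are merged before ranking (default 100 kb, about the reach of the
#'   windows poisoned by one artifact site). A single spurious
#'   female-homozygous call zeroes the index at one site and lifts every
#'   window containing it above threshold, splitting one peak in two;
#'   merging across such pinholes is the window-level analogue of the
#'   `max_err` tolerance in LOH segmentation. Set to 0 to disable.
#' @return `candidates` with `peak_index` (max windowed mean index) and
#'   `mean_index` (interval mean) appended, re-ordered.
#' @export
rank_candidates <- function(candidates, scan, window_bp = 50000,
                            step_bp = 15000, min_sites = 5L,
                            merge_gap_bp = 100000) {
  if (!nrow(candidates)) {
    return(mutate(candidates, peak_index = double(), mean_index = double()))
  }
  if (merge_gap_bp > 0 && nrow(candidates) > 1) {
    candidates <- candidates %>% arrange(.data$chrom, .data$start)
    merged <- candidates[1, ]
    for (i in 2:nrow(candidates)) {
      k <- nrow(merged)
      if (candidates$chrom[i] == merged$chrom[k] &&
            candidates$start[i] - merged$end[k] <= merge_gap_bp) {
        merged$end[k] <- max(merged$end[k], candidates$end[i])
        merged$n_windows[k] <- merged$n_windows[k] + candidates$n_windows[i]
        merged$peak_value[k] <- min(merged$peak_value[k],
                                    candidates$peak_value[i])
      } else {
        merged <- bind_rows(merged, candidates[i, ])
      }
    }
    candidates <- merged
  }
  sites <- if (inherits(scan, "csd_scan")) scan$sites else as_tibble(scan)
  sites <- sites[!is.na(sites$index), ]
  stat <- purrr::map(seq_len(nrow(candidates)), function(i) {
    sel <- sites$chrom == candidates$chrom[i] &
      sites$pos > candidates$start[i] & sites$pos <= candidates$end[i]
    if (!any(sel)) return(c(NA_real_, NA_real_))
    pos <- sites$pos[sel]
    idx <- sites$index[sel]
    ws <- seq(candidates$start[i],
              max(candidates$start[i], candidates$end[i] - window_bp),
              by = step_bp)
    wmeans <- vapply(ws, function(w) {
      v <- idx[pos > w & pos <= min(w + window_bp, candidates$end[i])]
      if (length(v) >= min_sites) mean(v) else NA_real_
    }, 0)
    if (all(is.na(wmeans))) wmeans <- mean(idx)
    c(max(wmeans, na.rm = TRUE), mean(idx))
  })
  candidates$peak_index <- vapply(stat, `[`, 0, 1)
  candidates$mean_index <- vapply(stat, `[`, 0, 2)
  arrange(candidates, dplyr::desc(.data$peak_index),
          dplyr::desc(.data$n_windows), .data$peak_value, .data$chrom,
          .data$start)
}

#' BH-derived p-value cutoff
#'
#' The largest observed p-value whose BH q-value is at or below `fdr_alpha`;
#' drawing this cutoff on a mean-p track mirrors drawing the FDR-corrected
#' significance line on a genome scan. Returns 0 when no site passes.
#'
#' @param p,q Per-site p- and q-values.
#' @param fdr_alpha FDR level (default 0.05).
#' @return A single p-value cutoff.
#' @export
bh_p_cutoff <- function(p, q, fdr_alpha = 0.05) {
  ok <- !is.na(p) & !is.na(q) & q <= fdr_alpha
  if (!any(ok)) 0 else max(p[ok])
}

#' Per-SNP Fisher exact test of homozygosity by sex
#'
#' For each site, a two-sided Fisher exact test on the 2x2 table
#' (homozygous/heterozygous) x (diploid male/diploid female), with BH
#' q-values. Sites with an empty male or female margin are skipped (`NA`).
#'
#' @inheritParams csd_index
#' @return Tibble `chrom`, `pos`, `n_hom_male`, `n_het_male`, `n_hom_female`,
#'   `n_het_female`, `p`, `q`.
#' @export
fisher_homozygosity_scan <- function(geno, meta, clonal_line = NULL) {
  check_geno(geno); check_meta(meta)
  m <- meta[meta$ploidy == 2L, ]
  if (!is.null(clonal_line)) m <- m[m$clonal_line == clonal_line, ]
  sites <- geno_sites(geno)
  H <- hom_matrix(geno, m$sample_id, sites)
  fem <- m$sex == "female"
  nhm <- rowSums(H[, !fem, drop = FALSE] == 1, na.rm = TRUE)
  ntm <- rowSums(!is.na(H[, !fem, drop = FALSE]))
  nhf <- rowSums(H[, fem, drop = FALSE] == 1, na.rm = TRUE)
  ntf <- rowSums(!is.na(H[, fem, drop = FALSE]))
  p <- vapply(seq_len(nrow(sites)), function(i) {
    if (ntm[i] == 0 || ntf[i] == 0) return(NA_real_)
    tab <- matrix(c(nhm[i], ntm[i] - nhm[i], nhf[i], ntf[i] - nhf[i]), 2)
    fisher.test(tab)$p.value
  }, 0)
  tibble(chrom = sites$chrom, pos = sites$pos,
         n_hom_male = nhm, n_het_male = ntm - nhm,
         n_hom_female = nhf, n_het_female = ntf - nhf,
         p = p, q = bh_fdr(p))
}

#' Cohort-level contingency test of diploid-male production
#'
#' Pearson chi-square (with and without Yates continuity correction) and the
#' Fisher exact test on a 2x2 table of per-group haploid/diploid male counts,
#' e.g. counts of diploid and haploid males across clonal lines.
#'
#' @param counts A 2x2 nonnegative integer matrix (or object coercible to
#'   one), rows = groups, columns = categories.
#' @return One-row tibble: `chisq`, `df`, `p_chisq`, `chisq_yates`,
#'   `p_chisq_yates`, `p_fisher`.
#' @export
cohort_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)) || any(counts < 0)) {
    abort("counts must be a 2x2 nonnegative table")
  }
  plain <- suppressWarnings(chisq.test(counts, correct = FALSE))
  yates <- suppressWarnings(chisq.test(counts, correct = TRUE))
  fe <- fisher.test(counts)
  tibble(chisq = unname(plain$statistic), df = unname(plain$parameter),
         p_chisq = plain$p.value,
         chisq_yates = unname(yates$statistic),
         p_chisq_yates = yates$p.value,
         p_fisher = fe$p.value)
}
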