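#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All randomness in the package flows from one integer seed; independent
#' stages (and individuals within the simulator) draw from sub-streams whose
#' seeds are derived deterministically from the master seed and a text label.
#' The derivation is a small multiplicative hash kept strictly below 2^31.
#'
#' @param seed Integer master seed.
#' @param label Character scalar naming the sub-stream.
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(label)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Tile chromosomes with sliding windows
#'
#' Windows are 0-based half-open `[start, end)`, placed every `step_bp` bp
#' from 0; the final window is clipped to the chromosome length.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param window_bp,step_bp Window width and step, in bp (`window_bp >= step_bp`).
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
sliding_windows <- function(chrom_lengths, window_bp, step_bp = window_bp) {
  stopifnot(window_bp >= step_bp, step_bp > 0, length(chrom_lengths) > 0)
  purrr::imap_dfr(chrom_lengths, function(len, chrom) {
    starts <- seq(0, max(0, len - 1), by = step_bp)
    tibble(chrom = chrom, start = starts, end = pmin(starts + window_bp, len))
  })
}

# mean of x over sites within each window; sites with NA stat are dropped
window_stat <- function(windows, chrom, pos, x, fun = mean) {
  ok <- !is.na(x)
  chrom <- chrom[ok]; pos <- pos[ok]; x <- x[ok]
  vals <- purrr::map2(windows$start, seq_len(nrow(windows)), function(s, i) {
    sel <- chrom == windows$chrom[i] & pos > s & pos <= windows$end[i]
    x[sel]
  })
  windows %>%
    mutate(
      n_sites = purrr::map_int(vals, length),
      value = purrr::map_dbl(vals, function(v) if (length(v)) fun(v) else NA_real_)
    )
}

check_meta <- function(meta) {
  need <- c("sample_id", "sex", "ploidy", "colony", "clonal_line")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(paste0("metadata is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("metadata sample_id values must be unique")
  }
  if (!all(meta$ploidy %in% c(1L, 2L))) {
    abort("metadata ploidy must be 1 or 2")
  }
  if (!all(meta$sex %in% c("female", "male"))) {
    abort("metadata sex must be 'female' or 'male'")
  }
  invisible(meta)
}

check_geno <- function(geno) {
  need <- c("chrom", "pos", "ref", "alt", "sample_id", "a1", "a2", "dp", "ad")
  miss <- setdiff(need, names(geno))
  if (length(miss)) {
    abort(paste0("genotype table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(geno)
}

# unique sites of a long genotype table, in (chrom, pos) order of first appearance
geno_sites <- function(geno) {
  geno %>%
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt) %>%
    arrange(.data$chrom, .data$pos)
}

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
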