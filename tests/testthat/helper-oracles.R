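# Independent brute-force oracles. These are deliberately written as plain
# loops, separate from the package's vectorized implementations.

# step-up BH, coded from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    i <- o[r]
    val <- min(prev, p[i] * m / r)
    q[i] <- val
    prev <- val
  }
  q
}

# CSD index by explicit counting over individuals
oracle_csd_index <- function(female_calls, male_calls) {
  # calls: character vectors "het", "hom", NA
  f <- female_calls[!is.na(female_calls)]
  m <- male_calls[!is.na(male_calls)]
  if (!length(f) || !length(m)) return(NA_real_)
  for (x in f) if (x == "hom") return(0)
  n_hom <- 0
  for (x in m) if (x == "hom") n_hom <- n_hom + 1
  n_hom / length(m)
}

# two-sided Fisher exact p by enumeration over all tables with fixed margins
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  prob <- function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }
  p_obs <- prob(a)
  lo <- max(0, r1 - (n - c1)); hi <- min(r1, c1)
  tot <- 0
  for (x in lo:hi) {
    px <- prob(x)
    if (px <= p_obs * (1 + 1e-7)) tot <- tot + px
  }
  tot
}

# mean pairwise difference per window over explicit haplotype pairs
oracle_windowed_pi <- function(hap_mat, pos, window_bp, step_bp, chrom_len) {
  # hap_mat: haplotypes x sites allele matrix (NA = missing copy)
  starts <- seq(0, max(0, chrom_len - 1), by = step_bp)
  sapply(starts, function(s) {
    e <- min(s + window_bp, chrom_len)
    tot <- 0
    for (j in seq_along(pos)) {
      if (pos[j] > s && pos[j] <= e) {
        al <- hap_mat[, j]
        al <- al[!is.na(al)]
        nh <- length(al)
        if (nh >= 2) {
          dsum <- 0; np <- 0
          for (x in 1:(nh - 1)) for (y in (x + 1):nh) {
            np <- np + 1
            if (al[x] != al[y]) dsum <- dsum + 1
          }
          tot <- tot + dsum / np
        }
      }
    }
    tot / window_bp
  })
}

# per-SNP support counting for the LOH intersection
oracle_max_support_run <- function(segments, snp_pos, female_hom_pos = numeric()) {
  support <- sapply(snp_pos, function(p) {
    if (p %in% female_hom_pos) return(-1L)
    length(unique(segments$sample_id[segments$start < p & segments$end >= p]))
  })
  mx <- max(support)
  if (mx < 1) return(NULL)
  runs <- rle(support == mx)
  ends <- cumsum(runs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  i <- which(runs$values)[1]
  list(support = mx, pos = snp_pos[starts[i]:ends[i]])
}

# small long-format genotype table builder
make_geno <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"dp" %in% names(df)) df$dp <- 20L
  if (!"ad" %in% names(df)) {
    df$ad <- lapply(seq_len(nrow(df)), function(i) {
      a1 <- df$a1[i]; a2 <- df$a2[i]
      if (is.na(a1)) return(c(0L, 0L))
      if (!is.na(a2) && a1 != a2) c(10L, 10L)
      else {
        ad <- c(0L, 0L); ad[a1 + 1L] <- 20L; ad
      }
    })
  }
  if (!"ref" %in% names(df)) df$ref <- "A"
  if (!"alt" %in% names(df)) df$alt <- "T"
  df[, c("chrom", "pos", "ref", "alt", "sample_id", "a1", "a2", "dp", "ad")]
}

make_meta <- function(sample_id, sex, ploidy, colony = "c1", clonal_line = "A") {
  tibble::tibble(sample_id = sample_id, sex = sex, ploidy = as.integer(ploidy),
                 colony = colony, clonal_line = clonal_line)
}

locus_fixture_paths <- function() {
  list(vcf = system.file("extdata", "locus_classes_synthetic.vcf", package = "csdmapr"),
       meta = system.file("extdata", "locus_classes_synthetic_meta.tsv",
                          package = "csdmapr"))
}

# small shared simulated cohort, built once per test run
small_sim_config <- function(...) {
  defaults <- list(
    chrom_lengths = c(chrA = 4e5, chrB = 8e5),
    snp_density = 1e-3,
    csd = csd_model(tibble::tibble(chrom = "chrB", start = 6e5, end = 6.5e5),
                    rule = "single", stochastic_male_rate = 0),
    reads = read_model(collapsed_regions = tibble::tibble(
      chrom = "chrA", start = 5000, end = 10000)),
    colonies_per_line = 2L, offspring_per_colony = 10L)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

.sim_cache <- new.env(parent = emptyenv())
cached_small_sim <- function() {
  if (is.null(.sim_cache$sim)) .sim_cache$sim <- simulate_cohort(small_sim_config(), seed = 99L)
  .sim_cache$sim
}
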