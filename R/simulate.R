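#' Parameter constructors for the cohort simulator
#'
#' These small validated lists hold the biological and technical parameters of
#' the synthetic-cohort generator.
#'
#' * `csd_model()` — the planted complementary sex determination (CSD)
#'   architecture: one or more genomic intervals at which heterozygosity
#'   triggers female development, homo-/hemizygosity permits male development.
#'   `stochastic_male_rate` is the probability that a locus-heterozygous
#'   diploid nevertheless develops male (non-genetic diploid males).
#' * `meiosis_params()` — central-fusion automixis: `crossover_rate` is the
#'   expected crossovers per chromosome per meiosis (Poisson),
#'   `coinheritance_fidelity` the probability that reciprocally recombined
#'   chromatids are co-inherited (no heterozygosity loss distal to the
#'   crossover), and `haploid_male_rate` the probability that an offspring
#'   arises from an unfused haploid meiotic product.
#' * `read_model()` — sequencing noise: negative-binomial depth with mean
#'   `mean_depth` and size `depth_size` (larger = less overdispersed), per-read
#'   miscall probability `base_error`, and `collapsed_regions`, intervals of
#'   falsely collapsed repeats in which haploid samples emit heterozygous
#'   calls.
#'
#' @param loci Tibble/data frame with `chrom`, `start`, `end` (0-based
#'   half-open) giving the planted CSD locus/loci.
#' @param rule `"single"` or `"multi"`; `"multi"` requires at least two loci
#'   (heterozygosity at any one locus suffices for female development).
#' @param stochastic_male_rate Probability in `[0, 1]`.
#' @param crossover_rate Expected crossovers per chromosome per meiosis.
#' @param coinheritance_fidelity Probability in `[0, 1]`.
#' @param haploid_male_rate Probability in `[0, 1]`.
#' @param mean_depth Expected reads per site (> 0; 0 allowed and yields all
#'   missing calls).
#' @param depth_size Negative-binomial size (dispersion) parameter.
#' @param base_error Per-read miscall probability in `[0, 0.5)`.
#' @param collapsed_regions Tibble with `chrom`, `start`, `end` (0-based
#'   half-open) or `NULL`.
#' @return A validated parameter list of class `csd_model`, `meiosis_params`
#'   or `read_model`.
#' @name sim-params
NULL

#' @rdname sim-params
#' @export
csd_model <- function(loci, rule = c("single", "multi"), stochastic_male_rate = 0) {
  rule <- match.arg(rule)
  loci <- as_tibble(loci)
  stopifnot(all(c("chrom", "start", "end") %in% names(loci)),
            nrow(loci) >= 1, all(loci$end > loci$start))
  if (rule == "multi" && nrow(loci) < 2) {
    abort("rule 'multi' requires at least two loci")
  }
  if (rule == "single" && nrow(loci) != 1) {
    abort("rule 'single' requires exactly one locus")
  }
  if (stochastic_male_rate < 0 || stochastic_male_rate > 1) {
    abort("stochastic_male_rate must be in [0, 1]")
  }
  structure(list(loci = loci, rule = rule,
                 stochastic_male_rate = stochastic_male_rate),
            class = "csd_model")
}

#' @rdname sim-params
#' @export
meiosis_params <- function(crossover_rate = 1.5, coinheritance_fidelity = 0.85,
                           haploid_male_rate = 0.05) {
  stopifnot(crossover_rate >= 0,
            coinheritance_fidelity >= 0, coinheritance_fidelity <= 1,
            haploid_male_rate >= 0, haploid_male_rate <= 1)
  structure(list(crossover_rate = crossover_rate,
                 coinheritance_fidelity = coinheritance_fidelity,
                 haploid_male_rate = haploid_male_rate),
            class = "meiosis_params")
}

#' @rdname sim-params
#' @export
read_model <- function(mean_depth = 25, depth_size = 20, base_error = 0.001,
                       collapsed_regions = NULL) {
  stopifnot(mean_depth >= 0, depth_size > 0,
            base_error >= 0, base_error < 0.5)
  if (!is.null(collapsed_regions)) {
    collapsed_regions <- as_tibble(collapsed_regions)
    stopifnot(all(c("chrom", "start", "end") %in% names(collapsed_regions)))
  }
  structure(list(mean_depth = mean_depth, depth_size = depth_size,
                 base_error = base_error, collapsed_regions = collapsed_regions),
            class = "read_model")
}

#' Simulate a clonal-line founder genome
#'
#' Draws a SNP panel along each chromosome and an ancestral-heterozygosity
#' mask for the diploid founder of a clonal line. Sites are drawn uniformly,
#' then sorted and deduplicated. The heterozygosity mask is drawn either
#' independently per site or in contiguous blocks of `het_block_bp` bp
#' (whole blocks are heterozygous or homozygous), mimicking the line-specific
#' ancestrally homozygous regions seen among clonal lines.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param snp_density Expected SNPs per bp (> 0).
#' @param anc_het_fraction Fraction of sites (or blocks) heterozygous in the
#'   founder, in `[0, 1]`.
#' @param seed Integer seed.
#' @param het_block_bp Block length for the mask in bp, or `NULL` for
#'   independent per-site draws.
#' @param sites Optional site panel (tibble `chrom`, `pos`, `ref`, `alt`) to
#'   reuse across founders of different lines; positions are 1-based.
#' @param force_het Optional intervals (tibble `chrom`, `start`, `end`,
#'   0-based half-open) forced heterozygous — used to guarantee the planted
#'   CSD locus is heterozygous in a viable founder.
#' @return An object of class `founder_genome`: `chrom_lengths`, a `sites`
#'   tibble (`chrom`, `pos`, `ref`, `alt`, `anc_het`) and haplotypes `h1`,
#'   `h2` (allele indices, 0 = ref).
#' @export
simulate_founder <- function(chrom_lengths, snp_density, anc_het_fraction,
                             seed, het_block_bp = NULL, sites = NULL,
                             force_het = NULL) {
  if (length(chrom_lengths) == 0 || any(chrom_lengths <= 0)) {
    abort("chrom_lengths must name at least one chromosome of positive length")
  }
  stopifnot(snp_density > 0, anc_het_fraction >= 0, anc_het_fraction <= 1)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    if (is.null(sites)) {
      sites <- purrr::imap_dfr(chrom_lengths, function(len, chrom) {
        n <- max(1L, round(snp_density * len))
        pos <- sort(unique(sample.int(len, n, replace = TRUE)))
        ref <- sample(bases, length(pos), replace = TRUE)
        alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
        tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = unname(alt))
      })
    } else {
      sites <- as_tibble(sites)[, c("chrom", "pos", "ref", "alt")]
    }
    n <- nrow(sites)
    if (is.null(het_block_bp)) {
      het <- runif(n) < anc_het_fraction
    } else {
      block <- floor(sites$pos / het_block_bp)
      key <- paste(sites$chrom, block)
      ub <- unique(key)
      het <- (runif(length(ub)) < anc_het_fraction)[match(key, ub)]
    }
    if (!is.null(force_het) && nrow(force_het)) {
      for (i in seq_len(nrow(force_het))) {
        het <- het | (sites$chrom == force_het$chrom[i] &
                        sites$pos > force_het$start[i] &
                        sites$pos <= force_het$end[i])
      }
    }
    hom_allele <- ifelse(runif(n) < 0.5, 0L, 1L)
    h1 <- ifelse(het, 0L, hom_allele)
    h2 <- ifelse(het, 1L, hom_allele)
    structure(list(chrom_lengths = chrom_lengths,
                   sites = mutate(sites, anc_het = het),
                   h1 = as.integer(h1), h2 = as.integer(h2)),
              class = "founder_genome")
  })
}

new_individual <- function(h1, h2, ploidy) {
  list(h1 = as.integer(h1),
       h2 = if (ploidy == 2L) as.integer(h2) else NULL,
       ploidy = as.integer(ploidy))
}

#' Produce one offspring by central-fusion automixis
#'
#' Simulates a single maternal meiosis with Poisson-distributed crossovers
#' placed uniformly per chromosome, then fuses two central meiotic products.
#' With probability `coinheritance_fidelity` per crossover the reciprocally
#' recombined chromatids are co-inherited and heterozygosity is preserved
#' across the breakpoint; otherwise heterozygosity is lost from the breakpoint
#' to the chromosome end (higher coordinate), homozygous for one of the two
#' maternal haplotypes chosen with equal probability. With probability
#' `haploid_male_rate` a single (recombinant) haploid product is returned
#' instead.
#'
#' @param mother An individual as returned by this function or the founder
#'   haplotypes (a list with `h1`, `h2`, `ploidy = 2`).
#' @param founder The `founder_genome` providing site coordinates.
#' @param params A [meiosis_params()] object.
#' @param seed Integer seed.
#' @param forced_breakpoints Optional named list (chromosome -> integer bp
#'   positions) overriding the random crossover draw — used for targeted
#'   tests of tract structure.
#' @return List with `individual` (haplotypes + ploidy) and `tracts`, a tibble
#'   of true LOH tracts (`chrom`, `start`, `end` 0-based half-open,
#'   `maternal_hap` in `{1, 2}`), empty for haploids.
#' @export
reproduce_central_fusion <- function(mother, founder, params, seed,
                                     forced_breakpoints = NULL) {
  if (is.null(mother$h2) || mother$ploidy != 2L) {
    abort("mother must be diploid")
  }
  sites <- founder$sites
  with_seed(seed, {
    haploid <- runif(1) < params$haploid_male_rate
    tracts <- tibble(chrom = character(), start = double(), end = double(),
                     maternal_hap = integer())
    if (haploid) {
      h <- integer(nrow(sites))
      for (chrom in names(founder$chrom_lengths)) {
        len <- founder$chrom_lengths[[chrom]]
        idx <- which(sites$chrom == chrom)
        bps <- forced_breakpoints[[chrom]] %||%
          {
            k <- rpois(1, params$crossover_rate)
            if (k > 0) sort(sample.int(len - 1L, k, replace = TRUE)) else integer()
          }
        start_hap <- sample(1:2, 1)
        n_sw <- vapply(sites$pos[idx], function(p) sum(bps < p), 0)
        use_h1 <- ((n_sw %% 2 == 0) == (start_hap == 1))
        h[idx] <- ifelse(use_h1, mother$h1[idx], mother$h2[idx])
      }
      return(list(individual = new_individual(h, NULL, 1L), tracts = tracts))
    }
    h1 <- mother$h1
    h2 <- mother$h2
    for (chrom in names(founder$chrom_lengths)) {
      len <- founder$chrom_lengths[[chrom]]
      idx <- which(sites$chrom == chrom)
      bps <- forced_breakpoints[[chrom]] %||%
        {
          k <- rpois(1, params$crossover_rate)
          if (k > 0) sort(sample.int(len - 1L, k, replace = TRUE)) else integer()
        }
      if (!length(bps)) next
      bps <- sort(bps)
      faithful <- runif(length(bps)) < params$coinheritance_fidelity
      failed <- bps[!faithful]
      if (!length(failed)) next
      chosen <- sample(1:2, length(failed), replace = TRUE)
      for (j in seq_along(failed)) {
        distal <- idx[sites$pos[idx] > failed[j]]
        src <- if (chosen[j] == 1) mother$h1 else mother$h2
        h1[distal] <- src[distal]
        h2[distal] <- src[distal]
      }
      ends <- c(failed[-1], len)
      tr <- tibble(chrom = chrom, start = as.double(failed),
                   end = as.double(ends), maternal_hap = chosen)
      # merge adjacent tracts homozygous for the same maternal haplotype
      keep <- c(TRUE, tr$maternal_hap[-1] != tr$maternal_hap[-nrow(tr)])
      grp <- cumsum(keep)
      tr <- tr %>%
        group_by(grp = grp) %>%
        summarise(chrom = first(.data$chrom), start = min(.data$start),
                  end = max(.data$end), maternal_hap = first(.data$maternal_hap),
                  .groups = "drop") %>%
        select(-"grp")
      tracts <- bind_rows(tracts, tr)
    }
    list(individual = new_individual(h1, h2, 2L), tracts = tracts)
  })
}

locus_site_index <- function(sites, locus) {
  which(sites$chrom == locus$chrom & sites$pos > locus$start &
          sites$pos <= locus$end)
}

#' Assign sex from genotype under a CSD model
#'
#' Haploids develop male. A diploid heterozygous at one or more model loci
#' develops female — except with probability `stochastic_male_rate` it
#' develops male regardless (a non-genetic diploid male). A diploid
#' homozygous at every locus develops male.
#'
#' @param individual Individual (haplotypes + ploidy).
#' @param founder The `founder_genome` providing site coordinates.
#' @param model A [csd_model()].
#' @param seed Integer seed (used only for the stochastic flip).
#' @return `"male"` or `"female"`.
#' @export
assign_sex <- function(individual, founder, model, seed = 1L) {
  sites <- founder$sites
  het_any <- FALSE
  for (i in seq_len(nrow(model$loci))) {
    idx <- locus_site_index(sites, model$loci[i, ])
    if (!length(idx)) {
      abort(paste0("invalid model: locus ", model$loci$chrom[i], ":",
                   model$loci$start[i], "-", model$loci$end[i],
                   " contains no SNPs"))
    }
    if (individual$ploidy == 2L &&
        any(individual$h1[idx] != individual$h2[idx])) {
      het_any <- TRUE
    }
  }
  if (individual$ploidy == 1L) return("male")
  if (!het_any) return("male")
  if (model$stochastic_male_rate > 0 &&
      with_seed(seed, runif(1)) < model$stochastic_male_rate) {
    return("male")
  }
  "female"
}

#' Simulate sequencing reads and genotype calls for a set of individuals
#'
#' Per site and sample, total depth is negative-binomial; reads originate
#' from the individual's true allele copies and miscall to the site's other
#' allele with probability `base_error`. The genotype call is rule-based:
#' both alleles observed with at least one read each yields a heterozygous
#' call, a single observed allele yields a homozygous (or haploid) call, and
#' zero reads yields a missing call. Haploid samples inside
#' `collapsed_regions` draw reads from both site alleles in equal proportion,
#' emitting the spurious heterozygous calls characteristic of falsely
#' collapsed repeats.
#'
#' @param individuals Named list of individuals (names = sample ids).
#' @param founder The `founder_genome`.
#' @param reads A [read_model()].
#' @param seed Integer seed; each sample uses a derived sub-stream.
#' @return A long genotype tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `a1`, `a2`, `dp`, `ad` (list of per-allele read counts).
#'   For haploid single-allele calls `a2` is `NA`; fully missing calls have
#'   `a1 = a2 = NA`.
#' @export
emit_genotype_calls <- function(individuals, founder, reads, seed) {
  sites <- founder$sites
  n <- nrow(sites)
  collapsed <- rep(FALSE, n)
  if (!is.null(reads$collapsed_regions)) {
    cr <- reads$collapsed_regions
    for (i in seq_len(nrow(cr))) {
      collapsed <- collapsed | (sites$chrom == cr$chrom[i] &
                                  sites$pos > cr$start[i] &
                                  sites$pos <= cr$end[i])
    }
  }
  purrr::imap_dfr(individuals, function(ind, sid) {
    with_seed(derive_seed(seed, paste0("reads:", sid)), {
      dp <- if (reads$mean_depth <= 0) {
        rep(0L, n)
      } else {
        rnbinom(n, size = reads$depth_size, mu = reads$mean_depth)
      }
      p1 <- if (ind$ploidy == 2L) (ind$h1 + ind$h2) / 2 else as.double(ind$h1)
      if (ind$ploidy == 1L) p1[collapsed] <- 0.5
      src1 <- rbinom(n, dp, p1)
      src0 <- dp - src1
      e <- reads$base_error
      ad1 <- src1 - rbinom(n, src1, e) + rbinom(n, src0, e)
      ad0 <- dp - ad1
      het <- ad0 > 0 & ad1 > 0
      a1 <- dplyr::case_when(dp == 0L ~ NA_integer_,
                             het ~ 0L,
                             ad1 > 0 ~ 1L,
                             TRUE ~ 0L)
      a2 <- dplyr::case_when(dp == 0L ~ NA_integer_,
                             het ~ 1L,
                             ind$ploidy == 1L ~ NA_integer_,
                             TRUE ~ a1)
      tibble(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
             alt = sites$alt, sample_id = sid, a1 = a1, a2 = a2,
             dp = as.integer(dp),
             ad = purrr::map2(as.integer(ad0), as.integer(ad1), c))
    })
  })
}

#' Default cohort configuration
#'
#' Bundles the study-style conditions for [simulate_cohort()]: clonal lines
#' descended from single diploid founders, colonies founded by daughters of
#' the line founder, and per-colony offspring produced by central-fusion
#' automixis with a planted CSD locus.
#'
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param snp_density Expected SNPs per bp.
#' @param anc_het_fraction,het_block_bp Founder heterozygosity level and block
#'   size (see [simulate_founder()]).
#' @param csd A [csd_model()]; its loci are forced heterozygous in every
#'   founder (a homozygous founder could leave no female descendants).
#' @param meiosis A [meiosis_params()].
#' @param reads A [read_model()].
#' @param lines Character vector of clonal-line ids.
#' @param colonies_per_line,offspring_per_colony Cohort design.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(chrom_lengths = c(chr1 = 1e6, chr2 = 4e6),
                          snp_density = 2e-3,
                          anc_het_fraction = 0.6,
                          het_block_bp = 1e5,
                          csd = csd_model(
                            tibble(chrom = "chr2", start = 3.0e6, end = 3.046e6),
                            rule = "single", stochastic_male_rate = 0.05),
                          meiosis = meiosis_params(),
                          reads = read_model(collapsed_regions = tibble(
                            chrom = names(chrom_lengths)[1],
                            start = 10000, end = 15000)),
                          lines = "A",
                          colonies_per_line = 4L,
                          offspring_per_colony = 15L) {
  stopifnot(colonies_per_line >= 1, offspring_per_colony >= 1)
  structure(list(chrom_lengths = chrom_lengths, snp_density = snp_density,
                 anc_het_fraction = anc_het_fraction,
                 het_block_bp = het_block_bp, csd = csd, meiosis = meiosis,
                 reads = reads, lines = lines,
                 colonies_per_line = as.integer(colonies_per_line),
                 offspring_per_colony = as.integer(offspring_per_colony)),
            class = "cohort_config")
}

#' Simulate a complete clonal cohort
#'
#' Draws a shared SNP panel, one founder per clonal line (planted CSD loci
#' forced heterozygous), colony mothers as diploid female daughters of the
#' founder, and per-colony offspring whose sexes emerge from the CSD model
#' applied to their simulated genotypes. Genotype calls with sequencing noise
#' are emitted for all colony members (mothers and offspring; line founders
#' themselves are not sequenced).
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed; all sub-streams derive from it.
#' @param out_dir Optional directory; when given, writes `cohort.vcf`,
#'   `meta.tsv`, `loh_tracts.tsv`, `planted_loci.tsv` and `config.txt`.
#' @return List with `geno` (long genotype tibble), `meta` (sample metadata),
#'   `truth` (list: `loh_tracts`, `planted_loci`, `individuals`), `founders`
#'   (per line), and `paths` (when written).
#' @export
simulate_cohort <- function(config, seed, out_dir = NULL) {
  panel <- simulate_founder(config$chrom_lengths, config$snp_density,
                            config$anc_het_fraction,
                            seed = derive_seed(seed, "panel"),
                            het_block_bp = config$het_block_bp,
                            force_het = config$csd$loci)
  founders <- list()
  individuals <- list()
  meta <- list()
  tracts <- list()
  for (line in config$lines) {
    fdr <- simulate_founder(config$chrom_lengths, config$snp_density,
                            config$anc_het_fraction,
                            seed = derive_seed(seed, paste0("founder:", line)),
                            het_block_bp = config$het_block_bp,
                            sites = panel$sites, force_het = config$csd$loci)
    founders[[line]] <- fdr
    founder_ind <- new_individual(fdr$h1, fdr$h2, 2L)
    for (ci in seq_len(config$colonies_per_line)) {
      colony <- sprintf("%s_c%d", line, ci)
      # colony mother: a diploid female daughter of the line founder
      mother <- NULL
      for (try in 1:100) {
        rs <- derive_seed(seed, sprintf("mother:%s:%d", colony, try))
        off <- reproduce_central_fusion(founder_ind, fdr, config$meiosis, rs)
        if (off$individual$ploidy == 2L &&
            assign_sex(off$individual, fdr, config$csd,
                       derive_seed(rs, "sex")) == "female") {
          mother <- off
          break
        }
      }
      if (is.null(mother)) abort("failed to draw a diploid female colony mother")
      mid <- paste0(colony, "_mother")
      individuals[[mid]] <- mother$individual
      meta[[mid]] <- tibble(sample_id = mid, sex = "female", ploidy = 2L,
                            colony = colony, clonal_line = line)
      if (nrow(mother$tracts)) {
        tracts[[mid]] <- mutate(mother$tracts, sample_id = mid)
      }
      for (oi in seq_len(config$offspring_per_colony)) {
        oid <- sprintf("%s_o%02d", colony, oi)
        rs <- derive_seed(seed, paste0("meiosis:", oid))
        off <- reproduce_central_fusion(mother$individual, fdr,
                                        config$meiosis, rs)
        sex <- assign_sex(off$individual, fdr, config$csd,
                          derive_seed(rs, "sex"))
        individuals[[oid]] <- off$individual
        meta[[oid]] <- tibble(sample_id = oid, sex = sex,
                              ploidy = off$individual$ploidy,
                              colony = colony, clonal_line = line)
        if (nrow(off$tracts)) {
          tracts[[oid]] <- mutate(off$tracts, sample_id = oid)
        }
      }
    }
  }
  meta <- bind_rows(meta)
  tracts <- if (length(tracts)) {
    bind_rows(tracts) %>%
      select("sample_id", "chrom", "start", "end", "maternal_hap")
  } else {
    tibble(sample_id = character(), chrom = character(), start = double(),
           end = double(), maternal_hap = integer())
  }
  geno <- emit_genotype_calls(individuals, panel, config$reads,
                              derive_seed(seed, "reads"))
  truth <- list(loh_tracts = tracts, planted_loci = config$csd$loci,
                individuals = individuals)
  out <- list(geno = geno, meta = meta, truth = truth, founders = founders,
              panel = panel)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- list(
      vcf = file.path(out_dir, "cohort.vcf"),
      meta = file.path(out_dir, "meta.tsv"),
      loh_tracts = file.path(out_dir, "loh_tracts.tsv"),
      planted_loci = file.path(out_dir, "planted_loci.tsv"),
      config = file.path(out_dir, "config.txt"))
    write_cohort_vcf(geno, meta, paths$vcf,
                     chrom_lengths = config$chrom_lengths)
    readr::write_tsv(meta, paths$meta)
    readr::write_tsv(
      mutate(tracts, allele = paste0("hap", .data$maternal_hap)) %>%
        select("sample_id", "chrom", "start", "end", "allele"),
      paths$loh_tracts)
    readr::write_tsv(config$csd$loci, paths$planted_loci)
    writeLines(config_echo(config, seed), paths$config)
    out$paths <- paths
  }
  out
}

config_echo <- function(config, seed) {
  c(sprintf("seed=%d", seed),
    sprintf("chrom_lengths=%s",
            paste(sprintf("%s:%g", names(config$chrom_lengths),
                          config$chrom_lengths), collapse = ",")),
    sprintf("snp_density=%g", config$snp_density),
    sprintf("anc_het_fraction=%g", config$anc_het_fraction),
    sprintf("het_block_bp=%g", config$het_block_bp %||% NA_real_),
    sprintf("csd_rule=%s", config$csd$rule),
    sprintf("csd_loci=%s",
            paste(sprintf("%s:%g-%g", config$csd$loci$chrom,
                          config$csd$loci$start, config$csd$loci$end),
                  collapse = ",")),
    sprintf("stochastic_male_rate=%g", config$csd$stochastic_male_rate),
    sprintf("crossover_rate=%g", config$meiosis$crossover_rate),
    sprintf("coinheritance_fidelity=%g", config$meiosis$coinheritance_fidelity),
    sprintf("haploid_male_rate=%g", config$meiosis$haploid_male_rate),
    sprintf("mean_depth=%g", config$reads$mean_depth),
    sprintf("depth_size=%g", config$reads$depth_size),
    sprintf("base_error=%g", config$reads$base_error),
    sprintf("lines=%s", paste(config$lines, collapse = ",")),
    sprintf("colonies_per_line=%d", config$colonies_per_line),
    sprintf("offspring_per_colony=%d", config$offspring_per_colony))
}
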