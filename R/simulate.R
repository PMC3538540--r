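# Forward Wright-Fisher simulation of breed demographies on a sparse
# regional SNP panel. The generator emulates the design the analysis
# pipeline assumes: ~10 independent 1-Mb chromosomal regions of ~150 SNPs
# each with density increased in the first 100 kb, two diverged ancestral
# pools (east/west), and per-breed founder bottleneck + expansion histories
# producing elevated LD in strongly bottlenecked breeds and low LD in
# random-bred populations. No mutation occurs during breed history: panel
# SNPs are treated as pre-ascertained array markers.

#' Simulation configuration
#'
#' @param seed integer seed; all outputs are pure functions of the
#'   configuration including this seed.
#' @param n_regions number of 1-Mb chromosomal regions (default 10; the
#'   first ten take the panel chromosome labels A1, A2, B3, C2, D1, D2, D4,
#'   E2, F2, X).
#' @param region_length_bp region length (default 1e6).
#' @param snps_per_region SNPs per region (default 150).
#' @param dense_snps SNPs of each region placed uniformly in the first
#'   `dense_end_bp` (default one third of `snps_per_region`, i.e. 50 of 150
#'   in the first 100 kb, for fine-scale LD estimation).
#' @param dense_end_bp length of the dense end (default 1e5).
#' @param recomb_rate recombination rate per bp per generation (default
#'   1e-8).
#' @param pool_size diploid size of each ancestral pool (default 100).
#' @param pool_generations generations of random mating with recombination
#'   after linkage-equilibrium assembly of the pools (default 50;
#'   accumulates realistic background LD).
#' @param split_F drift parameter separating the two ancestral pools: pool 2
#'   allele frequencies are pool 1 frequencies perturbed with variance
#'   `split_F * p(1-p)` (default 0.15).
#' @param missing_rate genotype missingness applied to emitted calls
#'   (default 0.03).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_regions = 10L, region_length_bp = 1e6,
                       snps_per_region = 150L,
                       dense_snps = max(1L, snps_per_region %/% 3L),
                       dense_end_bp = 1e5, recomb_rate = 1e-8,
                       pool_size = 100L, pool_generations = 50L,
                       split_F = 0.15, missing_rate = 0.03) {
  cfg <- list(seed = as.integer(seed), n_regions = as.integer(n_regions),
              region_length_bp = region_length_bp,
              snps_per_region = as.integer(snps_per_region),
              dense_snps = as.integer(dense_snps),
              dense_end_bp = dense_end_bp, recomb_rate = recomb_rate,
              pool_size = as.integer(pool_size),
              pool_generations = as.integer(pool_generations),
              split_F = split_F, missing_rate = missing_rate)
  stopifnot(cfg$n_regions >= 1, cfg$snps_per_region >= 2,
            cfg$dense_snps <= cfg$snps_per_region,
            cfg$dense_end_bp < cfg$region_length_bp,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$split_F >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Per-breed demography configuration
#'
#' @param name population label.
#' @param pool ancestral pool, `"east"` or `"west"`.
#' @param founder_count diploid founders drawn from the pool.
#' @param bottleneck_Ne,bottleneck_generations diploid size and duration of
#'   the founding bottleneck.
#' @param expansion_Ne diploid size after expansion.
#' @param total_generations total generations from founding to sampling.
#' @param sample_n diploid individuals sampled (must not exceed
#'   `expansion_Ne`).
#' @return list of class `breed_config`.
#' @export
breed_config <- function(name, pool = "west", founder_count = 15L,
                         bottleneck_Ne = 15L, bottleneck_generations = 8L,
                         expansion_Ne = 100L, total_generations = 40L,
                         sample_n = 20L) {
  stopifnot(founder_count >= 1, bottleneck_Ne >= 1, expansion_Ne >= 1,
            bottleneck_generations >= 0,
            total_generations >= bottleneck_generations,
            sample_n <= expansion_Ne)
  structure(list(name = name, pool = pool,
                 founder_count = as.integer(founder_count),
                 bottleneck_Ne = as.integer(bottleneck_Ne),
                 bottleneck_generations = as.integer(bottleneck_generations),
                 expansion_Ne = as.integer(expansion_Ne),
                 total_generations = as.integer(total_generations),
                 sample_n = as.integer(sample_n)),
            class = "breed_config")
}

PANEL_CHROMS <- c("A1", "A2", "B3", "C2", "D1", "D2", "D4", "E2", "F2", "X")

#' Build the SNP map
#'
#' Deterministic given the configuration seed: per region, `dense_snps`
#' positions uniform over the first `dense_end_bp` and the remainder uniform
#' over the rest, made unique and strictly increasing.
#'
#' @param cfg a [sim_config()].
#' @return data.frame `snp_id`, `chromosome`, `region`, `position_bp`.
#' @export
build_snp_map <- function(cfg) {
  if (cfg$snps_per_region > 0.5 * cfg$region_length_bp)
    stop("infeasible SNP density for region length")
  chroms <- if (cfg$n_regions <= length(PANEL_CHROMS))
    PANEL_CHROMS[seq_len(cfg$n_regions)]
  else paste0("C", seq_len(cfg$n_regions))
  with_seed(derive_seed(cfg$seed, 1L), {
    maps <- lapply(seq_len(cfg$n_regions), function(r) {
      n_rest <- cfg$snps_per_region - cfg$dense_snps
      repeat {
        pos <- c(sample.int(cfg$dense_end_bp, cfg$dense_snps),
                 if (n_rest > 0)
                   cfg$dense_end_bp +
                     sample.int(cfg$region_length_bp - cfg$dense_end_bp, n_rest))
        if (!anyDuplicated(pos)) break
      }
      pos <- sort(pos)
      data.frame(
        snp_id = sprintf("%s_%07d", chroms[r], pos),
        chromosome = chroms[r], region = chroms[r],
        position_bp = as.integer(pos), stringsAsFactors = FALSE)
    })
    do.call(rbind, maps)
  })
}

# One Wright-Fisher generation. state: list over regions of haplotype
# matrices (2N x m, rows 2i-1, 2i = individual i). Regions share the
# parental pedigree (independent assortment); crossover counts are
# Poisson(recomb_rate * region_length) with uniform breakpoints. Most
# gametes carry zero crossovers at 1 Mb scale, so recombinants are patched
# individually while the rest is a single matrix row-copy.
.wf_generation <- function(state, n_offspring, positions, region_length,
                           recomb_rate) {
  n_parents <- nrow(state[[1]]) / 2L
  mothers <- sample.int(n_parents, n_offspring, replace = TRUE)
  fathers <- sample.int(n_parents, n_offspring, replace = TRUE)
  parent_of_gamete <- as.vector(rbind(mothers, fathers))  # 2 per offspring
  lapply(seq_along(state), function(r) {
    H <- state[[r]]
    m <- ncol(H)
    n_gam <- 2L * n_offspring
    start_hap <- sample.int(2L, n_gam, replace = TRUE)  # 1 or 2
    n_x <- rpois(n_gam, recomb_rate * region_length)
    rows <- 2L * (parent_of_gamete - 1L) + start_hap
    G <- H[rows, , drop = FALSE]
    for (g in which(n_x > 0)) {
      bp <- sort(runif(n_x[g], 0, region_length))
      seg <- findInterval(positions[[r]], bp)  # segment index per SNP
      use_other <- seg %% 2L == 1L
      other_row <- 2L * (parent_of_gamete[g] - 1L) + (3L - start_hap[g])
      G[g, use_other] <- H[other_row, use_other]
    }
    G
  })
}

#' Simulate the two diverged ancestral pools
#'
#' Pool 1 per-SNP frequencies are Beta(0.5, 0.5) truncated to
#' \[0.05, 0.95\]; pool 2 frequencies are a drift perturbation with variance
#' `split_F * p(1-p)`, truncated to \[0.01, 0.99\]. Haplotypes are assembled
#' at linkage equilibrium and then evolved `pool_generations` generations of
#' random mating with recombination to accumulate background LD.
#'
#' @param cfg a [sim_config()].
#' @param map SNP map from [build_snp_map()] (rebuilt from `cfg` when NULL).
#' @return list with `pools` (named list `east`/`west` of per-region
#'   haplotype matrices), `freqs` (per-SNP frequencies per pool), `map`.
#' @export
simulate_ancestral <- function(cfg, map = NULL) {
  map <- map %||% build_snp_map(cfg)
  regions <- unique(map$region)
  positions <- lapply(regions, function(r) map$position_bp[map$region == r])
  with_seed(derive_seed(cfg$seed, 2L), {
    m_tot <- nrow(map)
    p1 <- rbeta(m_tot, 0.5, 0.5)
    p1 <- pmin(0.95, pmax(0.05, p1))
    p2 <- p1 + rnorm(m_tot, 0, sqrt(cfg$split_F * p1 * (1 - p1)))
    p2 <- pmin(0.99, pmax(0.01, p2))
    if (cfg$split_F == 0) p2 <- p1
    build_pool <- function(p) {
      state <- lapply(seq_along(regions), function(ri) {
        idx <- which(map$region == regions[ri])
        h <- matrix(rbinom(2L * cfg$pool_size * length(idx), 1L,
                           rep(p[idx], each = 2L * cfg$pool_size)),
                    nrow = 2L * cfg$pool_size)
        h
      })
      for (g in seq_len(cfg$pool_generations))
        state <- .wf_generation(state, cfg$pool_size, positions,
                                cfg$region_length_bp, cfg$recomb_rate)
      state
    }
    pools <- list(east = build_pool(p1), west = build_pool(p2))
    list(pools = pools, freqs = list(east = p1, west = p2), map = map)
  })
}

#' Found and sample one breed
#'
#' Draws `founder_count` diploid founders from an ancestral pool, runs a
#' forward Wright-Fisher history (bottleneck then expansion, recombination,
#' no mutation), samples `sample_n` diploids, and emits unphased genotype
#' codes plus the phased truth haplotypes (recorded before missingness is
#' applied).
#'
#' @param pool per-region haplotype matrices (one element of
#'   `simulate_ancestral(cfg)$pools`).
#' @param bcfg a [breed_config()].
#' @param cfg a [sim_config()].
#' @param map SNP map matching `pool`.
#' @param seed integer seed for this breed's history.
#' @return list with `genotypes` (samples x SNPs codes, `NA` = missing),
#'   `truth` (list of per-region phased haplotype matrices, rows 2i-1/2i =
#'   sample i), `sample_ids`.
#' @export
found_breed <- function(pool, bcfg, cfg, map, seed = cfg$seed) {
  regions <- unique(map$region)
  positions <- lapply(regions, function(r) map$position_bp[map$region == r])
  if (2L * bcfg$founder_count > nrow(pool[[1]]))
    stop("founder_count exceeds pool size")
  with_seed(seed, {
    founders <- sample.int(nrow(pool[[1]]) / 2L, bcfg$founder_count)
    rows <- as.vector(rbind(2L * founders - 1L, 2L * founders))
    state <- lapply(pool, function(H) H[rows, , drop = FALSE])
    for (g in seq_len(bcfg$total_generations)) {
      ne <- if (g <= bcfg$bottleneck_generations) bcfg$bottleneck_Ne
            else bcfg$expansion_Ne
      state <- .wf_generation(state, ne, positions, cfg$region_length_bp,
                              cfg$recomb_rate)
    }
    n_final <- nrow(state[[1]]) / 2L
    take <- sort(sample.int(n_final, bcfg$sample_n))
    rows <- as.vector(rbind(2L * take - 1L, 2L * take))
    truth <- lapply(state, function(H) H[rows, , drop = FALSE])
    geno <- do.call(cbind, lapply(truth, function(H) {
      H[seq(1, nrow(H), 2), , drop = FALSE] +
        H[seq(2, nrow(H), 2), , drop = FALSE]
    }))
    colnames(geno) <- map$snp_id
    sample_ids <- sprintf("%s_%03d", bcfg$name, seq_len(bcfg$sample_n))
    rownames(geno) <- sample_ids
    if (cfg$missing_rate > 0) {
      miss <- matrix(runif(length(geno)) < cfg$missing_rate, nrow(geno))
      geno[miss] <- NA_integer_
    }
    list(genotypes = geno, truth = truth, sample_ids = sample_ids)
  })
}

#' Roster of the emulated study panel
#'
#' The 23 genotyped populations of the emulated design (18 breeds, three of
#' them sampled as domestic/foreign pairs, plus an eastern and a western
#' random-bred population) with their sample sizes (total 408), ancestral
#' pool assignment, and a qualitative LD class driving the demography
#' presets: `strong` (few founders, tight bottleneck: long LD), `moderate`,
#' or `weak` (many founders / random-bred-like: short LD). The combined
#' random-bred population (`RB` = eastern + western) is derived, not
#' simulated.
#'
#' @return data.frame with `population`, `n`, `pool`, `ld_class`.
#' @export
cat_panel_roster <- function() {
  df <- read.delim(text =
"population\tn\tpool\tld_class
ABY\t21\twest\tmoderate
ANG\t14\twest\tweak
BIR\t20\teast\tstrong
BURD\t19\teast\tstrong
BURF\t19\teast\tstrong
CHA\t8\twest\tmoderate
COR\t21\twest\tmoderate
EGY\t9\teast\tmoderate
JAP\t12\twest\tweak
KORD\t19\teast\tmoderate
KORF\t17\teast\tmoderate
MAIN\t19\twest\tstrong
MANX\t20\twest\tweak
NFC\t20\twest\tmoderate
OCI\t21\teast\tmoderate
PER\t19\twest\tmoderate
RUS\t18\twest\tmoderate
SIA\t19\teast\tstrong
SIB\t19\twest\tweak
VAND\t19\teast\tmoderate
VANF\t12\teast\tmoderate
ERB\t22\teast\tweak
WRB\t21\twest\tweak", stringsAsFactors = FALSE)
  df
}

.preset_breed <- function(population, n, pool, ld_class) {
  par <- switch(ld_class,
    strong = list(founder_count = 6L, bottleneck_Ne = 6L, expansion_Ne = 80L),
    moderate = list(founder_count = 15L, bottleneck_Ne = 15L,
                    expansion_Ne = 100L),
    weak = list(founder_count = 60L, bottleneck_Ne = 60L, expansion_Ne = 150L),
    stop("unknown ld_class: ", ld_class))
  breed_config(population, pool = pool,
               founder_count = par$founder_count,
               bottleneck_Ne = par$bottleneck_Ne,
               bottleneck_generations = 8L,
               expansion_Ne = par$expansion_Ne,
               total_generations = 40L,
               sample_n = as.integer(n))
}

#' Generate the emulated study panel
#'
#' Builds every roster population from the two ancestral pools with its
#' preset demography and returns one multi-population dataset, optionally
#' writing VCF + popmap + SNP map + truth TSVs.
#'
#' @param cfg a [sim_config()].
#' @param roster data.frame as from [cat_panel_roster()] (subset it for
#'   scaled-down runs).
#' @param out_dir optional output directory for `genotypes.vcf`,
#'   `popmap.tsv`, `snp_map.tsv`, `truth.tsv`.
#' @return A [genotype_dataset()] with a `truth` attribute (named list per
#'   population of per-region phased haplotype matrices).
#' @export
emulate_study <- function(cfg = sim_config(), roster = cat_panel_roster(),
                          out_dir = NULL) {
  anc <- simulate_ancestral(cfg)
  map <- anc$map
  calls <- list(); samples <- list(); truth <- list()
  for (i in seq_len(nrow(roster))) {
    bcfg <- .preset_breed(roster$population[i], roster$n[i],
                          roster$pool[i], roster$ld_class[i])
    res <- found_breed(anc$pools[[roster$pool[i]]], bcfg, cfg, map,
                       seed = derive_seed(cfg$seed, 100L + i))
    calls[[i]] <- res$genotypes
    samples[[i]] <- data.frame(sample_id = res$sample_ids,
                               population = roster$population[i],
                               stringsAsFactors = FALSE)
    truth[[roster$population[i]]] <- res$truth
  }
  ds <- genotype_dataset(do.call(rbind, calls), do.call(rbind, samples), map)
  attr(ds, "truth") <- truth
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genotypes_vcf(ds, file.path(out_dir, "genotypes.vcf"))
    write_tsv(ds$samples, file.path(out_dir, "popmap.tsv"))
    write_tsv(ds$snps, file.path(out_dir, "snp_map.tsv"))
    write_truth_tsv(truth, map, file.path(out_dir, "truth.tsv"))
  }
  ds
}

#' Combine populations under a new label
#'
#' Used e.g. to form the combined random-bred population from its eastern
#' and western components.
#'
#' @param ds a [genotype_dataset()].
#' @param members population labels to merge.
#' @param label new label.
#' @return `genotype_dataset` holding only the merged samples.
#' @export
combine_populations <- function(ds, members, label) {
  keep <- ds$samples$population %in% members
  if (!any(keep)) stop("no samples in: ", paste(members, collapse = ", "))
  s <- ds$samples[keep, , drop = FALSE]
  s$population <- label
  genotype_dataset(ds$calls[keep, , drop = FALSE], s, ds$snps)
}

# Truth haplotypes as TSV: sample, haplotype_index (1/2), region, allele
# string.
write_truth_tsv <- function(truth, map, path) {
  rows <- list()
  for (popname in names(truth)) {
    regs <- unique(map$region)
    for (ri in seq_along(regs)) {
      H <- truth[[popname]][[ri]]
      n <- nrow(H) / 2L
      for (i in seq_len(n)) for (h in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sprintf("%s_%03d", popname, i),
          haplotype_index = h, region = regs[ri],
          alleles = paste(H[2L * (i - 1L) + h, ], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  write_tsv(do.call(rbind, rows), path)
}
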