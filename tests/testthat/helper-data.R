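# Shared fixture builders and independent oracles.

# Minimal dataset from a calls matrix (samples x snps), one chromosome by
# default; positions 1000, 2000, ...
toy_ds <- function(calls, populations = NULL, chromosome = NULL,
                   positions = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  populations <- populations %||% rep("P1", n)
  chromosome <- chromosome %||% rep("c1", m)
  positions <- positions %||% (seq_len(m) * 1000L)
  genotype_dataset(
    calls,
    data.frame(sample_id = sprintf("s%02d", seq_len(n)),
               population = populations, stringsAsFactors = FALSE),
    data.frame(snp_id = sprintf("snp%02d", seq_len(m)),
               chromosome = chromosome, region = chromosome,
               position_bp = positions, stringsAsFactors = FALSE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# ---- independent two-locus EM oracle -------------------------------------
# Multinomial log-likelihood of a 3x3 genotype table under HWE given the
# four haplotype frequencies (computed from first principles, not via the
# package's internals).
oracle_loglik <- function(counts, fAB, fAb, faB, fab) {
  # counts[i+1, j+1]: alt dosage i at locus A, j at locus B; fAB refers to
  # the REF-REF haplotype, matching two_locus_em()'s labeling.
  p <- matrix(0, 3, 3)
  p[1, 1] <- fAB^2;        p[1, 2] <- 2 * fAB * fAb;  p[1, 3] <- fAb^2
  p[2, 1] <- 2 * fAB * faB
  p[2, 2] <- 2 * (fAB * fab + fAb * faB)
  p[2, 3] <- 2 * fAb * fab
  p[3, 1] <- faB^2;        p[3, 2] <- 2 * faB * fab;  p[3, 3] <- fab^2
  sum(ifelse(counts > 0,
             ifelse(p > 0, counts * log(pmax(p, 1e-300)), -Inf), 0))
}

# Grid search over the single free phase parameter: marginal allele
# frequencies are fixed at their observed values (a property of the MLE),
# leaving fAB free within its Frechet bounds. Returns the best grid point
# and all near-ties.
em_grid_oracle <- function(counts, step = 1e-3) {
  n2 <- 2 * sum(counts)
  # observed REF allele frequencies
  pA <- sum((2 - (row(counts) - 1)) * counts) / n2
  pB <- sum((2 - (col(counts) - 1)) * counts) / n2
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  ll <- vapply(grid, function(fAB)
    oracle_loglik(counts, fAB, max(0, pA - fAB), max(0, pB - fAB),
                  max(0, 1 - pA - pB + fAB)),
    numeric(1))
  best <- max(ll)
  ties <- grid[ll >= best - 1e-9]
  list(fAB = grid[which.max(ll)], loglik = best, tied_fAB = ties,
       pA = pA, pB = pB)
}

# Random 3x3 genotype table with both loci polymorphic.
random_geno_table <- function(max_total = 40) {
  repeat {
    tot <- sample(4:max_total, 1)
    pA <- runif(1, 0.1, 0.9); pB <- runif(1, 0.1, 0.9)
    d <- runif(1, -0.5, 0.5) *
      (min(pA, pB) - max(0, pA + pB - 1)) + max(0, pA + pB - 1)
    f <- c(d, pA - d, pB - d, 1 - pA - pB + d)
    if (any(f < 0)) next
    hap <- sample(1:4, 2 * tot, replace = TRUE, prob = f)
    alt_a <- as.integer(hap %in% c(3, 4))  # f order: AB, Ab, aB, ab
    alt_b <- as.integer(hap %in% c(2, 4))
    ga <- alt_a[seq(1, 2 * tot, 2)] + alt_a[seq(2, 2 * tot, 2)]
    gb <- alt_b[seq(1, 2 * tot, 2)] + alt_b[seq(2, 2 * tot, 2)]
    counts <- table(factor(ga, 0:2), factor(gb, 0:2))
    counts <- matrix(as.numeric(counts), 3, 3)
    n2 <- 2 * sum(counts)
    pa <- sum((row(counts) - 1) * counts) / n2
    pb <- sum((col(counts) - 1) * counts) / n2
    if (pa > 0 && pa < 1 && pb > 0 && pb < 1) return(counts)
  }
}

# ---- brute-force solid-spine oracle --------------------------------------
# All valid intervals by direct evaluation of the two-sided definition,
# then the same left-to-right longest-first selection.
spine_oracle <- function(D, threshold = 0.8) {
  m <- nrow(D)
  ok <- function(x) !is.na(x) & x >= threshold
  valid <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) if (j > i) {
    c1 <- all(ok(D[i, (i + 1):j]))
    c2 <- all(ok(D[i:(j - 1), j]))
    valid[i, j] <- c1 && c2
  }
  blocks <- list()
  i <- 1L
  while (i < m) {
    js <- which(valid[i, ])
    if (length(js)) {
      j <- max(js)
      blocks[[length(blocks) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(blocks)) return(data.frame(first = integer(), last = integer()))
  b <- do.call(rbind, blocks)
  data.frame(first = b[, 1], last = b[, 2])
}

random_dprime_matrix <- function(m) {
  D <- matrix(runif(m * m), m, m)
  D[sample(length(D), size = round(0.05 * length(D)))] <- NA
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  diag(D) <- 1
  D
}

# Small simulated single-population dataset with phased truth.
sim_population <- function(seed, ld_class = "moderate", n_regions = 2,
                           snps_per_region = 40, sample_n = 20,
                           missing_rate = 0.02, pool = "west", bcfg = NULL) {
  cfg <- sim_config(seed = seed, n_regions = n_regions,
                    snps_per_region = snps_per_region,
                    dense_snps = min(10, snps_per_region),
                    pool_size = 80, pool_generations = 30,
                    missing_rate = missing_rate)
  anc <- simulate_ancestral(cfg)
  bcfg <- bcfg %||% popld:::.preset_breed("POP", sample_n, pool, ld_class)
  res <- found_breed(anc$pools[[pool]], bcfg, cfg, anc$map, seed = seed + 7)
  ds <- genotype_dataset(res$genotypes,
                         data.frame(sample_id = res$sample_ids,
                                    population = bcfg$name),
                         anc$map)
  list(ds = ds, truth = res$truth, map = anc$map, cfg = cfg, anc = anc)
}
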