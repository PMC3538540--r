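# Two-locus LD from unphased genotypes.
#
# The estimator is the standard composite of direct haplotype counting plus
# EM over the phase-ambiguous double-heterozygote cell: every genotype class
# except (het, het) determines its two haplotypes, and the double
# heterozygotes are split between coupling (AB/ab) and repulsion (Ab/aB)
# according to their expected posterior under the current frequency
# estimates, iterated to convergence. The engine below is vectorized over
# SNP pairs: each pair is one row of 3x3 genotype cell counts.

# Column order of the 9 genotype cells: (i, j) = (alt dosage at locus A,
# alt dosage at locus B), row-major: 00 01 02 10 11 12 20 21 22.
CELLS9 <- c("g00", "g01", "g02", "g10", "g11", "g12", "g20", "g21", "g22")

# Known (phase-unambiguous) haplotype counts per pair, and the double-het
# count. x11 = frequency of the alt-alt haplotype, x10 alt at A only, etc.
.known_counts <- function(N) {
  list(
    k00 = 2 * N[, 1] + N[, 2] + N[, 4],
    k01 = N[, 2] + 2 * N[, 3] + N[, 6],
    k10 = N[, 4] + 2 * N[, 7] + N[, 8],
    k11 = N[, 6] + N[, 8] + 2 * N[, 9],
    nDH = N[, 5],
    tot2 = 2 * rowSums(N))
}

.em_loglik <- function(N, x00, x01, x10, x11) {
  probs <- cbind(x00^2, 2 * x00 * x01, x01^2,
                 2 * x00 * x10, 2 * (x11 * x00 + x10 * x01), 2 * x01 * x11,
                 x10^2, 2 * x10 * x11, x11^2)
  rowSums(ifelse(N > 0, ifelse(probs > 0, N * log(probs), -Inf), 0))
}

# One EM run from a given double-het coupling split, vectorized over pairs.
.em_run <- function(kc, init_pc, tol = 1e-10, max_iter = 10000L) {
  x00 <- (kc$k00 + init_pc * kc$nDH) / kc$tot2
  x11 <- (kc$k11 + init_pc * kc$nDH) / kc$tot2
  x01 <- (kc$k01 + (1 - init_pc) * kc$nDH) / kc$tot2
  x10 <- (kc$k10 + (1 - init_pc) * kc$nDH) / kc$tot2
  iter <- 0L
  converged <- rep(FALSE, length(x00))
  repeat {
    iter <- iter + 1L
    num <- x11 * x00
    den <- num + x10 * x01
    pc <- ifelse(den > 0, num / den, 0.5)
    n00 <- (kc$k00 + pc * kc$nDH) / kc$tot2
    n11 <- (kc$k11 + pc * kc$nDH) / kc$tot2
    n01 <- (kc$k01 + (1 - pc) * kc$nDH) / kc$tot2
    n10 <- (kc$k10 + (1 - pc) * kc$nDH) / kc$tot2
    delta <- pmax(abs(n00 - x00), abs(n01 - x01),
                  abs(n10 - x10), abs(n11 - x11))
    x00 <- n00; x01 <- n01; x10 <- n10; x11 <- n11
    if (all(delta < tol)) { converged[] <- TRUE; break }
    if (iter >= max_iter) { converged <- delta < tol; break }
  }
  list(x00 = x00, x01 = x01, x10 = x10, x11 = x11,
       n_iter = iter, converged = converged)
}

# Full estimator with three starts (linkage-equilibrium-like 50/50 split,
# coupling-biased, repulsion-biased) and per-pair best-likelihood selection;
# ties go to the earlier start.
em_engine <- function(N, tol = 1e-10, max_iter = 10000L) {
  N <- matrix(as.numeric(N), ncol = 9)
  kc <- .known_counts(N)
  best <- NULL
  best_ll <- rep(-Inf, nrow(N))
  n_iter <- rep(0L, nrow(N))
  for (pc0 in c(0.5, 0.9, 0.1)) {
    run <- .em_run(kc, pc0, tol, max_iter)
    ll <- .em_loglik(N, run$x00, run$x01, run$x10, run$x11)
    take <- ll > best_ll + 1e-12
    if (is.null(best)) { best <- run; best_ll <- ll; n_iter <- rep(run$n_iter, nrow(N)) }
    else if (any(take)) {
      for (f in c("x00", "x01", "x10", "x11", "converged"))
        best[[f]][take] <- run[[f]][take]
      best_ll[take] <- ll[take]
      n_iter[take] <- run$n_iter
    }
  }
  pA <- best$x10 + best$x11
  pB <- best$x01 + best$x11
  degenerate <- kc$nDH == rowSums(N) & rowSums(N) > 0
  list(x00 = best$x00, x01 = best$x01, x10 = best$x10, x11 = best$x11,
       pA_alt = pA, pB_alt = pB, loglik = best_ll,
       n_iter = n_iter, converged = best$converged, degenerate = degenerate,
       n_used = rowSums(N))
}

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic loci from
#' a 3x3 table of joint unphased genotype counts, assuming random mating.
#' Only the double-heterozygote cell is phase-ambiguous; it is split by EM.
#' Three starts (50/50, coupling-biased 0.9, repulsion-biased 0.1) are run
#' and the best-likelihood solution kept, so phase-uninformative tables
#' resolve to a maximum rather than the symmetric saddle point.
#'
#' @param counts 3x3 matrix: `counts[i+1, j+1]` is the number of individuals
#'   with alt dosage `i` at locus A and `j` at locus B.
#' @param tol convergence tolerance on the max frequency change.
#' @param max_iter iteration cap.
#' @return Object of class `hap_freqs2` with fields `f_AB`, `f_Ab`, `f_aB`,
#'   `f_ab` (A/B = reference alleles), `loglik`, `n_iter`, `converged`,
#'   `degenerate` (no phase-informative genotypes), and `loglik_trace`.
#' @export
two_locus_em <- function(counts, tol = 1e-10, max_iter = 10000L) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0), sum(counts) >= 1)
  N <- matrix(as.numeric(t(counts)), nrow = 1)
  kc <- .known_counts(N)
  pA <- (kc$k10 + kc$k11 + kc$nDH) / kc$tot2
  pB <- (kc$k01 + kc$k11 + kc$nDH) / kc$tot2
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("undefined LD: monomorphic locus in the genotype table")
  fit <- em_engine(N, tol, max_iter)
  trace <- .em_trace(N, tol, max_iter)
  structure(list(
    f_AB = fit$x00, f_Ab = fit$x01, f_aB = fit$x10, f_ab = fit$x11,
    p_A = 1 - fit$pA_alt, p_B = 1 - fit$pB_alt,
    loglik = fit$loglik, n_iter = fit$n_iter,
    converged = fit$converged, degenerate = fit$degenerate,
    loglik_trace = trace), class = "hap_freqs2")
}

# Log-likelihood trace of the winning start (re-run iteration by iteration);
# used to verify EM monotonicity.
.em_trace <- function(N, tol, max_iter) {
  kc <- .known_counts(N)
  best_pc0 <- 0.5; best_ll <- -Inf
  for (pc0 in c(0.5, 0.9, 0.1)) {
    run <- .em_run(kc, pc0, tol, max_iter)
    ll <- .em_loglik(N, run$x00, run$x01, run$x10, run$x11)
    if (ll > best_ll + 1e-12) { best_ll <- ll; best_pc0 <- pc0 }
  }
  x00 <- (kc$k00 + best_pc0 * kc$nDH) / kc$tot2
  x11 <- (kc$k11 + best_pc0 * kc$nDH) / kc$tot2
  x01 <- (kc$k01 + (1 - best_pc0) * kc$nDH) / kc$tot2
  x10 <- (kc$k10 + (1 - best_pc0) * kc$nDH) / kc$tot2
  trace <- .em_loglik(N, x00, x01, x10, x11)
  for (it in seq_len(max_iter)) {
    num <- x11 * x00; den <- num + x10 * x01
    pc <- ifelse(den > 0, num / den, 0.5)
    n00 <- (kc$k00 + pc * kc$nDH) / kc$tot2
    n11 <- (kc$k11 + pc * kc$nDH) / kc$tot2
    n01 <- (kc$k01 + (1 - pc) * kc$nDH) / kc$tot2
    n10 <- (kc$k10 + (1 - pc) * kc$nDH) / kc$tot2
    delta <- max(abs(n00 - x00), abs(n01 - x01), abs(n10 - x10), abs(n11 - x11))
    x00 <- n00; x01 <- n01; x10 <- n10; x11 <- n11
    trace <- c(trace, .em_loglik(N, x00, x01, x10, x11))
    if (delta < tol) break
  }
  trace
}

#' LD coefficients from two-locus haplotype frequencies
#'
#' `D = f_AB - p_A * p_B`; `r2 = D^2 / (p_A(1-p_A) p_B(1-p_B))`;
#' `|D'| = |D| / D_max` with `D_max = min(p_A(1-p_B), (1-p_A)p_B)` when
#' `D > 0` and `min(p_A p_B, (1-p_A)(1-p_B))` when `D < 0`; `D = 0` gives
#' `|D'| = 0`.
#'
#' @param h a `hap_freqs2` from [two_locus_em()], or a numeric vector of the
#'   four haplotype frequencies `(f_AB, f_Ab, f_aB, f_ab)`.
#' @return list with `D`, `abs_dprime`, `r2`.
#' @export
ld_measures <- function(h) {
  if (inherits(h, "hap_freqs2")) f <- c(h$f_AB, h$f_Ab, h$f_aB, h$f_ab)
  else f <- as.numeric(h)
  stopifnot(length(f) == 4, abs(sum(f) - 1) < 1e-6)
  pA <- f[1] + f[2]  # reference allele at locus A
  pB <- f[1] + f[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("undefined LD: monomorphic marginal")
  m <- .ld_from_freqs(f[4] + f[3], f[4] + f[2], f[4])  # alt-based, same D
  list(D = m$D, abs_dprime = m$abs_dprime, r2 = m$r2)
}

# Vectorized alt-allele-based LD measures: pA, pB alt freqs, x11 alt-alt
# haplotype frequency. D is labeling-invariant; D_11 = D_00.
.ld_from_freqs <- function(pA, pB, x11) {
  D <- x11 - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- ifelse(denom > 0, D^2 / denom, NA_real_)
  dmax <- ifelse(D > 0, pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  abs_dprime <- ifelse(D == 0, 0, abs(D) / dmax)
  list(D = D, r2 = r2, abs_dprime = abs_dprime)
}

# 9-column pair cell counts for all pairs between SNP index sets ia and ib of
# the calls matrix (ia == ib gives the upper triangle of intra pairs).
# Returns list(N = npairs x 9, a = snp index, b = snp index).
.pair_counts <- function(calls, ia, ib = NULL) {
  intra <- is.null(ib)
  if (intra) ib <- ia
  Ia <- lapply(0:2, function(v) {
    m <- calls[, ia, drop = FALSE] == v
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  })
  Ib <- if (intra) Ia else lapply(0:2, function(v) {
    m <- calls[, ib, drop = FALSE] == v
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  })
  if (intra) {
    na <- length(ia)
    sel <- which(upper.tri(matrix(0, na, na)))
    ai <- row(matrix(0, na, na))[sel]; bi <- col(matrix(0, na, na))[sel]
  } else {
    na <- length(ia); nb <- length(ib)
    ai <- rep(seq_len(na), times = nb)
    bi <- rep(seq_len(nb), each = na)
    sel <- NULL
  }
  cols <- vector("list", 9)
  k <- 0
  for (i in 0:2) for (j in 0:2) {
    k <- k + 1
    cp <- crossprod(Ia[[i + 1]], Ib[[j + 1]])
    cols[[k]] <- if (intra) cp[sel] else as.vector(cp)
  }
  N <- do.call(cbind, cols)
  colnames(N) <- CELLS9
  list(N = N, a = ia[ai], b = ib[bi])
}

#' Pairwise LD table for one population
#'
#' Computes r-squared and |D'| for every unordered pair of SNPs on the same
#' chromosome, from pairwise-complete individuals (both calls non-missing).
#' Pairs whose pairwise-complete subset leaves a locus monomorphic are
#' dropped and counted in the `n_dropped_monomorphic` attribute.
#'
#' @param ds a QC-passed [genotype_dataset()] restricted to one population.
#' @return data.frame of class `ld_table` with columns `snp_a`, `snp_b`,
#'   `chrom`, `distance_bp`, `n_used`, `r2`, `abs_dprime`,
#'   `inter_chromosome` (all `FALSE`); attribute `n_dropped_monomorphic`.
#' @export
pairwise_ld_region <- function(ds) {
  if (length(unique(ds$samples$population)) != 1)
    warning("dataset spans multiple populations; LD is intended per population")
  chroms <- unique(ds$snps$chromosome)
  out <- list()
  dropped <- 0L
  for (chr in chroms) {
    idx <- which(ds$snps$chromosome == chr)
    if (length(idx) < 2) next
    pc <- .pair_counts(ds$calls, idx)
    fit <- em_engine(pc$N)
    mono <- fit$pA_alt <= 0 | fit$pA_alt >= 1 | fit$pB_alt <= 0 |
      fit$pB_alt >= 1 | fit$n_used == 0
    dropped <- dropped + sum(mono)
    if (all(mono)) next
    m <- .ld_from_freqs(fit$pA_alt[!mono], fit$pB_alt[!mono], fit$x11[!mono])
    out[[chr]] <- data.frame(
      snp_a = ds$snps$snp_id[pc$a[!mono]],
      snp_b = ds$snps$snp_id[pc$b[!mono]],
      chrom = chr,
      distance_bp = abs(ds$snps$position_bp[pc$a[!mono]] -
                          ds$snps$position_bp[pc$b[!mono]]),
      n_used = fit$n_used[!mono],
      r2 = m$r2,
      abs_dprime = m$abs_dprime,
      inter_chromosome = FALSE,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    warning("fewer than 2 usable SNPs on every chromosome: empty LD table")
    tab <- data.frame(snp_a = character(), snp_b = character(),
                      chrom = character(), distance_bp = integer(),
                      n_used = integer(), r2 = numeric(),
                      abs_dprime = numeric(), inter_chromosome = logical(),
                      stringsAsFactors = FALSE)
  } else tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "n_dropped_monomorphic") <- dropped
  class(tab) <- c("ld_table", "data.frame")
  tab
}

#' Background (inter-chromosomal) LD
#'
#' Mean r-squared over all SNP pairs on different chromosomes — an empirical
#' null for unlinked loci. SNPs are first filtered to within-population
#' `MAF >= maf_min` (default 0.1) among called genotypes.
#'
#' @param ds population [genotype_dataset()] (post call-rate QC).
#' @param maf_min MAF cutoff applied before pairing.
#' @return list with `mean_r2`, `n_pairs` and `n_dropped_monomorphic`.
#' @export
background_ld <- function(ds, maf_min = 0.1) {
  n_called <- colSums(!is.na(ds$calls))
  p <- colSums(ds$calls, na.rm = TRUE) / pmax(1, 2 * n_called)
  maf <- pmin(p, 1 - p)
  keep <- n_called > 0 & maf >= maf_min & maf > 0
  ds2 <- subset_snps(ds, which(keep))
  chroms <- unique(ds2$snps$chromosome)
  if (length(chroms) < 2)
    stop("background LD needs SNPs on at least two chromosomes")
  sum_r2 <- 0; n_pairs <- 0L; dropped <- 0L
  for (i in seq_along(chroms)[-length(chroms)]) for (j in (i + 1):length(chroms)) {
    ia <- which(ds2$snps$chromosome == chroms[i])
    ib <- which(ds2$snps$chromosome == chroms[j])
    pc <- .pair_counts(ds2$calls, ia, ib)
    fit <- em_engine(pc$N)
    mono <- fit$pA_alt <= 0 | fit$pA_alt >= 1 | fit$pB_alt <= 0 |
      fit$pB_alt >= 1 | fit$n_used == 0
    dropped <- dropped + sum(mono)
    if (all(mono)) next
    m <- .ld_from_freqs(fit$pA_alt[!mono], fit$pB_alt[!mono], fit$x11[!mono])
    sum_r2 <- sum_r2 + sum(m$r2)
    n_pairs <- n_pairs + sum(!mono)
  }
  if (n_pairs == 0) stop("no usable inter-chromosome pairs")
  list(mean_r2 = sum_r2 / n_pairs, n_pairs = n_pairs,
       n_dropped_monomorphic = dropped)
}

#' Write an LD table as TSV
#'
#' @param tab an `ld_table`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ld_table <- function(tab, path) {
  write_tsv(tab[, c("snp_a", "snp_b", "chrom", "distance_bp", "n_used",
                    "r2", "abs_dprime")], path)
}
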