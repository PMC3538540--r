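#' Observed/expected heterozygosity and inbreeding coefficient
#'
#' Per SNP, observed heterozygosity is the fraction of heterozygotes among
#' called individuals; expected heterozygosity uses the small-sample
#' correction `2p(1-p) * 2n_c / (2n_c - 1)` with `n_c` the called
#' individuals. `Ho` and `He` are means over SNPs (those with at least one
#' called genotype), and `Fis = 1 - Ho/He`.
#'
#' @param ds population [genotype_dataset()] (typically one region).
#' @return list with `Ho`, `He`, `Fis` (`NA` when `He = 0`), `n_snps`.
#' @export
heterozygosity_fis <- function(ds) {
  calls <- ds$calls
  if (nrow(calls) < 2) stop("need at least 2 individuals")
  n_c <- colSums(!is.na(calls))
  use <- n_c > 0
  if (!any(use)) stop("no called SNPs")
  ho <- colMeans(calls == 1L, na.rm = TRUE)[use]
  p <- (colSums(calls, na.rm = TRUE) / (2 * n_c))[use]
  nc <- n_c[use]
  he <- 2 * p * (1 - p) * (2 * nc) / (2 * nc - 1)
  Ho <- mean(ho); He <- mean(he)
  list(Ho = Ho, He = He,
       Fis = if (He > 0) 1 - Ho / He else NA_real_,
       n_snps = sum(use))
}

#' Tajima's D from unphased genotypes
#'
#' The standard Tajima (1989) statistic computed phase-free: nucleotide
#' diversity `pi` is obtained from allele frequencies as
#' `sum over segregating sites of 2p(1-p) * n/(n-1)` with `n = 2 x`
#' individuals (the sequence count) — the identity between mean pairwise
#' difference and allele frequencies that does not require phase — and
#' Watterson's `theta_W = S / a1`. `D = (pi - theta_W) / sqrt(e1 S + e2
#' S(S-1))` with the canonical constants `a1, a2, b1, b2, c1, c2, e1, e2`.
#' With missing data, per-site allele frequencies use called genotypes while
#' the constants use the full sequence count; panels with a few percent
#' missingness are negligibly affected.
#'
#' @param ds population [genotype_dataset()] restricted to one region.
#' @return Tajima's D, or `NA` when no site segregates (e.g. a region
#'   monomorphic within a population).
#' @export
tajimas_d <- function(ds) {
  calls <- ds$calls
  n <- 2L * nrow(calls)  # sequences
  if (n < 4) stop("need at least 4 sequences (2 individuals)")
  n_c <- colSums(!is.na(calls))
  p <- colSums(calls, na.rm = TRUE) / pmax(1, 2 * n_c)
  seg <- n_c > 0 & p > 0 & p < 1
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi_hat <- sum(2 * p[seg] * (1 - p[seg])) * n / (n - 1)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Hudson-type pairwise Fst
#'
#' Ratio-of-averages moment estimator: per usable SNP,
#' `num = (p1 - p2)^2 - p1(1-p1)/(n1 - 1) - p2(1-p2)/(n2 - 1)` and
#' `den = p1(1-p2) + p2(1-p1)`, with `n_i` the called diploid individuals of
#' population i at that SNP; `Fst = sum(num) / sum(den)`. SNPs monomorphic
#' in both populations, or with fewer than 2 called individuals in either,
#' are skipped. The estimate is invariant to allele-label swaps and
#' symmetric in its arguments.
#'
#' @param dsA,dsB [genotype_dataset()]s sharing the same SNP panel.
#' @return Fst (ratio of averages across SNPs).
#' @export
pairwise_fst <- function(dsA, dsB) {
  stopifnot(identical(dsA$snps$snp_id, dsB$snps$snp_id))
  n1 <- colSums(!is.na(dsA$calls))
  n2 <- colSums(!is.na(dsB$calls))
  p1 <- colSums(dsA$calls, na.rm = TRUE) / pmax(1, 2 * n1)
  p2 <- colSums(dsB$calls, na.rm = TRUE) / pmax(1, 2 * n2)
  poly <- (p1 > 0 & p1 < 1) | (p2 > 0 & p2 < 1) | (p1 != p2)
  use <- n1 >= 2 & n2 >= 2 & poly
  if (!any(use)) stop("no usable SNPs for Fst")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num[use]) / sum(den[use])
}

#' Pairwise Fst matrix across populations
#'
#' @param ds multi-population [genotype_dataset()].
#' @param clip clip estimates into \[0, 1\] (default TRUE); pre-clip values
#'   are kept in the `"raw"` attribute.
#' @return symmetric matrix of class `fst_matrix` with zero diagonal.
#' @export
fst_matrix <- function(ds, clip = TRUE) {
  pops <- sort(unique(ds$samples$population))
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  sub <- lapply(pops, function(p) subset_population(ds, p))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    f <- pairwise_fst(sub[[i]], sub[[j]])
    m[i, j] <- m[j, i] <- f
  }
  raw <- m
  if (clip) m[] <- pmin(1, pmax(0, m))
  structure(m, raw = raw, class = c("fst_matrix", "matrix"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on a symmetric distance
#' matrix, typically a pairwise Fst matrix; negative branch lengths are
#' clamped to zero (a message notes how many).
#'
#' @param m symmetric numeric matrix with matching dimnames (an
#'   `fst_matrix` works directly).
#' @return an \pkg{ape} `phylo` tree (unrooted).
#' @export
nj_tree <- function(m) {
  m <- unclass(m)
  attr(m, "raw") <- NULL
  if (!isSymmetric(unname(m), tol = 1e-12))
    stop("distance matrix must be symmetric")
  if (nrow(m) < 3) stop("need at least 3 populations")
  if (any(!is.finite(m))) stop("distances must be finite")
  tr <- ape::nj(stats::as.dist(m))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message("clamped ", sum(neg), " negative branch length(s) to 0")
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Pearson correlation between LD extent and a genomic feature
#'
#' @param extents per-region LD extents (e.g. mean half-decay distances).
#' @param features per-region feature values (e.g. GC content, gene count),
#'   same order.
#' @return list with `r` and `p_value` (two-sided t test).
#' @export
feature_correlation <- function(extents, features) {
  stopifnot(length(extents) == length(features), length(extents) >= 3)
  if (stats::sd(extents) == 0 || stats::sd(features) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(extents, features, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Per-population, per-region summary statistics
#'
#' `Ho`, `He`, `Fis` and Tajima's D for every population x region cell.
#'
#' @param ds multi-population [genotype_dataset()].
#' @return data.frame with columns `population`, `region`, `Ho`, `He`,
#'   `Fis`, `TajD`.
#' @export
pop_summary <- function(ds) {
  pops <- unique(ds$samples$population)
  regs <- unique(ds$snps$region)
  out <- expand.grid(population = pops, region = regs,
                     stringsAsFactors = FALSE)
  out$Ho <- out$He <- out$Fis <- out$TajD <- NA_real_
  for (r in seq_len(nrow(out))) {
    dsr <- subset_region(subset_population(ds, out$population[r]),
                         out$region[r])
    h <- tryCatch(heterozygosity_fis(dsr), error = function(e) NULL)
    if (!is.null(h)) { out$Ho[r] <- h$Ho; out$He[r] <- h$He; out$Fis[r] <- h$Fis }
    out$TajD[r] <- tryCatch(tajimas_d(dsr), error = function(e) NA_real_)
  }
  out[, c("population", "region", "Ho", "He", "Fis", "TajD")]
}
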