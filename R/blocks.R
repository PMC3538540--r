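# Solid-spine-of-LD haplotype blocks and within-block haplotype frequencies.

#' Solid-spine block intervals from a |D'| matrix
#'
#' A candidate interval `[i..j]` is a valid spine block iff the first marker
#' is in strong LD with every later marker of the interval
#' (`|D'|(i, k) >= threshold` for all `k` in `(i..j]`) and the last marker is
#' in strong LD with every earlier one (`|D'|(k, j) >= threshold` for all `k`
#' in `[i..j)`). Intermediate-vs-intermediate pairs are unconstrained. Blocks
#' are found by left-to-right greedy extension: from each start the longest
#' valid interval is taken, the next search resumes after it, so blocks are
#' maximal and non-overlapping. Singleton markers form no block. `NA`
#' entries (e.g. pairs dropped as monomorphic) fail the threshold.
#'
#' @param dprime symmetric matrix of |D'| values (diagonal ignored).
#' @param threshold strong-LD threshold (default 0.8, the conventional
#'   solid-spine default).
#' @return data.frame with `first`, `last`, `n_markers` (marker indices into
#'   the matrix); zero rows when no block is found.
#' @export
spine_blocks_from_dprime <- function(dprime, threshold = 0.8) {
  m <- nrow(dprime)
  stopifnot(ncol(dprime) == m)
  ok <- function(x) !is.na(x) & x >= threshold
  blocks <- list()
  i <- 1L
  while (i < m) {
    best_j <- NA_integer_
    j <- i + 1L
    while (j <= m) {
      if (!ok(dprime[i, j])) break        # spine from i cannot span j
      if (all(ok(dprime[i:(j - 1L), j]))) best_j <- j
      j <- j + 1L
    }
    if (!is.na(best_j)) {
      blocks[[length(blocks) + 1L]] <- c(i, best_j)
      i <- best_j + 1L
    } else i <- i + 1L
  }
  if (!length(blocks))
    return(data.frame(first = integer(), last = integer(),
                      n_markers = integer()))
  b <- do.call(rbind, blocks)
  data.frame(first = b[, 1], last = b[, 2], n_markers = b[, 2] - b[, 1] + 1L)
}

# |D'| matrix for the SNPs of one region (pairwise-complete EM estimates;
# NA where a pair is monomorphic after pairwise deletion).
dprime_matrix <- function(ds) {
  m <- ncol(ds$calls)
  D <- matrix(NA_real_, m, m)
  if (m < 2) return(D)
  pc <- .pair_counts(ds$calls, seq_len(m))
  fit <- em_engine(pc$N)
  mono <- fit$pA_alt <= 0 | fit$pA_alt >= 1 | fit$pB_alt <= 0 |
    fit$pB_alt >= 1 | fit$n_used == 0
  vals <- rep(NA_real_, length(mono))
  if (any(!mono)) {
    mm <- .ld_from_freqs(fit$pA_alt[!mono], fit$pB_alt[!mono], fit$x11[!mono])
    vals[!mono] <- mm$abs_dprime
  }
  # .pair_counts(ia) walks the upper triangle column-major, matching upper.tri
  D[upper.tri(D)] <- vals
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  diag(D) <- 1
  D
}

#' Solid-spine haplotype blocks for one population
#'
#' Per region: filters markers to within-population `MAF >= maf_min`,
#' computes the pairwise |D'| matrix by two-locus EM, finds spine blocks with
#' [spine_blocks_from_dprime()], and estimates within-block haplotype
#' frequencies by multi-locus EM ([block_haplotype_freqs()]).
#'
#' @param ds population [genotype_dataset()] (post call-rate QC).
#' @param maf_min informative-marker MAF cutoff (default 0.05).
#' @param dprime_threshold strong-LD threshold (default 0.8).
#' @param estimate_haplotypes set `FALSE` to return block intervals only
#'   (skips the within-block EM; useful when only block counts and spans are
#'   needed).
#' @return list of `haplotype_block` objects; each has `region`, `first`,
#'   `last` (indices among the region's informative markers), `snp_ids`,
#'   `start_bp`, `end_bp`, `n_markers`, and `haplotypes` (data.frame with
#'   `haplotype` allele string over \{0 = ref, 1 = alt\}, `frequency`,
#'   `class`; `NULL` when `estimate_haplotypes = FALSE`).
#' @export
solid_spine_blocks <- function(ds, maf_min = 0.05, dprime_threshold = 0.8,
                               estimate_haplotypes = TRUE) {
  out <- list()
  for (reg in unique(ds$snps$region)) {
    dsr <- subset_region(ds, reg)
    n_called <- colSums(!is.na(dsr$calls))
    p <- colSums(dsr$calls, na.rm = TRUE) / pmax(1, 2 * n_called)
    maf <- pmin(p, 1 - p)
    keep <- n_called > 0 & maf >= maf_min & maf > 0
    if (sum(keep) < 2) next
    dsr <- subset_snps(dsr, which(keep))
    D <- dprime_matrix(dsr)
    b <- spine_blocks_from_dprime(D, dprime_threshold)
    for (k in seq_len(nrow(b))) {
      idx <- b$first[k]:b$last[k]
      haps <- if (estimate_haplotypes)
        block_haplotype_freqs(dsr$calls[, idx, drop = FALSE]) else NULL
      out[[length(out) + 1L]] <- structure(list(
        region = reg, first = b$first[k], last = b$last[k],
        snp_ids = dsr$snps$snp_id[idx],
        start_bp = dsr$snps$position_bp[b$first[k]],
        end_bp = dsr$snps$position_bp[b$last[k]],
        n_markers = length(idx),
        haplotypes = haps), class = "haplotype_block")
    }
  }
  out
}

# Multi-locus EM over phase configurations for <= max_markers markers.
# geno: matrix individuals x markers of dosages 0/1/2 (no NA).
# Returns named numeric vector of haplotype frequencies (names = 0/1
# strings), covering haplotypes with positive estimated frequency.
.block_em <- function(geno, tol = 1e-8, max_iter = 2000L) {
  L <- ncol(geno)
  n <- nrow(geno)
  pow2 <- 2L^(seq_len(L) - 1L)
  # per-individual compatible (hap1, hap2) index pairs
  pair_list <- lapply(seq_len(n), function(i) {
    g <- geno[i, ]
    het <- which(g == 1L)
    base <- sum(pow2[g == 2L])
    if (!length(het)) return(matrix(base, 1, 2))
    h <- length(het)
    sub <- seq_len(2^(h - 1)) - 1L  # fix first het on hap1 to break symmetry
    first <- pow2[het[1]]
    rest <- het[-1]
    h1 <- base + first
    h2 <- base
    if (length(rest)) {
      bits <- t(vapply(sub, function(s) as.integer(intToBits(s))[seq_along(rest)],
                       integer(length(rest))))
      if (length(rest) == 1L) bits <- matrix(bits, ncol = 1L)
      h1 <- base + first + as.vector(bits %*% pow2[rest])
      h2 <- base + as.vector((1L - bits) %*% pow2[rest])
    }
    cbind(h1, h2)
  })
  hap_ids <- sort(unique(unlist(pair_list)))
  f <- setNames(rep(1 / length(hap_ids), length(hap_ids)),
                as.character(hap_ids))
  for (it in seq_len(max_iter)) {
    counts <- setNames(numeric(length(f)), names(f))
    for (pl in pair_list) {
      a <- as.character(pl[, 1]); b <- as.character(pl[, 2])
      w <- f[a] * f[b] * ifelse(pl[, 1] == pl[, 2], 1, 2)
      if (sum(w) == 0) w <- rep(1 / length(w), length(w)) else w <- w / sum(w)
      for (q in seq_along(w)) {
        counts[a[q]] <- counts[a[q]] + w[q]
        counts[b[q]] <- counts[b[q]] + w[q]
      }
    }
    new_f <- counts / (2 * n)
    delta <- max(abs(new_f - f))
    f <- new_f
    if (delta < tol) break
  }
  f <- f[f > 0]
  names(f) <- vapply(as.integer(names(f)), function(h)
    paste(as.integer(intToBits(h))[seq_len(L)], collapse = ""), character(1))
  f
}

#' Within-block haplotype frequencies by EM
#'
#' Multi-locus haplotype frequency estimation over phase configurations.
#' Individuals with any missing call in the block are excluded. Blocks of
#' more than `max_em_markers` markers are handled by partition-ligation:
#' consecutive sub-blocks of at most `max_em_markers` markers are estimated
#' by EM, the top `ligate_top` haplotypes per side are ligated, and the
#' product space re-estimated and renormalized. Haplotypes with frequency
#' below `min_freq` (default 0.01) are discarded before counting and
#' classification: the single highest-frequency haplotype is `major`,
#' haplotypes above frequency 0.1 are `intermediate`, the rest pool into
#' `rare-pooled`.
#'
#' @param geno genotype code matrix (individuals x 2-60 markers), or a
#'   [genotype_dataset()] restricted to the block.
#' @param min_freq display threshold for reported haplotypes.
#' @param max_em_markers largest block handled by exact phase-configuration
#'   EM (default 8).
#' @param ligate_top candidates kept per side during ligation (default 20).
#' @return data.frame with `haplotype` (string over 0 = ref / 1 = alt),
#'   `frequency` (descending), `class`; attribute `rare_pooled_freq` holds
#'   the pooled rare mass.
#' @export
block_haplotype_freqs <- function(geno, min_freq = 0.01, max_em_markers = 8L,
                                  ligate_top = 20L) {
  if (inherits(geno, "genotype_dataset")) geno <- geno$calls
  geno <- as.matrix(geno)
  L <- ncol(geno)
  stopifnot(L >= 2, L <= 60)
  geno <- geno[stats::complete.cases(geno), , drop = FALSE]
  if (!nrow(geno)) stop("no individual fully genotyped in the block")
  poly <- apply(geno, 2, function(g) length(unique(g)) > 1 || any(g == 1L))
  if (!any(poly)) stop("block monomorphic after restriction")

  if (L <= max_em_markers) {
    f <- .block_em(geno)
  } else {
    # partition-ligation: estimate consecutive chunks, then merge pairwise
    n_chunk <- ceiling(L / max_em_markers)
    bounds <- floor(seq(0, L, length.out = n_chunk + 1))
    chunk_f <- lapply(seq_len(n_chunk), function(k) {
      idx <- (bounds[k] + 1):bounds[k + 1]
      f <- .block_em(geno[, idx, drop = FALSE])
      head(sort(f, decreasing = TRUE), ligate_top)
    })
    chunk_idx <- lapply(seq_len(n_chunk), function(k) (bounds[k] + 1):bounds[k + 1])
    f <- chunk_f[[1]]
    done <- chunk_idx[[1]]
    for (k in 2:n_chunk) {
      f <- .ligate(geno, done, chunk_idx[[k]], f, chunk_f[[k]], ligate_top)
      done <- c(done, chunk_idx[[k]])
    }
  }
  f <- sort(f / sum(f), decreasing = TRUE)
  kept <- f[f >= min_freq]
  if (!length(kept)) kept <- f[1]
  rare_pool <- 1 - sum(kept)
  out <- data.frame(haplotype = names(kept), frequency = as.numeric(kept),
                    class = .hap_classes(as.numeric(kept)),
                    stringsAsFactors = FALSE)
  attr(out, "rare_pooled_freq") <- max(0, rare_pool)
  out
}

# Frequency classes: the single top haplotype is "major", others above 0.1
# are "intermediate", the rest pool as "rare-pooled". Expects descending
# frequencies.
.hap_classes <- function(freqs) {
  cls <- rep("rare-pooled", length(freqs))
  cls[freqs > 0.1] <- "intermediate"
  if (length(cls)) cls[1] <- "major"
  cls
}

# Ligate two adjacent marker sets: candidate combined haplotypes are the
# cross product of each side's candidates; frequencies re-estimated by EM
# over individuals' compatible (combined hap, combined hap) pairs.
.ligate <- function(geno, idx_left, idx_right, f_left, f_right, top) {
  f_left <- head(sort(f_left, decreasing = TRUE), top)
  f_right <- head(sort(f_right, decreasing = TRUE), top)
  cand <- as.vector(outer(names(f_left), names(f_right), paste0))
  init <- as.vector(outer(as.numeric(f_left), as.numeric(f_right)))
  names(init) <- cand
  init <- init / sum(init)
  L <- length(idx_left) + length(idx_right)
  sub <- geno[, c(idx_left, idx_right), drop = FALSE]
  hap_bits <- do.call(rbind, lapply(cand, function(s)
    as.integer(strsplit(s, "")[[1]])))
  n <- nrow(sub)
  # per individual, compatible candidate pairs
  pair_list <- vector("list", n)
  for (i in seq_len(n)) {
    g <- sub[i, ]
    ok <- which(apply(hap_bits, 1, function(h) all(h <= g & (g - h) <= 1)))
    prs <- list()
    for (a in ok) {
      need <- g - hap_bits[a, ]
      hit <- ok[vapply(ok, function(b) all(hap_bits[b, ] == need), logical(1))]
      for (b in hit) if (b >= a) prs[[length(prs) + 1L]] <- c(a, b)
    }
    pair_list[[i]] <- if (length(prs)) do.call(rbind, prs) else NULL
  }
  keep_ind <- !vapply(pair_list, is.null, logical(1))
  pair_list <- pair_list[keep_ind]
  if (!length(pair_list)) return(init)
  f <- init
  for (it in seq_len(500L)) {
    counts <- numeric(length(f))
    for (pl in pair_list) {
      w <- f[pl[, 1]] * f[pl[, 2]] * ifelse(pl[, 1] == pl[, 2], 1, 2)
      if (sum(w) == 0) w <- rep(1 / nrow(pl), nrow(pl)) else w <- w / sum(w)
      for (q in seq_len(nrow(pl))) {
        counts[pl[q, 1]] <- counts[pl[q, 1]] + w[q]
        counts[pl[q, 2]] <- counts[pl[q, 2]] + w[q]
      }
    }
    new_f <- counts / (2 * length(pair_list))
    delta <- max(abs(new_f - f))
    f <- new_f
    if (delta < 1e-8) break
  }
  names(f) <- cand
  f[f > 0]
}

#' Haplotype diversity summary
#'
#' Counts blocks and haplotypes (frequency >= `min_freq`, default the 0.01
#' display threshold) per region, with totals across regions.
#'
#' @param blocks list of `haplotype_block` objects (one population), as
#'   returned by [solid_spine_blocks()].
#' @param regions optional character vector of all region labels, so regions
#'   without blocks contribute zero rows.
#' @param min_freq haplotype counting threshold.
#' @return list with `per_region` (data.frame `region`, `n_blocks`,
#'   `n_haplotypes`) and `totals`.
#' @export
diversity_summary <- function(blocks, regions = NULL, min_freq = 0.01) {
  regs <- regions %||% unique(vapply(blocks, function(b) b$region, character(1)))
  per <- data.frame(region = regs, n_blocks = 0L, n_haplotypes = 0L,
                    stringsAsFactors = FALSE)
  for (b in blocks) {
    i <- match(b$region, per$region)
    per$n_blocks[i] <- per$n_blocks[i] + 1L
    per$n_haplotypes[i] <- per$n_haplotypes[i] +
      sum(b$haplotypes$frequency >= min_freq)
  }
  list(per_region = per,
       totals = c(n_blocks = sum(per$n_blocks),
                  n_haplotypes = sum(per$n_haplotypes)))
}
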