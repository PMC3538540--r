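#' Expected r-squared under drift-recombination equilibrium
#'
#' The Hill-Weir expectation of r-squared for a population at
#' drift-recombination equilibrium, as a function of the population
#' recombination parameter `C` and the sample size `n`, including the
#' sample-size adjustment term:
#' \deqn{E[r^2] = \frac{10 + C}{(2 + C)(11 + C)}
#'   \left[1 + \frac{(3 + C)(12 + 12C + C^2)}{n(2 + C)(11 + C)}\right]}
#' The function is strictly decreasing in `C` for fixed `n`, with supremum
#' `(5/11)(1 + 18/(11 n))` at `C = 0` and limit `1/n` as `C` grows.
#'
#' @param C population recombination parameter, `C >= 0` (vectorized).
#' @param n sample size entering the adjustment term. Here `n` is the number
#'   of sampled diploid individuals (see Details).
#' @details Using individuals (not chromosomes) for `n` makes the analytic
#'   half-decay level `(5/22)(1 + 18/(11 n))` consistent with half-decay
#'   r-squared values conventionally reported for samples of 8-22
#'   individuals; a caller preferring chromosome counts can simply pass
#'   `2 * n_individuals`.
#' @return `E[r^2]`, same length as `C`.
#' @export
hill_weir_expected_r2 <- function(C, n) {
  if (any(C < 0)) stop("C must be non-negative")
  stopifnot(n >= 2)
  lead <- (10 + C) / ((2 + C) * (11 + C))
  adj <- 1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C))
  lead * adj
}

#' Fit the LD decay curve
#'
#' Least-squares fit of `r2_i ~ E[r^2](a * d_i, n)` over the single decay
#' coefficient `a` (per kb), on unbinned intra-chromosome SNP pairs. `a` is
#' located by a coarse log-grid search over `[1e-5, 1]` per kb and refined by
#' golden-section optimization on the log scale. Fits whose optimum sticks to
#' the grid boundary (e.g. when the observed r-squared never decays, or sits
#' at the `1/n` floor everywhere) are flagged non-converged.
#'
#' @param pairs an `ld_table` (or data.frame with `distance_bp`, `r2`,
#'   optionally `inter_chromosome`); only intra-chromosome rows with positive
#'   distance are used.
#' @param n model sample size (diploid individuals).
#' @param scope label recorded on the fit: a chromosome name, `"Auto"`
#'   (autosomes combined) or `"All"`. The caller is responsible for
#'   restricting `pairs` accordingly.
#' @param binned fit on per-bin mean r-squared instead of raw pairs
#'   (non-default; unbinned pairs are the primary mode).
#' @param bin_width_kb bin width when `binned = TRUE`.
#' @return Object of class `decay_fit`: `a_per_kb`, `n`, `scope`, `n_pairs`,
#'   `rss`, `converged`.
#' @export
fit_decay <- function(pairs, n, scope = "Auto", binned = FALSE,
                      bin_width_kb = 10) {
  if (!is.null(pairs$inter_chromosome)) pairs <- pairs[!pairs$inter_chromosome, ]
  pairs <- pairs[pairs$distance_bp > 0 & !is.na(pairs$r2), ]
  if (nrow(pairs) < 10) stop("need at least 10 intra-chromosome pairs to fit")
  n_pairs_used <- nrow(pairs)
  d_kb <- pairs$distance_bp / 1000
  r2 <- pairs$r2
  if (binned) {
    bin <- floor(d_kb / bin_width_kb)
    d_kb <- tapply(d_kb, bin, mean)
    r2 <- tapply(r2, bin, mean)
  }
  rss <- function(log10a) {
    e <- hill_weir_expected_r2(10^log10a * d_kb, n)
    sum((r2 - e)^2)
  }
  grid <- seq(-5, 0, length.out = 61)
  vals <- vapply(grid, rss, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- optimize(rss, interval = c(lo, hi), tol = 1e-10)
  a <- 10^opt$minimum
  # boundary fits carry no decay information
  converged <- opt$minimum > grid[1] + 0.02 && opt$minimum < grid[length(grid)] - 0.02
  structure(list(a_per_kb = a, n = n, scope = scope, n_pairs = n_pairs_used,
                 rss = opt$objective, converged = converged),
            class = "decay_fit")
}

#' @method print decay_fit
#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit [%s]: a = %.6g per kb, n = %d, %d pairs, rss = %.4g%s\n",
              x$scope, x$a_per_kb, x$n, x$n_pairs, x$rss,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Half-decay point of a fitted curve
#'
#' The curve maximum is its zero-recombination limit
#' `E[r^2](0, n) = (5/11)(1 + 18/(11 n))` — a data-independent quantity —
#' and the half-decay level is half of that. The distance at which the
#' fitted curve reaches that level is solved by bisection (tolerance 1e-6
#' kb). When the level is not reached within `max_distance_kb` the distance
#' is reported as `Inf` with `reached = FALSE` (the conventional "> 1000 kb"
#' sentinel when formatted).
#'
#' @param fit a `decay_fit`.
#' @param max_distance_kb search horizon in kb (default 1000).
#' @return list with `r2_level`, `distance_kb` (`Inf` when unreached),
#'   `reached`, and `max_distance_kb`.
#' @export
half_decay <- function(fit, max_distance_kb = 1000) {
  if (!isTRUE(fit$converged)) stop("half_decay requires a converged fit")
  level <- 0.5 * hill_weir_expected_r2(0, fit$n)
  f <- function(d) hill_weir_expected_r2(fit$a_per_kb * d, fit$n) - level
  if (f(max_distance_kb) > 0)
    return(list(r2_level = level, distance_kb = Inf, reached = FALSE,
                max_distance_kb = max_distance_kb))
  d50 <- uniroot(f, interval = c(1e-12, max_distance_kb), tol = 1e-6)$root
  list(r2_level = level, distance_kb = d50, reached = TRUE,
       max_distance_kb = max_distance_kb)
}

format_half_decay_distance <- function(hd) {
  if (hd$reached) sprintf("%.0f", hd$distance_kb)
  else paste0(">", format(hd$max_distance_kb))
}

# Restrict an ld_table to a fitting scope given the SNP map chromosome of
# each pair. "Auto" drops the X chromosome; "All" keeps everything; any
# other value names one chromosome.
scope_pairs <- function(pairs, scope) {
  if (scope == "All") pairs
  else if (scope == "Auto") pairs[pairs$chrom != "X", , drop = FALSE]
  else pairs[pairs$chrom == scope, , drop = FALSE]
}

#' Inflation of the LD extent from the stricter MAF cutoff
#'
#' Runs the full QC -> pairwise LD -> decay fit -> half-decay chain twice for
#' one population, at `MAF >= 0.05` and `MAF >= 0.1`, and reports the percent
#' inflation of the half-decay distance attributable to the higher cutoff:
#' `100 * (d50(0.1) - d50(0.05)) / d50(0.1)`. Distances are solved without a
#' search horizon so the ratio is defined even when a sentinel would be
#' printed.
#'
#' @param ds full [genotype_dataset()].
#' @param population population label.
#' @param call_rate_min call-rate threshold passed to [apply_qc()].
#' @param scope fitting scope (default `"Auto"`).
#' @return list with `percent`, `d50_maf05`, `d50_maf10`, and the two fits.
#' @export
maf_inflation <- function(ds, population, call_rate_min = 0.80, scope = "Auto") {
  run_one <- function(maf) {
    qc <- apply_qc(ds, population, call_rate_min, maf)
    tab <- scope_pairs(pairwise_ld_region(qc$dataset), scope)
    fit <- fit_decay(tab, n = nrow(qc$dataset$calls), scope = scope)
    list(fit = fit,
         d50 = half_decay(fit, max_distance_kb = 1e9)$distance_kb)
  }
  lo <- run_one(0.05)
  hi <- run_one(0.10)
  list(percent = maf_inflation_pct(lo$d50, hi$d50),
       d50_maf05 = lo$d50, d50_maf10 = hi$d50,
       fit_maf05 = lo$fit, fit_maf10 = hi$fit)
}

#' Percent inflation of the LD extent
#'
#' @param d50_maf05,d50_maf10 half-decay distances (kb) estimated with the
#'   0.05 and 0.1 MAF cutoffs.
#' @return `100 * (d50_maf10 - d50_maf05) / d50_maf10`.
#' @export
maf_inflation_pct <- function(d50_maf05, d50_maf10) {
  100 * (d50_maf10 - d50_maf05) / d50_maf10
}

#' Fraction of GWAS-informative pairs by distance class
#'
#' For each half-open distance class `[lo, hi)` in kb, the fraction of
#' intra-chromosome SNP pairs whose r-squared is at least `r2_threshold`.
#' A pair with r-squared at or above the threshold means one member tags the
#' other for association mapping. Empty classes yield `NA` (undefined), not
#' zero.
#'
#' @param pairs an `ld_table`; inter-chromosome rows are excluded.
#' @param r2_threshold tagging threshold (default 0.8).
#' @param breaks_kb class boundaries in kb; class i is
#'   `[breaks_kb[i], breaks_kb[i+1])`.
#' @return data.frame with `lo_kb`, `hi_kb`, `n_pairs`, `n_ge_threshold`,
#'   `fraction`.
#' @export
informative_fractions <- function(pairs, r2_threshold = 0.8,
                                  breaks_kb = c(0, 20, 40, 60, 80, 100,
                                                200, 400, 600, 1000)) {
  if (!is.null(pairs$inter_chromosome)) pairs <- pairs[!pairs$inter_chromosome, ]
  d_kb <- pairs$distance_bp / 1000
  out <- data.frame(lo_kb = breaks_kb[-length(breaks_kb)],
                    hi_kb = breaks_kb[-1])
  out$n_pairs <- out$n_ge_threshold <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- d_kb >= out$lo_kb[i] & d_kb < out$hi_kb[i]
    out$n_pairs[i] <- sum(sel)
    out$n_ge_threshold[i] <- sum(pairs$r2[sel] >= r2_threshold)
  }
  out$fraction <- ifelse(out$n_pairs > 0, out$n_ge_threshold / out$n_pairs,
                         NA_real_)
  out
}
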