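#' Minor allele frequency from genotype codes
#'
#' Computed from called genotypes only: with `p` the alternate-allele
#' frequency `(2 * n_hom_alt + n_het) / (2 * n_called)`, the MAF is
#' `min(p, 1 - p)`.
#'
#' @param calls vector of codes in \{0, 1, 2, NA\} for one SNP.
#' @return MAF in \[0, 0.5\].
#' @export
minor_allele_freq <- function(calls) {
  called <- calls[!is.na(calls)]
  if (!length(called)) stop("all genotypes missing: MAF undefined")
  p <- sum(called) / (2 * length(called))
  min(p, 1 - p)
}

#' Per-population SNP quality control
#'
#' Restricts the dataset to one population, then removes SNPs that (1) have a
#' call rate below `call_rate_min` within that population, (2) are
#' monomorphic within that population, or (3) have a within-population MAF
#' below `maf_min` (MAF computed from called genotypes after the call-rate
#' filter). A SNP is counted in the first category it fails, so the report
#' categories are reproducible and always sum to the input SNP count. All
#' thresholds are per population: the same SNP may pass in one population and
#' fail in another.
#'
#' @param ds a [genotype_dataset()].
#' @param population population label.
#' @param call_rate_min minimum fraction of called genotypes (default 0.80).
#' @param maf_min minimum minor allele frequency; SNPs are retained when
#'   `MAF >= maf_min`.
#' @param exclude_male_x when `TRUE` and the dataset carries a `sex` column
#'   (values `"M"`/`"F"`), calls of male individuals on the chromosome
#'   labeled `X` are set missing before filtering — male X genotypes are
#'   hemizygous and would otherwise distort heterozygosity-based
#'   statistics. Off by default: all samples are treated as diploid
#'   everywhere.
#' @return A list with `dataset` (the population's samples x retained SNPs;
#'   possibly zero SNPs) and `report` (one-row data.frame with counts
#'   `n_total`, `n_failed_callrate`, `n_monomorphic`, `n_low_maf`,
#'   `n_retained` and `pct_retained`).
#' @export
apply_qc <- function(ds, population, call_rate_min = 0.80, maf_min = 0.05,
                     exclude_male_x = FALSE) {
  stopifnot(call_rate_min > 0, call_rate_min <= 1,
            maf_min >= 0, maf_min < 0.5)
  pop <- subset_population(ds, population)
  if (exclude_male_x && "sex" %in% names(pop$samples)) {
    male <- pop$samples$sex %in% c("M", "m", "male")
    on_x <- pop$snps$chromosome == "X"
    if (any(male) && any(on_x)) pop$calls[male, on_x] <- NA_integer_
  }
  calls <- pop$calls
  n_samp <- nrow(calls)
  call_rate <- colMeans(!is.na(calls))
  n_called <- colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  # heterozygote-only columns are polymorphic even though p may be 0.5 with
  # alt == n_called; monomorphic means a single allele among called genotypes
  mono <- n_called == 0 | maf == 0

  fail_cr <- call_rate < call_rate_min
  fail_mono <- !fail_cr & mono
  fail_maf <- !fail_cr & !fail_mono & maf < maf_min
  keep <- !fail_cr & !fail_mono & !fail_maf

  report <- data.frame(
    population = population,
    n_samples = n_samp,
    n_total = ncol(calls),
    n_failed_callrate = sum(fail_cr),
    n_monomorphic = sum(fail_mono),
    n_low_maf = sum(fail_maf),
    n_retained = sum(keep),
    pct_retained = 100 * sum(keep) / max(1L, ncol(calls)),
    stringsAsFactors = FALSE)

  dataset <- if (any(keep)) subset_snps(pop, keep) else {
    out <- pop
    out$calls <- pop$calls[, 0, drop = FALSE]
    out$snps <- pop$snps[0, , drop = FALSE]
    out
  }
  list(dataset = dataset, report = report)
}

#' QC report across populations
#'
#' Runs [apply_qc()] for every population and binds the one-row reports.
#'
#' @inheritParams apply_qc
#' @return data.frame with one row per population.
#' @export
qc_report <- function(ds, call_rate_min = 0.80, maf_min = 0.05) {
  pops <- unique(ds$samples$population)
  do.call(rbind, lapply(pops, function(p)
    apply_qc(ds, p, call_rate_min, maf_min)$report))
}
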