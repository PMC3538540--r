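#' Genotype dataset container
#'
#' A `genotype_dataset` bundles an unphased biallelic genotype matrix with its
#' SNP map and sample-to-population assignment. Genotypes are coded as alt
#' allele dosages: 0 (homozygous reference), 1 (heterozygous), 2 (homozygous
#' alternate), `NA` (missing). Every downstream stage (QC, LD, haplotype
#' blocks, population statistics) consumes this container.
#'
#' @param calls integer matrix, samples x SNPs, entries in \{0, 1, 2, NA\}.
#'   Row names are sample ids, column names SNP ids (set from `samples`/`snps`
#'   when absent).
#' @param samples data.frame with columns `sample_id`, `population`.
#' @param snps data.frame with columns `snp_id`, `chromosome`, `region`,
#'   `position_bp` (1-based). Positions must be strictly increasing within a
#'   (chromosome, region).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(calls, samples, snps) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  rownames(calls) <- samples$sample_id
  colnames(calls) <- snps$snp_id
  ds <- structure(list(calls = calls, samples = samples, snps = snps),
                  class = "genotype_dataset")
  validate_genotype_dataset(ds)
  ds
}

validate_genotype_dataset <- function(ds) {
  calls <- ds$calls; samples <- ds$samples; snps <- ds$snps
  stopifnot(is.matrix(calls))
  if (nrow(calls) != nrow(samples))
    stop("calls has ", nrow(calls), " rows but ", nrow(samples), " samples")
  if (ncol(calls) != nrow(snps))
    stop("calls has ", ncol(calls), " columns but ", nrow(snps), " SNPs")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample ids: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  if (any(is.na(samples$population) | samples$population == ""))
    stop("every sample needs a non-empty population label")
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  key <- paste(snps$chromosome, snps$region)
  for (k in unique(key)) {
    pos <- snps$position_bp[key == k]
    if (any(diff(pos) <= 0)) {
      off <- snps$snp_id[key == k][which(diff(pos) <= 0)[1] + 1]
      stop("positions not strictly increasing within ", k,
           "; first offender: ", off)
    }
  }
  invisible(ds)
}

#' @method print genotype_dataset
#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$calls), "samples x", ncol(x$calls), "SNPs\n")
  cat("  populations:", paste(sort(unique(x$samples$population)), collapse = ", "), "\n")
  cat("  chromosomes:", paste(unique(x$snps$chromosome), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Restrict a dataset to one population
#'
#' @param ds a `genotype_dataset`.
#' @param population population label present in `ds`.
#' @return `genotype_dataset` with only that population's samples.
#' @export
subset_population <- function(ds, population) {
  keep <- ds$samples$population == population
  if (!any(keep)) stop("population not present or empty: ", population)
  genotype_dataset(ds$calls[keep, , drop = FALSE],
                   ds$samples[keep, , drop = FALSE], ds$snps)
}

#' Restrict a dataset to a subset of SNPs
#'
#' @param ds a `genotype_dataset`.
#' @param idx logical or integer index over SNP columns, or character snp ids.
#' @return `genotype_dataset` with only the selected SNPs (order preserved).
#' @export
subset_snps <- function(ds, idx) {
  if (is.character(idx)) idx <- match(idx, ds$snps$snp_id)
  genotype_dataset(ds$calls[, idx, drop = FALSE], ds$samples,
                   ds$snps[idx, , drop = FALSE])
}

#' Restrict a dataset to one chromosomal region
#'
#' @param ds a `genotype_dataset`.
#' @param region region label present in the SNP map.
#' @return `genotype_dataset` of that region's SNPs.
#' @export
subset_region <- function(ds, region) {
  keep <- ds$snps$region == region
  if (!any(keep)) stop("region not present: ", region)
  subset_snps(ds, keep)
}

#' Read genotypes, a population map and an optional SNP map
#'
#' Accepts either a VCF (v4.x, biallelic SNVs; phase separators are ignored —
#' the data are treated as unphased) or a simple TSV dialect: a header row
#' `sample_id<TAB><snp_1><TAB>...` followed by one row per sample with cells
#' in \{0, 1, 2, NA\}. The popmap TSV has columns `sample_id`, `population`
#' and must cover every genotyped sample exactly. The SNP map TSV has columns
#' `snp_id`, `chromosome`, `region`, `position_bp`; it is required for TSV
#' input and optional for VCF (chromosome doubles as region when absent).
#'
#' @param genotype_path path to the VCF or TSV genotype file.
#' @param popmap_path path to the popmap TSV.
#' @param map_path optional path to the SNP map TSV.
#' @param multiallelic `"skip"` drops multi-allelic VCF records with a
#'   warning; `"error"` aborts.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(genotype_path, popmap_path, map_path = NULL,
                           multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(genotype_path)) stop("genotype file not found: ", genotype_path)
  if (!file.exists(popmap_path)) stop("popmap file not found: ", popmap_path)
  first <- readLines(genotype_path, n = 1L, warn = FALSE)
  is_vcf <- grepl("\\.vcf(\\.gz)?$", genotype_path) || startsWith(first, "##")
  if (is_vcf) {
    parsed <- read_genotypes_vcf(genotype_path, multiallelic)
  } else {
    parsed <- read_genotypes_tsv(genotype_path)
  }
  calls <- parsed$calls
  snps <- parsed$snps

  popmap <- read.delim(popmap_path, stringsAsFactors = FALSE)
  names(popmap)[1:2] <- c("sample_id", "population")
  has_sex <- "sex" %in% names(popmap)
  unknown <- setdiff(popmap$sample_id, rownames(calls))
  if (length(unknown))
    stop("popmap lists samples absent from the genotype file: ",
         paste(unknown, collapse = ", "))
  unmapped <- setdiff(rownames(calls), popmap$sample_id)
  if (length(unmapped))
    stop("samples without population assignment: ",
         paste(unmapped, collapse = ", "))
  samples <- data.frame(
    sample_id = rownames(calls),
    population = popmap$population[match(rownames(calls), popmap$sample_id)],
    stringsAsFactors = FALSE)
  if (has_sex)
    samples$sex <- popmap$sex[match(rownames(calls), popmap$sample_id)]

  if (!is.null(map_path)) {
    map <- read.delim(map_path, stringsAsFactors = FALSE)
    names(map)[1:4] <- c("snp_id", "chromosome", "region", "position_bp")
    missing_map <- setdiff(colnames(calls), map$snp_id)
    if (length(missing_map))
      stop("SNPs absent from map: ", paste(missing_map, collapse = ", "))
    snps <- map[match(colnames(calls), map$snp_id), , drop = FALSE]
    rownames(snps) <- NULL
  } else if (is.null(snps)) {
    stop("a SNP map is required for TSV genotype input")
  }
  genotype_dataset(calls, samples, snps)
}

read_genotypes_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  sample_id <- as.character(tab[[1]])
  calls <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(calls) <- "integer")
  rownames(calls) <- sample_id
  list(calls = calls, snps = NULL)
}

read_genotypes_vcf <- function(path, multiallelic) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multi-allelic records present: ",
           paste(fix$ID[multi], collapse = ", "))
    warning("skipped ", sum(multi), " multi-allelic record(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% "1/1"] <- 2L
    out
  }
  calls <- t(apply(gt, 2, code))  # samples x snps
  if (nrow(fix) == 1L) calls <- matrix(calls, ncol = 1L)
  rownames(calls) <- colnames(gt)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID)
  colnames(calls) <- ids
  snps <- data.frame(snp_id = ids, chromosome = fix$CHROM,
                     region = fix$CHROM,
                     position_bp = as.integer(fix$POS),
                     stringsAsFactors = FALSE)
  list(calls = calls, snps = snps)
}

#' Write a dataset in the TSV dialect
#'
#' Emits the genotype TSV, SNP map TSV and popmap TSV that
#' [read_genotypes()] accepts. Missing genotypes are written as `NA`.
#'
#' @param ds a `genotype_dataset`.
#' @param genotype_path,map_path,popmap_path output paths.
#' @return Invisibly, the genotype path.
#' @export
write_genotypes_tsv <- function(ds, genotype_path, map_path, popmap_path) {
  g <- as.data.frame(ds$calls, check.names = FALSE)
  g <- cbind(sample_id = rownames(ds$calls), g)
  write_tsv(g, genotype_path)
  write_tsv(ds$snps[, c("snp_id", "chromosome", "region", "position_bp")],
            map_path)
  write_tsv(ds$samples[, c("sample_id", "population")], popmap_path)
  invisible(genotype_path)
}

#' Write a dataset as a minimal VCF
#'
#' Emits an uncompressed VCFv4.2 with placeholder `A`/`C` alleles (allele
#' identity is not tracked by the genotype codes) and unphased `GT` calls;
#' missing calls become `./.`.
#'
#' @param ds a `genotype_dataset`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_genotypes_vcf <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  for (chr in unique(ds$snps$chromosome))
    writeLines(sprintf("##contig=<ID=%s>", chr), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ds$samples$sample_id), collapse = "\t"),
             con)
  gt_map <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(ds$snps)), function(j) {
    g <- ds$calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_map[g + 1L])
    paste(c(ds$snps$chromosome[j], ds$snps$position_bp[j], ds$snps$snp_id[j],
            "A", "C", ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}
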