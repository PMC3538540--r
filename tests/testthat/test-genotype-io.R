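# Reading/writing genotype data and per-population SNP QC.

write_tsv_fixture <- function(lines, file) writeLines(lines, file)

test_that("TSV dialect round-trips a small fixture verbatim", {
  td <- withr::local_tempdir()
  gp <- file.path(td, "geno.tsv"); mp <- file.path(td, "map.tsv")
  pp <- file.path(td, "pop.tsv")
  write_tsv_fixture(c("sample_id\tsnpA\tsnpB",
                      "s1\t0\t1", "s2\t2\tNA", "s3\t1\t1"), gp)
  write_tsv_fixture(c("snp_id\tchromosome\tregion\tposition_bp",
                      "snpA\tc1\tc1\t100", "snpB\tc1\tc1\t250"), mp)
  write_tsv_fixture(c("sample_id\tpopulation",
                      "s1\tP1", "s2\tP1", "s3\tP2"), pp)
  ds <- read_genotypes(gp, pp, mp)
  expect_identical(unname(ds$calls),
                   matrix(c(0L, 2L, 1L, 1L, NA, 1L), nrow = 3))
  expect_identical(ds$samples$population, c("P1", "P1", "P2"))
  expect_identical(ds$snps$position_bp, c(100L, 250L))

  # write -> read identity
  out <- file.path(td, "o.tsv"); om <- file.path(td, "om.tsv")
  op <- file.path(td, "op.tsv")
  write_genotypes_tsv(ds, out, om, op)
  ds2 <- read_genotypes(out, op, om)
  expect_identical(ds2$calls, ds$calls)
  expect_identical(ds2$snps, ds$snps)
})

test_that("VCF input maps GT codes and skips multi-allelic sites with a warning", {
  td <- withr::local_tempdir()
  vp <- file.path(td, "x.vcf"); pp <- file.path(td, "pop.tsv")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "c1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0|1",
    "c1\t200\tv2\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t1/2",
    "c1\t300\tv3\tA\tG\t.\tPASS\t.\tGT\t1/1\t./."), vp)
  writeLines(c("sample_id\tpopulation", "s1\tP", "s2\tP"), pp)
  expect_warning(ds <- read_genotypes(vp, pp), "multi-allelic")
  expect_identical(colnames(ds$calls), c("v1", "v3"))
  expect_identical(unname(ds$calls), matrix(c(0L, 1L, 2L, NA), nrow = 2))
  expect_error(read_genotypes(vp, pp, multiallelic = "error"),
               "multi-allelic")
})

test_that("popmap mismatches and unsorted maps raise informative errors", {
  td <- withr::local_tempdir()
  gp <- file.path(td, "g.tsv"); pp <- file.path(td, "p.tsv")
  mp <- file.path(td, "m.tsv")
  writeLines(c("sample_id\ta", "s1\t0", "s2\t1"), gp)
  writeLines(c("snp_id\tchromosome\tregion\tposition_bp", "a\tc1\tc1\t5"), mp)
  writeLines(c("sample_id\tpopulation", "s1\tP", "sX\tP"), pp)
  expect_error(read_genotypes(gp, pp, mp), "sX")
  writeLines(c("sample_id\tpopulation", "s1\tP"), pp)
  expect_error(read_genotypes(gp, pp, mp), "s2")

  # unsorted positions name the first offender
  expect_error(
    toy_ds(matrix(0:1, 2, 2), positions = c(500L, 400L)),
    "snp02")
})

test_that("simulated dataset round-trips through the VCF writer", {
  sim <- sim_population(seed = 42, n_regions = 2, snps_per_region = 15,
                        sample_n = 8)
  td <- withr::local_tempdir()
  vp <- file.path(td, "sim.vcf"); pp <- file.path(td, "pop.tsv")
  mp <- file.path(td, "map.tsv")
  write_genotypes_vcf(sim$ds, vp)
  write.table(sim$ds$samples, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$ds$snps, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  ds2 <- read_genotypes(vp, pp, mp)
  expect_identical(unname(ds2$calls), unname(sim$ds$calls))
})

test_that("minor allele frequency counts alleles among called genotypes", {
  expect_equal(minor_allele_freq(c(0, 0, 1, 1, 2)), 0.4)
  expect_equal(minor_allele_freq(c(0, 0, 0)), 0)
  expect_equal(minor_allele_freq(1), 0.5)
  expect_equal(minor_allele_freq(c(2, NA, 2)), 0)
  expect_error(minor_allele_freq(c(NA_integer_, NA_integer_)), "missing")
})

test_that("QC assigns failures to call-rate, monomorphic, then MAF in order", {
  # 20 samples; snp1 called in 15/20 (0.75 < 0.8); snp2 monomorphic in P1
  # but not P2; snp3 single het among 20 -> MAF 1/40 = 0.025 < 0.05;
  # snp4 clean
  calls <- cbind(
    snp1 = c(rep(0L, 8), rep(1L, 7), rep(NA, 5)),
    snp2 = rep(0L, 20),
    snp3 = c(1L, rep(0L, 19)),
    snp4 = rep(c(0L, 1L), 10))
  ds <- toy_ds(calls, populations = rep("P1", 20))
  # add a second population where snp2 is polymorphic
  ds2 <- genotype_dataset(
    rbind(ds$calls, matrix(c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L), 2, 4)),
    data.frame(sample_id = c(ds$samples$sample_id, "t1", "t2"),
               population = c(ds$samples$population, "P2", "P2")),
    ds$snps)
  qc <- apply_qc(ds2, "P1", call_rate_min = 0.8, maf_min = 0.05)
  r <- qc$report
  expect_equal(r$n_failed_callrate, 1)
  expect_equal(r$n_monomorphic, 1)
  expect_equal(r$n_low_maf, 1)
  expect_equal(r$n_retained, 1)
  expect_identical(qc$dataset$snps$snp_id, "snp04")
  # snp2 passes in P2, confirming monomorphism is population-specific
  qc2 <- apply_qc(ds2, "P2", maf_min = 0.05)
  expect_true("snp02" %in% qc2$dataset$snps$snp_id)
  # categories always sum to the panel size
  expect_equal(r$n_failed_callrate + r$n_monomorphic + r$n_low_maf +
                 r$n_retained, r$n_total)
})

test_that("QC is idempotent and monotone in the MAF threshold", {
  sim <- sim_population(seed = 9, n_regions = 2, snps_per_region = 30)
  q1 <- apply_qc(sim$ds, "POP", 0.8, 0.05)
  q2 <- apply_qc(q1$dataset, "POP", 0.8, 0.05)
  expect_identical(q2$dataset$calls, q1$dataset$calls)
  expect_equal(q2$report$n_retained, q1$report$n_retained)

  kept <- vapply(c(0, 0.05, 0.1, 0.2, 0.3),
                 function(m) apply_qc(sim$ds, "POP", 0.8, m)$report$n_retained,
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("male X calls can be excluded via the sex column flag", {
  calls <- cbind(snpA = c(1L, 1L, 1L, 1L), snpX = c(1L, 1L, 1L, 1L))
  ds <- toy_ds(calls, chromosome = c("c1", "X"), positions = c(100L, 100L))
  ds$samples$sex <- c("M", "M", "F", "F")
  # default: all treated as diploid, both SNPs fully called
  q0 <- apply_qc(ds, "P1", call_rate_min = 0.5, maf_min = 0)
  expect_equal(ncol(q0$dataset$calls), 2)
  expect_false(anyNA(q0$dataset$calls))
  # flag on: male X calls become missing (here dropping the X SNP's call
  # rate to 0.5, which the 0.8 threshold then rejects)
  q1 <- apply_qc(ds, "P1", call_rate_min = 0.8, maf_min = 0,
                 exclude_male_x = TRUE)
  expect_equal(q1$report$n_failed_callrate, 1)
  expect_identical(q1$dataset$snps$snp_id, "snp01")
})

test_that("QC handles empty outcomes without error", {
  ds <- toy_ds(matrix(0L, 4, 3))
  qc <- apply_qc(ds, "P1", 0.8, 0.05)
  expect_equal(qc$report$n_monomorphic, 3)
  expect_equal(ncol(qc$dataset$calls), 0)
  expect_error(apply_qc(ds, "nope"), "population")
})
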