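# Two-locus EM, LD measures, pairwise tables, background LD.

tbl <- function(...) matrix(c(...), 3, 3, byrow = TRUE)

test_that("EM equals direct haplotype counting when phase is unambiguous", {
  em <- two_locus_em(tbl(2, 0, 0,
                         0, 0, 0,
                         0, 0, 2))
  expect_equal(em$f_AB, 0.5, tolerance = 1e-12)
  expect_equal(em$f_ab, 0.5, tolerance = 1e-12)
  expect_equal(em$f_Ab + em$f_aB, 0, tolerance = 1e-12)
  m <- ld_measures(em)
  expect_equal(m$D, 0.25)
  expect_equal(m$r2, 1)
  # a mixed table without double heterozygotes is still exact counting
  em2 <- two_locus_em(tbl(3, 1, 0,
                          1, 0, 1,
                          0, 1, 3))
  n2 <- 2 * 10
  expect_equal(em2$f_AB, (2 * 3 + 1 + 1) / n2, tolerance = 1e-9)
  expect_true(em2$converged)
})

test_that("phase-uninformative tables resolve to a likelihood maximum and are flagged", {
  em <- two_locus_em(tbl(0, 0, 0,
                         0, 4, 0,
                         0, 0, 0))
  expect_true(em$degenerate)
  # the double-het-only likelihood 2(f_AB f_ab + f_Ab f_aB) is maximized at
  # perfect coupling/repulsion, not at the symmetric point
  orc <- em_grid_oracle(tbl(0, 0, 0, 0, 4, 0, 0, 0, 0))
  expect_equal(em$loglik, orc$loglik, tolerance = 1e-6)
  expect_true(any(abs(orc$tied_fAB - em$f_AB) < 1e-3))
})

test_that("coupling resolution matches the grid-search MLE", {
  counts <- tbl(2, 0, 0,
                0, 1, 0,
                0, 0, 2)
  em <- two_locus_em(counts)
  orc <- em_grid_oracle(counts)
  expect_equal(em$f_AB, 0.5, tolerance = 1e-3)
  expect_equal(em$f_ab, 0.5, tolerance = 1e-3)
  expect_true(any(abs(orc$tied_fAB - em$f_AB) < 1e-3))
})

test_that("EM matches the grid-search MLE on random tables", {
  withr::local_seed(71)
  for (k in 1:40) {
    counts <- random_geno_table(40)
    em <- two_locus_em(counts)
    orc <- em_grid_oracle(counts)
    expect_gte(em$loglik, orc$loglik - 1e-6)
    expect_true(any(abs(orc$tied_fAB - em$f_AB) < 1e-3),
                info = paste("table", k))
  }
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  withr::local_seed(5)
  for (k in 1:20) {
    em <- two_locus_em(random_geno_table(30))
    tr <- em$loglik_trace[is.finite(em$loglik_trace)]
    expect_true(all(diff(tr) >= -1e-9))
  }
})

test_that("EM rejects monomorphic loci", {
  expect_error(two_locus_em(tbl(2, 2, 0, 0, 0, 0, 0, 0, 0)), "monomorphic")
})

test_that("LD measures reproduce hand-computed values", {
  expect_equal(ld_measures(c(0.5, 0, 0, 0.5)),
               list(D = 0.25, abs_dprime = 1, r2 = 1))
  # independence
  m <- ld_measures(c(0.35, 0.35, 0.15, 0.15))  # pA = 0.7, pB = 0.5, D = 0
  expect_equal(m$D, 0, tolerance = 1e-12)
  expect_equal(m$r2, 0, tolerance = 1e-12)
  expect_equal(m$abs_dprime, 0)
  m2 <- ld_measures(c(0.4, 0.1, 0.1, 0.4))
  expect_equal(m2$D, 0.15)
  expect_equal(m2$r2, 0.36)
  expect_equal(m2$abs_dprime, 0.6)
  expect_error(ld_measures(c(1, 0, 0, 0)), "monomorphic")
})

test_that("r2 never exceeds squared |D'| and label swaps leave both unchanged", {
  withr::local_seed(11)
  for (k in 1:50) {
    counts <- random_geno_table(40)
    m <- ld_measures(two_locus_em(counts))
    expect_lte(m$r2, m$abs_dprime^2 + 1e-9)
    # swap allele labels at locus A (reverse rows), then at locus B
    mA <- ld_measures(two_locus_em(counts[3:1, ]))
    mB <- ld_measures(two_locus_em(counts[, 3:1]))
    expect_equal(mA$r2, m$r2, tolerance = 1e-6)
    expect_equal(mA$abs_dprime, m$abs_dprime, tolerance = 1e-6)
    expect_equal(mB$r2, m$r2, tolerance = 1e-6)
    expect_equal(mB$abs_dprime, m$abs_dprime, tolerance = 1e-6)
  }
})

test_that("pairwise LD tables enumerate intra-chromosome pairs only", {
  withr::local_seed(2)
  calls <- matrix(sample(0:2, 120, replace = TRUE), nrow = 12)
  ds <- toy_ds(calls, chromosome = rep(c("c1", "c2"), each = 5),
               positions = rep(1:5 * 1000L, 2))
  tab <- pairwise_ld_region(ds)
  expect_equal(nrow(tab), 2 * choose(5, 2))
  expect_true(all(!tab$inter_chromosome))
  expect_true(all(tab$chrom %in% c("c1", "c2")))
  # three SNPs on one chromosome -> exactly C(3,2) pairs
  ds3 <- toy_ds(calls[, 1:3])
  expect_equal(nrow(pairwise_ld_region(ds3)), 3)
})

test_that("pairs are computed on pairwise-complete individuals", {
  calls <- cbind(c(0L, 1L, 2L, 0L, 1L, NA),
                 c(0L, 1L, 2L, NA, 1L, 2L))
  ds <- toy_ds(calls)
  tab <- pairwise_ld_region(ds)
  expect_equal(tab$n_used, 4)  # rows 1,2,3,5
  # monomorphic-after-deletion pairs are dropped and counted
  calls2 <- cbind(c(0L, 0L, 0L, 1L), c(NA, 0L, 1L, NA))
  tab2 <- suppressWarnings(pairwise_ld_region(toy_ds(calls2)))
  expect_equal(nrow(tab2), 0)
  expect_equal(attr(tab2, "n_dropped_monomorphic"), 1)
})

test_that("EM r2 tracks the squared dosage correlation on true haplotypes", {
  sim <- sim_population(seed = 21, n_regions = 1, snps_per_region = 30,
                        sample_n = 50, missing_rate = 0,
                        bcfg = breed_config("POP", founder_count = 40,
                                            bottleneck_Ne = 40,
                                            bottleneck_generations = 5,
                                            expansion_Ne = 80,
                                            total_generations = 15,
                                            sample_n = 50))
  qc <- apply_qc(sim$ds, "POP", 0.8, 0.05)
  tab <- pairwise_ld_region(qc$dataset)
  H <- sim$truth[[1]]
  idx <- match(qc$dataset$snps$snp_id, sim$map$snp_id)
  r2_true <- mapply(function(a, b) {
    ia <- idx[match(a, qc$dataset$snps$snp_id)]
    ib <- idx[match(b, qc$dataset$snps$snp_id)]
    suppressWarnings(cor(H[, ia], H[, ib])^2)
  }, tab$snp_a, tab$snp_b)
  keep <- is.finite(r2_true)
  expect_gt(sum(keep), 50)
  expect_lt(mean(abs(tab$r2[keep] - r2_true[keep])), 0.02)
})

test_that("background LD reflects independence and perfect duplication", {
  withr::local_seed(33)
  n <- 100
  c1 <- matrix(rbinom(n * 10, 2, 0.4), n, 10)
  c2 <- matrix(rbinom(n * 10, 2, 0.4), n, 10)
  ds_ind <- toy_ds(cbind(c1, c2), chromosome = rep(c("c1", "c2"), each = 10),
                   positions = rep(1:10 * 1000L, 2))
  bg <- background_ld(ds_ind, maf_min = 0.1)
  expect_lt(bg$mean_r2, 0.05)
  expect_equal(bg$n_pairs, 100)

  # second chromosome duplicating the first's genotypes column-for-column:
  # with one shared underlying haplotype pattern every cross pair is perfect
  dup <- matrix(rep(c1[, 1], 6), n, 6)
  ds_dup <- toy_ds(dup, chromosome = rep(c("c1", "c2"), each = 3),
                   positions = rep(1:3 * 1000L, 2))
  expect_gt(background_ld(ds_dup, maf_min = 0.1)$mean_r2, 0.99)

  expect_error(background_ld(toy_ds(c1), maf_min = 0.1), "two chromosomes")
})
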