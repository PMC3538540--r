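# Heterozygosity/Fis, Tajima's D, Hudson Fst, NJ trees, feature correlation.

test_that("heterozygosity and Fis reproduce the hand-computed toy case", {
  # one SNP, 10 individuals, 6 hets, p = 0.5
  calls <- matrix(c(2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L), ncol = 1)
  h <- heterozygosity_fis(toy_ds(calls))
  expect_equal(h$Ho, 0.6)
  expect_equal(h$He, 0.5 * 20 / 19, tolerance = 1e-12)
  expect_equal(h$Fis, 1 - 0.6 / (0.5 * 20 / 19), tolerance = 1e-4)
  expect_equal(round(h$Fis, 2), -0.14)

  # all homozygous at p = 0.5: full heterozygote deficit
  calls2 <- matrix(c(0L, 0L, 2L, 2L), ncol = 1)
  h2 <- heterozygosity_fis(toy_ds(calls2))
  expect_equal(h2$Ho, 0)
  expect_equal(h2$Fis, 1)
})

test_that("Fis is near zero under Hardy-Weinberg sampling", {
  withr::local_seed(3)
  fis <- sapply(1:6, function(k) {
    p <- runif(30, 0.2, 0.8)
    calls <- sapply(p, function(pp) rbinom(500, 2, pp))
    heterozygosity_fis(toy_ds(calls))$Fis
  })
  expect_lt(mean(abs(fis)), 0.02)
})

test_that("Tajima's D matches the independent constant evaluation", {
  # 2 diploids = 4 sequences, one singleton site
  calls <- matrix(c(1L, 0L), ncol = 1)
  d <- tajimas_d(toy_ds(calls))
  # independent evaluation: pi = 3/6 pairwise differences = 0.5,
  # theta_W = 1/a1 with a1 = 1 + 1/2 + 1/3
  a1 <- 1 + 1 / 2 + 1 / 3; a2 <- 1 + 1 / 4 + 1 / 9
  b1 <- 5 / 9; b2 <- 2 * (16 + 4 + 3) / (9 * 4 * 3)
  c1 <- b1 - 1 / a1; c2 <- b2 - 6 / (4 * a1) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  expect_equal(d, (0.5 - 1 / a1) / sqrt(e1 + 0), tolerance = 1e-9)
  expect_equal(round(d, 3), -0.612)
})

test_that("Tajima's D is undefined without segregating sites and label-invariant", {
  expect_true(is.na(tajimas_d(toy_ds(matrix(0L, 5, 3)))))
  withr::local_seed(13)
  calls <- sapply(runif(12, 0.1, 0.9), function(p) rbinom(10, 2, p))
  d1 <- tajimas_d(toy_ds(calls))
  d2 <- tajimas_d(toy_ds(2L - calls))  # swap which allele is reference
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("Hudson Fst reproduces the worked single-SNP value and bounds", {
  # p1 = 0.8, p2 = 0.2, 20 diploid individuals each
  mk <- function(p, n = 20) matrix(rbinom(n, 2, p), ncol = 1)
  dsA <- toy_ds(matrix(c(rep(2L, 12), rep(1L, 8)), ncol = 1))   # p = 0.8
  dsB <- toy_ds(matrix(c(rep(0L, 12), rep(1L, 8)), ncol = 1))   # p = 0.2
  f <- pairwise_fst(dsA, dsB)
  num <- 0.36 - 2 * (0.8 * 0.2 / 19)
  expect_equal(num, 0.34316, tolerance = 1e-4)
  expect_equal(f, num / 0.68, tolerance = 1e-9)
  expect_equal(f, 0.5047, tolerance = 1e-3)
  # symmetry and label-swap invariance
  expect_equal(pairwise_fst(dsB, dsA), f, tolerance = 1e-12)
  expect_equal(pairwise_fst(toy_ds(2L - dsA$calls), toy_ds(2L - dsB$calls)),
               f, tolerance = 1e-12)
  # fixed difference
  expect_equal(pairwise_fst(toy_ds(matrix(2L, 5, 2)),
                            toy_ds(matrix(0L, 5, 2))), 1)
})

test_that("Fst is near zero for two samples of one panmictic population", {
  withr::local_seed(17)
  p <- runif(100, 0.2, 0.8)
  mk <- function() sapply(p, function(pp) rbinom(100, 2, pp))
  f <- pairwise_fst(toy_ds(mk()), toy_ds(mk()))
  expect_lt(abs(f), 0.01)
})

test_that("Fst matrix is symmetric with zero diagonal", {
  sim <- sim_population(seed = 29, n_regions = 2, snps_per_region = 25,
                        sample_n = 12)
  ds2 <- sim_population(seed = 30, n_regions = 2, snps_per_region = 25,
                        sample_n = 12)$ds
  # different populations over the same panel requires a shared map; build
  # two populations from one simulation instead
  sim3 <- sim_population(seed = 31, n_regions = 2, snps_per_region = 25,
                         sample_n = 12)
  dsB <- genotype_dataset(sim3$ds$calls,
                          data.frame(sample_id = paste0("b_", sim3$ds$samples$sample_id),
                                     population = "P2"),
                          sim$map)
  all <- genotype_dataset(rbind(sim$ds$calls, dsB$calls),
                          rbind(sim$ds$samples, dsB$samples), sim$map)
  m <- fst_matrix(all)
  expect_true(isSymmetric(unclass(m)[,]))
  expect_equal(unname(diag(unclass(m))), c(0, 0))
  expect_true(all(unclass(m) >= 0 & unclass(m) <= 1))
})

test_that("NJ solves the 3-taxon case in closed form", {
  m <- matrix(c(0, 2, 4,
                2, 0, 4,
                4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(m)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
})

test_that("NJ recovers additive matrices exactly", {
  withr::local_seed(43)
  for (k in 1:20) {
    ntax <- sample(4:8, 1)
    tr0 <- ape::rtree(ntax, rooted = FALSE,
                      br = function(n) runif(n, 0.1, 1))
    dm <- ape::cophenetic.phylo(tr0)
    dm <- dm[sort(rownames(dm)), sort(colnames(dm))]
    tr <- nj_tree(dm)
    # path-length matrix reproduced
    dm2 <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
    expect_equal(dm2, dm, tolerance = 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(tr0), tr), setNames(0, "PH85"),
                 ignore_attr = TRUE)
  }
})

test_that("NJ rejects malformed input and clamps negative branches", {
  m <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_error(nj_tree(m), "symmetric")
  # strongly non-additive matrix can produce a negative internal branch
  m2 <- matrix(c(0, 1, 1, 1,
                 1, 0, 1, 1,
                 1, 1, 0, 1,
                 1, 1, 1, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(m2)  # equidistant: all terminal branches equal
  term <- tr$edge.length[tr$edge[, 2] <= 4]
  expect_equal(term, rep(term[1], 4), tolerance = 1e-12)
  expect_true(all(tr$edge.length >= 0))
})

test_that("feature correlation matches the covariance formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(feature_correlation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  withr::local_seed(47)
  a <- rnorm(10); b <- rnorm(10)
  fc <- feature_correlation(a, b)
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(fc$r, r_direct, tolerance = 1e-12)
  expect_error(feature_correlation(rep(1, 5), 1:5), "variance")
})

test_that("population summary covers every population-region cell", {
  sim <- sim_population(seed = 53, n_regions = 2, snps_per_region = 20,
                        sample_n = 10)
  s <- pop_summary(sim$ds)
  expect_equal(nrow(s), 2)
  expect_true(all(s$Ho >= 0 & s$Ho <= 1, na.rm = TRUE))
  expect_true(all(s$He >= 0 & s$He <= 1, na.rm = TRUE))
  expect_equal(s$Fis, 1 - s$Ho / s$He, tolerance = 1e-9)
})
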