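test_that("simulations are reproducible under a seed", {
  m <- population_model(4, 0.3, 15, 0.002)
  g1 <- sim_genotypes(c(0.6, 0.3, 0.1), m, 50, seed = 42)
  g2 <- sim_genotypes(c(0.6, 0.3, 0.1), m, 50, seed = 42)
  expect_identical(g1, g2)
  d1 <- sim_allele_depth(g1, 20, m, seed = 43)
  d2 <- sim_allele_depth(g1, 20, m, seed = 43)
  expect_identical(d1, d2)
  c1 <- sim_benchmark_cohort(m, n_ind = 20, n_mendelian = 5, n_paralogs = 5,
                             seed = 44)
  c2 <- sim_benchmark_cohort(m, n_ind = 20, n_mendelian = 5, n_paralogs = 5,
                             seed = 44)
  expect_identical(c1$mendelian$loci, c2$mendelian$loci)
  expect_identical(c1$paralogs$loci, c2$paralogs$loci)
})

test_that("genotype simulation honors the inbreeding coefficient", {
  ## F = 1: every individual fully autozygous
  g <- sim_genotypes(c(0.5, 0.5), population_model(4, 1), 300, seed = 1)
  expect_true(all(g %in% c(0L, 4L)))
  ## F = 0, diploid: heterozygote fraction ~ 2pq (binomial check, 3 SE)
  g0 <- sim_genotypes(c(0.5, 0.5), population_model(2, 0), 10000, seed = 2)
  het <- mean(g0[, 1] == 1L)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 10000))
  ## F = 0.5, diploid, p = 0.9/0.1: het fraction ~ (1 - F) 2pq = 0.09
  g5 <- sim_genotypes(c(0.9, 0.1), population_model(2, 0.5), 20000, seed = 3)
  het5 <- mean(g5[, 1] == 1L)
  expect_lt(abs(het5 - 0.09), 3 * sqrt(0.09 * 0.91 / 20000))
  ## rows always sum to the ploidy
  gm <- sim_genotypes(c(0.2, 0.5, 0.3), population_model(6, 0.4), 500, seed = 4)
  expect_true(all(rowSums(gm) == 6L))
})

test_that("any two allele copies are identical by state with rate F + (1-F) sum(p^2)", {
  ## pairwise identity is exactly F for IBD plus random coincidence otherwise;
  ## checked for a polyploid where construction subtleties would show up
  p <- c(0.5, 0.5); F <- 0.3; n <- 20000
  g <- sim_genotypes(p, population_model(4, F), n, seed = 9)
  ## probability two copies of an individual match, sampled without replacement
  ibs <- mean(rowSums(g * (g - 1)) / (4 * 3))
  expected <- F + (1 - F) * sum(p^2)
  expect_lt(abs(ibs - expected), 3 * 0.35 / sqrt(n))
})

test_that("read depths follow dosage under low noise and spread under overdispersion", {
  m_inf <- population_model(2, 0, 1e6, 0)
  g <- matrix(c(1L, 1L), 1)
  d <- sim_allele_depth(g[rep(1, 2000), ], rep(1000L, 2000), m_inf, seed = 5)
  ratio <- d[, 1] / rowSums(d)
  expect_lt(abs(mean(ratio) - 0.5), 3 * sd(ratio) / sqrt(2000))
  ## homozygote with no error: single-allele reads, zero diversity
  hom <- sim_allele_depth(matrix(c(2L, 0L), 1)[rep(1, 50), ], 20,
                          population_model(2, 0, 20, 0), seed = 6)
  expect_true(all(hom[, 2] == 0L))
  expect_true(all(hind_individual(hom) %in% c(0, NA)))
  ## variance ordering in the overdispersion parameter
  v <- sapply(c(5, 20), function(od) {
    dd <- sim_allele_depth(g[rep(1, 5000), ], rep(20L, 5000),
                           population_model(2, 0, od, 0), seed = 7)
    var(dd[, 1] / rowSums(dd))
  })
  expect_gt(v[1], v[2])
})

test_that("per-read errors move the expected fraction of reads", {
  m <- population_model(2, 0, 20, 0.3)
  d <- sim_allele_depth(matrix(c(2L, 0L), 1)[rep(1, 400), ], rep(50L, 400),
                        m, seed = 8)
  moved <- sum(d[, 2]) / sum(d)
  expect_lt(abs(moved - 0.3), 3 * sqrt(0.3 * 0.7 / sum(d)))
  ## monomorphic locus gains a dummy error column
  d1 <- sim_allele_depth(matrix(2L, 10, 1), rep(30L, 10),
                         population_model(2, 0, 20, 0.1), seed = 9)
  expect_equal(ncol(d1), 2L)
})

test_that("collapsed paralogs combine two loci and inflate the statistic", {
  m <- population_model(2, 0, 20, 0)
  ## two monomorphic components, equal fixed depths: every individual is an
  ## artificial balanced heterozygote; H_ind/H_E = D/(D-1) at D = 10
  d <- sim_collapsed_paralog(1, 1, m, 40, rep(5L, 40), rep(5L, 40), seed = 10)
  expect_equal(ncol(d), 2L)
  r <- hindhe(d)
  expect_equal(unname(r$locus_means), 10 / 9, tolerance = 1e-12)
  ## depth additivity of the components
  d2 <- sim_collapsed_paralog(c(0.7, 0.3), c(0.9, 0.1), m, 500, 20, 20,
                              seed = 11)
  expect_lt(abs(mean(rowSums(d2)) - 40), 3)
  ## polymorphic paralogs sit above the Mendelian expectation
  means <- replicate(60, {
    dd <- sim_collapsed_paralog(c(0.95, 0.05), c(0.95, 0.05), m, 200, 20, 20)
    hindhe(dd)$locus_means
  })
  expect_gt(mean(means, na.rm = TRUE), 0.55)
})

test_that("null alleles depress the statistic monotonically", {
  m <- population_model(2, 0, 20, 0.001)
  grand <- sapply(c(0.01, 0.1, 0.3), function(nf) {
    means <- replicate(150, {
      d <- sim_null_allele_locus(0.25, nf, m, 300, 20)
      hindhe(d)$locus_means
    })
    mean(means, na.rm = TRUE)
  })
  expect_true(all(diff(grand) < 0))
  expect_error(sim_null_allele_locus(0.2, 1, m, 10, 20), "null_freq")
})

test_that("benchmark cohort construction matches its stated recipe", {
  m <- population_model(2, 0.1, 20, 0.001)
  coh <- sim_benchmark_cohort(m, n_ind = 60, n_mendelian = 150,
                              n_paralogs = 80, seed = 12)
  expect_equal(length(coh$mendelian), 150L)
  expect_equal(length(coh$paralogs), 80L)
  na <- coh$mendelian$info$n_alleles
  expect_true(all(na >= 2 & na <= 8))
  ## frequency construction: sums to one, rare alleles at least 0.01
  for (f in coh$mendelian_freqs[1:20]) {
    expect_equal(sum(f), 1)
    if (length(f) > 1) expect_true(all(f[-1] >= 0.01))
  }
  ## paralogs carry the union of two components (2..16 alleles)
  expect_true(all(coh$paralogs$info$n_alleles >= 2 &
                    coh$paralogs$info$n_alleles <= 16))
  ## skipping paralogs works
  coh0 <- sim_benchmark_cohort(m, n_ind = 20, n_mendelian = 10,
                               n_paralogs = 0, seed = 13)
  expect_null(coh0$paralogs)
})

test_that("gamma depth hierarchy has the requested mean", {
  D <- sim_genotype_depths(20000, 20, seed = 14)
  expect_true(all(D >= 0))
  expect_lt(abs(mean(D) - 20), 0.4)
  ## heavier spread than Poisson: the signature of the gamma hierarchy
  expect_gt(var(D), 2 * 20)
})
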