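test_that("within-individual diversity matches the Gini-Simpson arithmetic", {
  expect_equal(hind_individual(c(5, 5)), 0.5 * 10 / 9)
  expect_equal(hind_individual(c(10, 0)), 0)
  expect_equal(hind_individual(c(1, 1)), 1)
  expect_true(is.na(hind_individual(c(0, 1))))
  expect_true(is.na(hind_individual(c(0, 0))))
  expect_error(hind_individual(c(-1, 2)), "non-negative")
})

test_that("estimator equals the unordered read-pair enumeration oracle", {
  set.seed(7)
  for (case in 1:60) {
    j <- sample(1:4, 1)
    d <- rmultinom(1, sample(0:30, 1), rep(1, j))[, 1]
    expect_equal(hind_individual(d), pair_oracle(d),
                 info = paste("depths:", paste(d, collapse = ",")))
  }
})

test_that("diversity is permutation-invariant and bounded in [0, 1]", {
  set.seed(11)
  for (case in 1:40) {
    d <- rmultinom(1, sample(2:40, 1), runif(sample(2:5, 1)))[, 1]
    h <- hind_individual(d)
    expect_identical(h, hind_individual(rev(d)))
    expect_gte(h, 0); expect_lte(h, 1)
  }
})

test_that("allele frequencies are unweighted means of depth ratios", {
  expect_equal(unname(allele_frequencies(rbind(c(10, 0), c(0, 10)))),
               c(0.5, 0.5))
  expect_equal(unname(allele_frequencies(matrix(c(3, 1), 1))), c(0.75, 0.25))
  expect_equal(unname(allele_frequencies(rbind(c(2, 0), c(2, 0), c(1, 1)))),
               c(5 / 6, 1 / 6))
  ## zero-depth rows do not enter the denominator
  expect_equal(unname(allele_frequencies(rbind(c(3, 1), c(0, 0)))),
               c(0.75, 0.25))
  expect_error(allele_frequencies(rbind(c(0, 0))), "undefined")
})

test_that("expected heterozygosity is one minus the frequency sum of squares", {
  expect_equal(expected_het(c(0.5, 0.5)), 0.5)
  expect_equal(expected_het(1), 0)
  expect_equal(expected_het(c(0.9, 0.05, 0.05)), 1 - 0.815)
  expect_error(expected_het(c(0.5, 0.4)), "sum to 1")
})

test_that("the statistic behaves correctly on canonical loci", {
  ## fixed homozygotes: polymorphic in the population, monomorphic in reads
  r <- hindhe(rbind(c(10, 0), c(0, 10)))
  expect_equal(unname(r$locus_means), 0)
  ## every individual an even heterozygote: value above one
  r2 <- hindhe(depth_dataset(list(L = rbind(c(5, 5), c(5, 5), c(5, 5)))))
  expect_equal(unname(r2$locus_means), (0.5 * 10 / 9) / 0.5)
  ## monomorphic reads everywhere: H_E = 0, locus missing
  r3 <- hindhe(rbind(c(9, 0), c(7, 0)))
  expect_true(is.na(r3$locus_means))
  ## all-zero locus stays missing, others unaffected
  ds <- depth_dataset(list(a = rbind(c(5, 5), c(5, 5)),
                           b = rbind(c(0, 0), c(0, 0))))
  r4 <- hindhe(ds)
  expect_true(is.na(r4$locus_means["b"]))
  expect_false(is.na(r4$locus_means["a"]))
})

test_that("locus and individual means use finite entries only", {
  ds <- depth_dataset(list(
    L1 = rbind(c(5, 5), c(1, 0), c(4, 0)),   # middle row below two reads
    L2 = rbind(c(0, 0), c(0, 0), c(6, 6))))
  r <- hindhe(ds)
  expect_equal(unname(r$n_used), c(2L, 1L))
  expect_equal(unname(r$locus_means[1]),
               mean(r$values[c(1, 3), 1]))
  expect_equal(unname(r$individual_means[2]), r$values[2, 2])
})

test_that("closed-form expectation and inbreeding inversion agree", {
  expect_equal(expected_hindhe_value(2), 0.5)
  expect_equal(expected_hindhe_value(4), 0.75)
  expect_equal(expected_hindhe_value(2, inbreeding = 1), 0)
  expect_equal(expected_hindhe_value(population_model(4, 0.5)), 0.375)
  expect_equal(estimate_inbreeding(0.5, 2), 0)
  expect_equal(estimate_inbreeding(0.375, 4), 0.5)
  expect_warning(f <- estimate_inbreeding(0.6, 2), "exceeds")
  expect_equal(f, 0)
  ## round trip through the expectation
  for (k in c(2, 4, 6)) for (F in c(0, 0.3, 0.8))
    expect_equal(estimate_inbreeding(expected_hindhe_value(k, F), k), F)
})

test_that("histogram mode finds the bulk of a peaked distribution", {
  set.seed(5)
  v <- c(rnorm(2000, 0.48, 0.03), runif(200, 0.7, 1.2))
  expect_lt(abs(hindhe_mode(v) - 0.48), 0.03)
})

test_that("result object methods summarize without altering values", {
  m <- population_model(2)
  ds <- sim_dataset(m, 30, 12, maf = 0.3, mean_depth = 20, seed = 2)
  r <- hindhe(ds)
  expect_s3_class(r, "hindhe_result")
  expect_identical(as.matrix(r), r$values)
  expect_output(print(r), "individuals x 12 loci")
  s <- summary(r)
  expect_output(print(s), "Per-locus means")
  ## plot returns a histogram invisibly
  pdf(NULL); h <- plot(r); dev.off()
  expect_true(is.list(h))
})
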