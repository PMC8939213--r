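test_that("cross designs are validated", {
  expect_error(cross_design(3, c(2, 1), c(3, 0)), "even")
  expect_error(cross_design(2, c(2, 1), c(2, 0)), "sum to the ploidy")
  expect_error(cross_design(4, c(3, 2), c(4, 0)), "sum to the ploidy")
  d <- cross_design(4, c(3, 1), c(4, 0))
  expect_equal(d$parent2, c(4L, 0L))
  expect_output(print(d), "3/1 x 4/0")
})

test_that("cross expectation matches closed forms for diploid crosses", {
  expect_lt(abs(he_map(cross_design(2, c(1, 1), c(2, 0)), 5e4, seed = 1) - 0.5),
            0.01)
  expect_lt(abs(he_map(cross_design(2, c(1, 1), c(1, 1)), 5e4, seed = 2) - 0.5),
            0.01)
})

test_that("cross expectation agrees with exhaustive gamete enumeration", {
  for (nm in names(f1_marker_types)) {
    ty <- f1_marker_types[[nm]]
    exact <- he_map_enum(ty$k, ty$p1, ty$p2)
    mc <- he_map(cross_design(ty$k, ty$p1, ty$p2), n_sim = 2e4,
                 seed = 100 + match(nm, names(f1_marker_types)))
    ## per-progeny values lie in [0, 1]: 3 conservative binomial SEs
    expect_lt(abs(mc - exact), 3 * 0.5 / sqrt(2e4),
              label = paste(nm, "MC vs enumeration"))
  }
  ## frozen enumeration values for the classic tetraploid cases
  expect_equal(he_map_enum(4, c(3, 1), c(4, 0)), 0.25)
  expect_equal(he_map_enum(4, c(2, 2), c(4, 0)), 4 / 9, tolerance = 1e-12)
  expect_equal(he_map_enum(4, c(1, 3), c(4, 0)), 7 / 12, tolerance = 1e-12)
})

test_that("backcrossing and selfing reduce progeny heterozygosity as expected", {
  ## selfing halves heterozygosity each generation in diploids
  f2 <- cross_design(2, c(1, 1), c(1, 1))
  f3 <- cross_design(2, c(1, 1), c(1, 1), n_gen_self = 1)
  f4 <- cross_design(2, c(1, 1), c(1, 1), n_gen_self = 2)
  expect_lt(abs(he_map(f3, 5e4, seed = 3) - 0.25), 0.01)
  expect_lt(abs(he_map(f4, 5e4, seed = 4) - 0.125), 0.01)
  ## backcross of (Aa x aa) F1 to the heterozygous recurrent parent
  bc <- cross_design(2, c(1, 1), c(2, 0), n_gen_backcross = 1)
  expect_lt(abs(he_map(bc, 5e4, seed = 5) - 0.5), 0.01)
})

test_that("mapping statistic flags an all-heterozygote locus", {
  d <- matrix(10L, 4, 2)
  des <- cross_design(2, c(1, 1), c(2, 0))
  r <- hindhe_mapping(d, des, n_sim = 5e4, seed = 6)
  ## every progeny at [10,10]: H_ind = 0.5 * 20/19, expectation 0.5
  expect_equal(unname(r$locus_means), (0.5 * 20 / 19) / 0.5, tolerance = 0.02)
  expect_gt(unname(r$locus_means), 1)
})

test_that("monomorphic crosses are missing with a warning", {
  ds <- depth_dataset(list(m1 = rbind(c(10, 0), c(12, 0))))
  des <- cross_design(2, c(2, 0), c(2, 0))
  expect_warning(r <- hindhe_mapping(ds, des, n_sim = 1000), "monomorphic")
  expect_true(all(is.na(r$values)))
})

test_that("simulated mapping populations center near the deflated expectation", {
  model <- population_model(2, 0, 20, 0.001)
  des <- cross_design(2, c(1, 1), c(2, 0))
  ds <- sim_mapping_population(des, model, 300, 150, mean_depth = 20, seed = 7)
  r <- hindhe_mapping(ds, des, n_sim = 1e5, seed = 8)
  ## overdispersion od = 20 deflates the mean by od/(od+1)
  expect_lt(abs(mean(r$locus_means) - 0.5 * 20 / 21), 0.02)
  expect_equal(unname(r$expected), 0.5)
})

test_that("high-heterozygosity tetraploid crosses have tighter locus means", {
  sd_tri <- sd(f1_locus_means("triplex_x_nulliplex", 250, n_ind = 300,
                              seed = 21))
  sd_sim <- sd(f1_locus_means("simplex_x_nulliplex", 250, n_ind = 300,
                              seed = 22))
  expect_lt(sd_tri, sd_sim)
})

test_that("per-locus cross designs load from TSV", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("locus\tparent1\tparent2", "L1\t3/1\t4/0", "L2\t2/2\t2/2"),
             path)
  des <- read_cross_designs(path, ploidy = 4)
  expect_equal(names(des), c("L1", "L2"))
  expect_equal(des$L1$parent1, c(3L, 1L))
  expect_equal(des$L2$parent2, c(2L, 2L))
})
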