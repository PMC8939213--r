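## Lazily computed, cached simulations shared by the acceptance tests (the
## same cohorts feed several criteria; simulating them once keeps the suite
## fast).  Seeds are fixed so the cached objects are reproducible.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- force(expr)
  .cohort_cache[[key]]
}

## one benchmark cohort with the per-locus values of the three
## genotype-free statistics
benchmark_cohort_stats <- function(ploidy, inbreeding) {
  key <- sprintf("bench_%d_%g", ploidy, inbreeding)
  cached(key, {
    model <- population_model(ploidy, inbreeding,
                              overdispersion = 20, error_rate = 0.001)
    seed <- 100L * ploidy + round(10 * inbreeding)
    coh <- sim_benchmark_cohort(model, n_ind = 200, n_mendelian = 1000,
                                n_paralogs = 1000, seed = seed)
    list(
      mend_lm = hindhe(coh$mendelian)$locus_means,
      para_lm = hindhe(coh$paralogs)$locus_means,
      hap_m = haplotype_count_stat(coh$mendelian, ploidy),
      hap_p = haplotype_count_stat(coh$paralogs, ploidy),
      dep_m = mean_depth_stat(coh$mendelian),
      dep_p = mean_depth_stat(coh$paralogs),
      freqs = unlist(coh$mendelian_freqs),
      mend_depth_means = coh$mendelian$info$mean_depth)
  })
}

## proportion of paralogs exceeding the Mendelian percentile threshold
filtered_proportion <- function(mend, para, percentile = 95) {
  thr <- one_sided_threshold(mend, percentile)
  pv <- para[is.finite(para)]
  list(prop = mean(pv > thr), n = length(pv), threshold = thr)
}

## grand mean of per-locus values for one diversity-panel design
panel_grand_mean <- function(ploidy, inbreeding, maf, n_ind, n_loci,
                             mean_depth, error_rate = 0.001, od = 20,
                             seed = 1) {
  model <- population_model(ploidy, inbreeding, od, error_rate)
  ds <- sim_dataset(model, n_ind, n_loci, maf = maf, mean_depth = mean_depth,
                    seed = seed)
  mean(hindhe(ds)$locus_means, na.rm = TRUE)
}

## per-locus mean values for one F1 marker type
f1_locus_means <- function(type_name, n_loci, n_ind = 500, mean_depth = 20,
                           seed = 1) {
  ty <- f1_marker_types[[type_name]]
  key <- sprintf("f1_%s_%d_%d", type_name, n_loci, seed)
  cached(key, {
    model <- population_model(ty$k, 0, 20, 0.001)
    des <- cross_design(ty$k, ty$p1, ty$p2)
    ds <- sim_mapping_population(des, model, n_ind, n_loci,
                                 mean_depth = mean_depth, seed = seed)
    hindhe_mapping(ds, des, n_sim = 2e5, seed = seed + 1)$locus_means
  })
}
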