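## Dataset-matched filtering thresholds.  Because the variance of the
## statistic has no closed form, cutoffs are obtained by simulating Mendelian
## loci that mirror the empirical dataset's sample size, allele frequency
## spectrum and depth distribution, and taking quantiles of the simulated
## per-locus means.

#' Simulate the Mendelian reference distribution and filtering interval
#'
#' Each simulated locus copies one randomly chosen real locus: its estimated
#' allele frequencies (from depth ratios) and its per-individual total depth
#' column are taken together, preserving any frequency-depth association;
#' genotypes and allelic depths are then re-simulated under the supplied
#' population model as if the locus were Mendelian.  Quantiles of the
#' resulting per-locus means give the interval retaining a chosen fraction of
#' Mendelian loci.
#'
#' @param x A [depth_dataset()] with at least 10 loci (for smaller problems
#'   specify frequencies and depths directly via the simulator functions).
#' @param model A [population_model()] for the dataset (ploidy, inbreeding,
#'   overdispersion, error rate).
#' @param n_sim_loci Number of Mendelian loci to simulate.
#' @param retain_fraction Central probability mass to retain (default 0.95).
#' @param seed Optional integer seed.
#' @return An object of class `hindhe_thresholds`: list with `lower`,
#'   `upper`, `retain_fraction`, and `sim_locus_means` (the simulated
#'   distribution, for plotting or alternative quantiles).
#' @export
expected_hindhe <- function(x, model, n_sim_loci = 5000,
                            retain_fraction = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ds <- as_depth_dataset(x)
  L <- length(ds$loci)
  if (L < 10) stop("fewer than 10 loci: too few to resample; ",
                   "simulate from a parametric spec instead")
  if (retain_fraction <= 0 || retain_fraction >= 1)
    stop("retain_fraction must be in (0, 1)")
  freqs <- lapply(ds$loci, allele_frequencies)
  depths <- lapply(ds$loci, rowSums)
  pick <- sample.int(L, n_sim_loci, replace = TRUE)
  means <- vapply(pick, function(l) {
    d <- sim_allele_depth(sim_genotypes(freqs[[l]], model, length(depths[[l]])),
                          depths[[l]], model)
    he <- expected_het(allele_frequencies(d))
    if (he == 0) return(NA_real_)
    mean(.hind_rows(d) / he, na.rm = TRUE)
  }, 0)
  a <- (1 - retain_fraction) / 2
  q <- quantile(means, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  structure(list(lower = q[1], upper = q[2],
                 retain_fraction = retain_fraction,
                 sim_locus_means = means),
            class = "hindhe_thresholds")
}

#' @method print hindhe_thresholds
#' @export
print.hindhe_thresholds <- function(x, ...) {
  cat(sprintf(
    "H_ind/H_E interval retaining %.0f%% of simulated Mendelian loci: [%.3f, %.3f]\n",
    100 * x$retain_fraction, x$lower, x$upper))
  invisible(x)
}

#' One-sided percentile threshold from a Mendelian reference distribution
#'
#' The upper percentile of per-locus statistic values among known (or
#' simulated) Mendelian loci; loci exceeding it are candidate paralogs.
#'
#' @param mendelian_locus_means Numeric vector of per-locus values (at least
#'   100 finite values).
#' @param percentile Percentile to report, default 95.
#' @return The empirical percentile (linear interpolation between order
#'   statistics).
#' @export
one_sided_threshold <- function(mendelian_locus_means, percentile = 95) {
  v <- mendelian_locus_means[is.finite(mendelian_locus_means)]
  if (length(v) < 100)
    stop("need at least 100 finite values for a stable percentile")
  quantile(v, percentile / 100, names = FALSE)
}

#' Partition loci by statistic thresholds and mean depth
#'
#' Deterministic four-way partition: loci whose mean depth falls outside
#' `[min_mean_depth, max_mean_depth]` (or whose statistic is missing) are
#' `depth_excluded`; remaining loci are `too_low`, `retained`, or `too_high`
#' by their per-locus mean statistic.  Very shallow loci (mean depth below
#' about five) tend to carry artefactually low values and are excluded by
#' default.
#'
#' @param result A `hindhe_result` (see [hindhe()]).
#' @param lower,upper Finite thresholds, `lower < upper` (e.g. from
#'   [expected_hindhe()]).
#' @param min_mean_depth,max_mean_depth Depth limits (defaults 5 and `Inf`).
#' @return A list of class `hindhe_partition` with character vectors
#'   `retained`, `too_low`, `too_high`, `depth_excluded`, and a `counts`
#'   summary.
#' @export
filter_loci <- function(result, lower, upper, min_mean_depth = 5,
                        max_mean_depth = Inf) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("need finite thresholds with lower < upper")
  lm <- result$locus_means
  dep <- result$locus_depth_means
  ids <- names(lm)
  bad_depth <- dep < min_mean_depth | dep > max_mean_depth | !is.finite(lm)
  out <- list(
    retained = ids[!bad_depth & lm >= lower & lm <= upper],
    too_low = ids[!bad_depth & lm < lower],
    too_high = ids[!bad_depth & lm > upper],
    depth_excluded = ids[bad_depth])
  out$counts <- vapply(out, length, 0L)
  message("locus filter: ", paste(names(out$counts), out$counts,
                                  sep = "=", collapse = ", "))
  class(out) <- "hindhe_partition"
  out
}

#' @method print hindhe_partition
#' @export
print.hindhe_partition <- function(x, ...) {
  cat("Locus partition:\n")
  print(x$counts)
  invisible(x)
}

#' Flag individuals with outlying mean statistic
#'
#' Robust z-scores (median/MAD) of per-individual mean values.  Large
#' positive scores suggest unexpected ploidy, interspecific hybridity, or
#' sample mixtures; large negative scores suggest inbred or misassigned
#' samples.  No hard cutoff is imposed: outliers should be confirmed by
#' independent means (e.g. flow cytometry).
#'
#' @param result A `hindhe_result`.
#' @return Data frame with `individual`, `mean_hindhe`, `zscore`, ordered by
#'   decreasing absolute score.
#' @export
individual_outliers <- function(result) {
  im <- result$individual_means
  med <- median(im, na.rm = TRUE)
  s <- mad(im, na.rm = TRUE)
  z <- if (s > 0) (im - med) / s else rep(NA_real_, length(im))
  out <- data.frame(individual = names(im), mean_hindhe = unname(im),
                    zscore = unname(z), stringsAsFactors = FALSE)
  out[order(-abs(out$zscore)), , drop = FALSE]
}
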