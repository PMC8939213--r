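## Alternative paralog-screening statistics and the benchmark harness that
## compares them.  Two of them (observed/expected heterozygosity and the
## depth-ratio Z-score) need discrete genotypes, supplied by a deliberately
## simple single-pass empirical-Bayes caller: Dirichlet-multinomial read
## likelihood times a Hardy-Weinberg-with-inbreeding prior, posterior mode.

## all dosage vectors of j alleles summing to k, as a matrix (rows = genotypes)
.compositions_cache <- new.env(parent = emptyenv())
.compositions <- function(k, j) {
  key <- paste(k, j)
  if (!is.null(g <- .compositions_cache[[key]])) return(g)
  g <- if (j == 1L) matrix(k, 1, 1) else {
    do.call(rbind, lapply(0:k, function(a)
      cbind(a, .compositions(k - a, j - 1L))))
  }
  dimnames(g) <- NULL
  .compositions_cache[[key]] <- g
  g
}

## log prior P(g) under the Dirichlet-multinomial genotype model used by the
## simulator (multinomial at F = 0; fully autozygous at F = 1)
.genotype_log_prior <- function(G, freqs, F) {
  k <- sum(G[1, ]); j <- ncol(G)
  lchoosek <- lgamma(k + 1) - rowSums(lgamma(G + 1))
  if (F <= 0) {
    lp <- matrix(rep(log(freqs), each = nrow(G)), nrow(G), j)
    term <- G * lp
    term[G == 0] <- 0  # 0 * log(0) -> 0
    return(lchoosek + rowSums(term))
  }
  if (F >= 1) {
    out <- rep(-Inf, nrow(G))
    hom <- which(rowSums(G == k) == 1L)
    for (h in hom) out[h] <- log(freqs[which(G[h, ] == k)])
    return(out)
  }
  theta <- (1 - F) / F
  a <- matrix(rep(theta * freqs, each = nrow(G)), nrow(G), j)
  term <- lgamma(a + G) - lgamma(a)
  term[a == 0 & G == 0] <- 0
  term[a == 0 & G > 0] <- -Inf
  lchoosek + lgamma(theta) - lgamma(theta + k) + rowSums(term)
}

#' Call discrete genotypes from allelic depths
#'
#' Single-pass empirical-Bayes caller: allele frequencies are estimated from
#' depth ratios, a Hardy-Weinberg-with-inbreeding prior is placed on all
#' dosage vectors summing to the ploidy, the read likelihood is
#' Dirichlet-multinomial with concentration
#' `overdispersion * expected read fractions` (sequencing error folded into
#' the fractions), and the posterior mode is returned.  Individuals with
#' fewer than two reads are missing.  This caller exists to feed the
#' comparator statistics; it is not a genotyping product.
#'
#' @param depths Depth matrix for one locus.
#' @param model A [population_model()].
#' @param freqs Optional allele frequencies (estimated from `depths` by
#'   default).
#' @return Integer dosage matrix (`NA` rows for uncallable individuals).
#' @export
call_genotypes <- function(depths, model, freqs = NULL) {
  d <- as.matrix(depths)
  n <- nrow(d); j <- ncol(d)
  k <- model$ploidy; od <- model$overdispersion; err <- model$error_rate
  if (is.null(freqs)) freqs <- allele_frequencies(d)
  G <- .compositions(k, j)
  tau <- G / k
  if (j > 1L && err > 0)
    tau <- tau * (1 - err) + (1 - tau) * err / (j - 1)
  alpha <- od * tau  # rows sum to od for every genotype
  ## log-likelihood up to genotype-independent constants
  ll <- matrix(.genotype_log_prior(G, freqs, model$inbreeding),
               n, nrow(G), byrow = TRUE)
  for (i in seq_len(j)) {
    t1 <- lgamma(outer(d[, i], alpha[, i], "+"))
    t2 <- matrix(lgamma(alpha[, i]), n, nrow(G), byrow = TRUE)
    tt <- t1 - t2
    if (any(zero <- alpha[, i] == 0)) {  # impossible allele: -Inf unless d = 0
      tt[, zero] <- ifelse(d[, i] > 0, -Inf, 0)
    }
    ll <- ll + tt
  }
  best <- max.col(ll, ties.method = "first")
  out <- G[best, , drop = FALSE]
  out[rowSums(d) < 2, ] <- NA_integer_
  dimnames(out) <- dimnames(d)
  out
}

## shared computation of the two caller-based statistics, one locus
.caller_locus_stats <- function(d, model) {
  k <- model$ploidy
  freqs <- tryCatch(allele_frequencies(d), error = function(e) NULL)
  if (is.null(freqs)) return(c(ho_he = NA_real_, zscore = NA_real_))
  g <- call_genotypes(d, model, freqs)
  called <- !is.na(g[, 1])
  ho_he <- NA_real_
  he <- expected_het(freqs)
  if (any(called) && he > 0) {
    ho <- 1 - rowSums(g[called, , drop = FALSE] *
                        (g[called, , drop = FALSE] - 1)) / (k * (k - 1))
    ho_he <- mean(ho) / he
  }
  ## depth-ratio Z among genotypes with k-1 copies of the most common allele
  a <- which.max(freqs)  # ties: lowest index
  z <- NA_real_
  sel <- called & g[, a] == (k - 1L)
  if (any(sel, na.rm = TRUE)) {
    sel[is.na(sel)] <- FALSE
    N <- sum(rowSums(d[sel, , drop = FALSE]))
    NA_ <- sum(d[sel, a])
    if (N > 0) z <- abs(((k - 1) / k * N - NA_) / sqrt(N * (k - 1) / k / k))
  }
  c(ho_he = ho_he, zscore = z)
}

#' Observed over expected heterozygosity per locus
#'
#' Genotypes are called with [call_genotypes()]; observed heterozygosity per
#' individual is the probability that two alleles sampled from the called
#' genotype without replacement differ, averaged over callable individuals
#' and divided by expected heterozygosity.  Effective at flagging paralogs
#' but requires genotype calling, the very step the depth-based statistic is
#' designed to precede.
#'
#' @param x A [depth_dataset()] or depth matrix.
#' @param model A [population_model()].
#' @return Named numeric vector, one value per locus (`NA` where no
#'   individual is callable or the locus is monomorphic).
#' @export
ho_over_he <- function(x, model) {
  ds <- as_depth_dataset(x)
  vapply(ds$loci, function(d) .caller_locus_stats(d, model)[["ho_he"]], 0)
}

#' Absolute depth-ratio Z-score per locus
#'
#' Among individuals called with exactly `ploidy - 1` copies of the locus's
#' most common allele (the heterozygote class expected to be most common),
#' the summed depth of that allele is compared with its binomial expectation:
#' `Z = ((k-1)/k * N - N_A) / sqrt(N * (k-1)/k * 1/k)`.  Collapsed paralogs
#' distort the depth ratio and inflate `|Z|`.
#'
#' @inheritParams ho_over_he
#' @return Named numeric vector of `|Z|` per locus (`NA` where the
#'   heterozygote class is empty).
#' @export
depth_ratio_zscore <- function(x, model) {
  ds <- as_depth_dataset(x)
  vapply(ds$loci, function(d) .caller_locus_stats(d, model)[["zscore"]], 0)
}

#' Proportion of individuals with more haplotypes than the ploidy
#'
#' Counts, per individual, the alleles with read depth of `min_depth` or
#' more; the statistic is the proportion of individuals (among those with at
#' least one counted allele) whose count exceeds the ploidy.  Fast and
#' genotype-free, but insensitive in polyploids and inbred populations where
#' few individuals carry more than `k` distinguishable alleles even at a
#' collapsed paralog.
#'
#' @param x A [depth_dataset()] or depth matrix.
#' @param ploidy Integer ploidy `k`.
#' @param min_depth Reads required to count an allele as present (default 3).
#' @return Named numeric vector, one proportion per locus.
#' @export
haplotype_count_stat <- function(x, ploidy, min_depth = 3) {
  ds <- as_depth_dataset(x)
  vapply(ds$loci, function(d) {
    cnt <- rowSums(d >= min_depth)
    use <- cnt >= 1L
    if (!any(use)) return(NA_real_)
    mean(cnt[use] > ploidy)
  }, 0)
}

#' Mean read depth per locus
#'
#' The naive filter: collapsed paralogs attract the reads of all their
#' copies, so deep loci are suspect — but depth varies strongly among loci
#' for technical reasons, limiting its discrimination.
#'
#' @param x A [depth_dataset()] or depth matrix.
#' @return Named numeric vector of mean total depth per locus.
#' @export
mean_depth_stat <- function(x) {
  ds <- as_depth_dataset(x)
  vapply(ds$loci, function(d) mean(rowSums(d)), 0)
}

#' Benchmark paralog-filtering statistics on simulated cohorts
#'
#' For each ploidy and inbreeding level, simulates a cohort of Mendelian
#' loci and collapsed paralogs ([sim_benchmark_cohort()]), determines each
#' statistic's threshold as the chosen percentile among Mendelian loci, and
#' reports the proportion of paralogs exceeding it (with binomial standard
#' error).
#'
#' @param ploidies Integer vector of ploidies.
#' @param inbreeding_levels Numeric vector of inbreeding coefficients.
#' @param statistics Subset of
#'   `c("hindhe", "ho_he", "hap_count", "zscore", "mean_depth")`.  The two
#'   caller-based statistics dominate the runtime.
#' @param n_ind,n_mendelian,n_paralogs Cohort dimensions.
#' @param overdispersion,error_rate Read-depth model parameters.
#' @param percentile Mendelian percentile used as threshold (default 95).
#' @param seed Optional integer seed.
#' @return Data frame of class `paralog_benchmark`: one row per statistic x
#'   cohort with `threshold`, `prop_filtered`, `se`.
#' @export
run_benchmark <- function(ploidies = c(2L, 4L),
                          inbreeding_levels = c(0.1, 0.5, 0.9),
                          statistics = c("hindhe", "ho_he", "hap_count",
                                         "zscore", "mean_depth"),
                          n_ind = 200, n_mendelian = 1000, n_paralogs = 1000,
                          overdispersion = 20, error_rate = 0.001,
                          percentile = 95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  statistics <- match.arg(statistics, several.ok = TRUE)
  rows <- list()
  for (k in ploidies) for (F in inbreeding_levels) {
    model <- population_model(k, F, overdispersion, error_rate)
    coh <- sim_benchmark_cohort(model, n_ind, n_mendelian, n_paralogs)
    vals <- list()
    if ("hindhe" %in% statistics) {
      vals$hindhe <- list(m = hindhe(coh$mendelian)$locus_means,
                          p = hindhe(coh$paralogs)$locus_means)
    }
    if (any(c("ho_he", "zscore") %in% statistics)) {
      cm <- vapply(coh$mendelian$loci, .caller_locus_stats, c(0, 0), model = model)
      cp <- vapply(coh$paralogs$loci, .caller_locus_stats, c(0, 0), model = model)
      if ("ho_he" %in% statistics)
        vals$ho_he <- list(m = cm["ho_he", ], p = cp["ho_he", ])
      if ("zscore" %in% statistics)
        vals$zscore <- list(m = cm["zscore", ], p = cp["zscore", ])
    }
    if ("hap_count" %in% statistics)
      vals$hap_count <- list(m = haplotype_count_stat(coh$mendelian, k),
                             p = haplotype_count_stat(coh$paralogs, k))
    if ("mean_depth" %in% statistics)
      vals$mean_depth <- list(m = mean_depth_stat(coh$mendelian),
                              p = mean_depth_stat(coh$paralogs))
    for (s in names(vals)) {
      thr <- one_sided_threshold(vals[[s]]$m, percentile)
      pv <- vals[[s]]$p[is.finite(vals[[s]]$p)]
      prop <- mean(pv > thr)
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = s, ploidy = k, inbreeding = F, threshold = thr,
        prop_filtered = prop, se = sqrt(prop * (1 - prop) / length(pv)),
        n_paralogs = length(pv), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("paralog_benchmark", "data.frame")
  out
}

#' @method print paralog_benchmark
#' @export
print.paralog_benchmark <- function(x, digits = 3, ...) {
  cat("Paralog filtering benchmark (proportion filtered at the Mendelian",
      "percentile threshold):\n")
  y <- as.data.frame(x)
  y$prop_filtered <- sprintf(paste0("%.", digits, "f +/- %.", digits, "f"),
                             y$prop_filtered, y$se)
  y$threshold <- signif(y$threshold, 3)
  print(y[, c("statistic", "ploidy", "inbreeding", "threshold",
              "prop_filtered")], row.names = FALSE)
  invisible(x)
}
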