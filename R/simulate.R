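## Simulation of genotypes and allelic read depths.  Two layers of
## randomness: genotypes from allele frequencies under inbreeding, and read
## depths from genotypes under a Dirichlet-multinomial with per-read error.
## Every test fixture in the package is produced by these generators.

## row-wise multinomial via sequential conditional binomials (vectorized over
## rows; rmultinom itself cannot take a matrix of probabilities)
.rowwise_multinom <- function(size, prob) {
  n <- nrow(prob); j <- ncol(prob)
  out <- matrix(0L, n, j)
  rem <- as.integer(size)
  pleft <- rep(1, n)
  for (i in seq_len(j)) {
    pi <- ifelse(pleft > 0, pmin(pmax(prob[, i] / pleft, 0), 1), 0)
    di <- rbinom(n, rem, pi)
    out[, i] <- di
    rem <- rem - di
    pleft <- pleft - prob[, i]
  }
  out
}

## row-wise Dirichlet draws; rows whose gamma draws all underflow to zero
## (possible at very small concentrations) collapse to a single allele chosen
## with probability proportional to the concentration, the correct limit
.dirichlet_rows <- function(alpha) {
  n <- nrow(alpha); j <- ncol(alpha)
  g <- matrix(rgamma(n * j, shape = alpha), n, j)
  rs <- rowSums(g)
  bad <- which(rs == 0)
  for (b in bad) {
    g[b, ] <- 0
    g[b, sample.int(j, 1L, prob = alpha[b, ])] <- 1
    rs[b] <- 1
  }
  g / rs
}

## per-read sequencing error: each read is reassigned, with probability err,
## to an allele drawn uniformly from the other columns
.apply_read_errors <- function(d, err) {
  if (err <= 0) return(d)
  j <- ncol(d)
  if (j < 2L) stop("read errors need at least two allele columns")
  n <- nrow(d)
  d0 <- d  # errors drawn from the original counts: each read flips once
  for (i in seq_len(j)) {
    e <- rbinom(n, d0[, i], err)
    if (!any(e > 0)) next
    d[, i] <- d[, i] - e
    others <- setdiff(seq_len(j), i)
    rem <- e
    for (o in seq_along(others)) {
      ei <- rbinom(n, rem, 1 / (length(others) - o + 1))
      d[, others[o]] <- d[, others[o]] + ei
      rem <- rem - ei
    }
  }
  d
}

#' Simulate genotypes from allele frequencies under inbreeding
#'
#' Allele copies are drawn by a Polya urn with concentration
#' `theta = (1 - F)/F` times the allele frequencies, i.e. dosages follow a
#' Dirichlet-multinomial (the Balding-Nichols model generalized to ploidy
#' `k`).  Any two copies within an individual are identical by descent with
#' probability exactly `F`; `F = 0` reduces to independent draws
#' (Hardy-Weinberg) and `F = 1` to fully autozygous individuals.
#'
#' @param freqs Allele frequency vector (sums to one).
#' @param model A [population_model()]; only `ploidy` and `inbreeding` are
#'   used.
#' @param n Number of individuals.
#' @param seed Optional integer seed.
#' @return Integer dosage matrix, `n` x `length(freqs)`, rows summing to the
#'   ploidy.
#' @examples
#' sim_genotypes(c(0.5, 0.5), population_model(2, inbreeding = 1), 5, seed = 1)
#' @export
sim_genotypes <- function(freqs, model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(freqs) - 1) > 1e-6) stop("freqs must sum to 1")
  k <- model$ploidy; F <- model$inbreeding
  j <- length(freqs)
  if (j == 1L) return(matrix(rep(k, n), n, 1))
  if (F == 0) return(t(rmultinom(n, k, freqs)))
  if (F >= 1) {
    g <- matrix(0L, n, j)
    g[cbind(seq_len(n), sample.int(j, n, replace = TRUE, prob = freqs))] <- k
    return(g)
  }
  theta <- (1 - F) / F
  w <- .dirichlet_rows(matrix(theta * freqs, n, j, byrow = TRUE))
  .rowwise_multinom(rep(k, n), w)
}

#' Per-genotype read depths for a locus of given mean depth
#'
#' Genotype total depths are drawn from a gamma distribution with shape
#' `mean_depth/10` and scale 10 (mean `mean_depth`, echoing the strong
#' depth heterogeneity of multiplexed GBS libraries), rounded to integers.
#'
#' @param n Number of individuals.
#' @param mean_depth Mean total read depth of the locus.
#' @param seed Optional integer seed.
#' @return Integer vector of total depths (zeros possible at low means).
#' @export
sim_genotype_depths <- function(n, mean_depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as.integer(round(rgamma(n, shape = mean_depth / 10, scale = 10)))
}

#' Simulate allelic read depths from genotypes
#'
#' For each individual, allele proportions are drawn from a Dirichlet with
#' concentration `overdispersion * dosage/ploidy` and read counts
#' multinomially from those proportions; each read is then independently
#' misassigned with probability `error_rate` to a uniformly chosen other
#' allele.  For a monomorphic locus (one column) a dummy error-allele column
#' is appended when `error_rate > 0`.
#'
#' @param dosages Integer dosage matrix (individuals x alleles, rows summing
#'   to the ploidy), as from [sim_genotypes()].
#' @param depth Either a single number, interpreted as the locus mean depth
#'   fed to [sim_genotype_depths()], or an integer vector of per-individual
#'   total depths (use `rep(d, n)` for strictly fixed depth).
#' @param model A [population_model()].
#' @param seed Optional integer seed.
#' @return Integer depth matrix of the same shape as `dosages` (plus a dummy
#'   column in the monomorphic case).
#' @examples
#' g <- sim_genotypes(c(0.5, 0.5), population_model(2), 10, seed = 1)
#' sim_allele_depth(g, 20, population_model(2), seed = 2)
#' @export
sim_allele_depth <- function(dosages, depth, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- as.matrix(dosages)
  n <- nrow(g); j <- ncol(g)
  k <- model$ploidy
  if (any(rowSums(g) != k)) stop("dosage rows must sum to the ploidy")
  D <- if (length(depth) == 1L) sim_genotype_depths(n, depth) else as.integer(round(depth))
  if (length(D) != n) stop("depth vector must have one entry per individual")
  w <- .dirichlet_rows(model$overdispersion * g / k)
  d <- .rowwise_multinom(D, w)
  if (model$error_rate > 0) {
    if (j == 1L) d <- cbind(d, 0L)  # dummy error allele
    d <- .apply_read_errors(d, model$error_rate)
  }
  colnames(d) <- if (ncol(d) == j && !is.null(colnames(g))) colnames(g) else
    paste0("a", seq_len(ncol(d)))
  rownames(d) <- rownames(g)
  d
}

#' Simulate one Mendelian locus
#'
#' Convenience wrapper: genotypes via [sim_genotypes()], depths via
#' [sim_allele_depth()].
#'
#' @inheritParams sim_genotypes
#' @inheritParams sim_allele_depth
#' @return Integer depth matrix (individuals x alleles).
#' @export
sim_locus <- function(freqs, model, n, depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim_allele_depth(sim_genotypes(freqs, model, n), depth, model)
}

#' Simulate a panel of biallelic Mendelian loci
#'
#' The workhorse for diversity-panel experiments: `n_loci` independent
#' biallelic loci at a fixed minor allele frequency, one shared mean depth.
#'
#' @param model A [population_model()].
#' @param n_ind Number of individuals.
#' @param n_loci Number of loci.
#' @param maf Minor allele frequency shared by all loci.
#' @param mean_depth Locus mean depth (see [sim_genotype_depths()]).
#' @param seed Optional integer seed.
#' @return A [depth_dataset()].
#' @export
sim_dataset <- function(model, n_ind, n_loci, maf = 0.05, mean_depth = 20,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]")
  freqs <- c(1 - maf, maf)
  loci <- lapply(seq_len(n_loci), function(l)
    sim_locus(freqs, model, n_ind, mean_depth))
  names(loci) <- sprintf("sim%05d", seq_len(n_loci))
  depth_dataset(loci)
}

#' Allele frequency vector with one common and several rare alleles
#'
#' Emulates the frequency spectrum seen after standard variant-calling MAF
#' filters: each non-common allele frequency is `gamma(shape 0.3, scale 1)/10
#' + 0.01` (minimum minor allele frequency 0.01) and the common allele takes
#' the complement; vectors whose rare frequencies sum to one or more are
#' redrawn.
#'
#' @param n_alleles Number of alleles (1 returns the monomorphic vector `1`).
#' @param seed Optional integer seed.
#' @return Frequency vector of length `n_alleles`, common allele first.
#' @export
sim_allele_frequencies <- function(n_alleles, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_alleles < 1L) stop("n_alleles must be >= 1")
  if (n_alleles == 1L) return(1)
  repeat {
    rare <- rgamma(n_alleles - 1L, shape = 0.3, scale = 1) / 10 + 0.01
    if (sum(rare) < 1) return(c(1 - sum(rare), rare))
  }
}

#' Simulate a collapsed paralog
#'
#' Two independent Mendelian loci — each with its own allele frequencies,
#' genotypes, and locus depth — whose reads are erroneously attributed to a
#' single locus: the depth matrices are concatenated column-wise over
#' disjoint allele sets.  Because every individual then carries reads from
#' two segregating systems, the combined locus shows inflated within-
#' individual diversity.  Read errors are applied on the combined allele set.
#'
#' @param freqs1,freqs2 Component allele frequency vectors.
#' @param model A [population_model()].
#' @param n Number of individuals.
#' @param depth1,depth2 Per-component depth specifications (see
#'   [sim_allele_depth()]).
#' @param seed Optional integer seed.
#' @return Integer depth matrix with `length(freqs1) + length(freqs2)`
#'   columns.
#' @export
sim_collapsed_paralog <- function(freqs1, freqs2, model, n, depth1, depth2,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  noerr <- population_model(model$ploidy, model$inbreeding,
                            model$overdispersion, 0)
  d1 <- sim_allele_depth(sim_genotypes(freqs1, model, n), depth1, noerr)
  d2 <- sim_allele_depth(sim_genotypes(freqs2, model, n), depth2, noerr)
  d <- cbind(d1, d2)
  colnames(d) <- paste0("a", seq_len(ncol(d)))
  .apply_read_errors(d, model$error_rate)
}

#' Simulate a locus with a null allele
#'
#' A triallelic Mendelian locus in which one allele yields no reads (e.g. a
#' restriction-site or primer-site mutation, or a deletion): after read
#' simulation the null allele's depth column is discarded.  Individuals
#' carrying the null allele lose reads, depressing the locus's apparent
#' within-individual diversity.
#'
#' @param maf Frequency of the minor *visible* allele.
#' @param null_freq Frequency of the null allele (must be `< 1`).
#' @param model A [population_model()].
#' @param n Number of individuals.
#' @param depth Depth specification (see [sim_allele_depth()]).
#' @param seed Optional integer seed.
#' @return Integer depth matrix with two (visible) allele columns.
#' @export
sim_null_allele_locus <- function(maf, null_freq, model, n, depth,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (null_freq < 0 || null_freq >= 1) stop("null_freq must be in [0, 1)")
  if (maf + null_freq >= 1) stop("maf + null_freq must be < 1")
  freqs <- c(1 - maf - null_freq, maf, null_freq)
  g <- sim_genotypes(freqs, model, n)
  d <- sim_allele_depth(g, depth, model)
  d[, 1:2, drop = FALSE]
}

#' Simulate a paralog-filtering benchmark cohort
#'
#' One cohort of the cross-method benchmark: `n_mendelian` well-behaved loci
#' (2-8 alleles, frequencies from [sim_allele_frequencies()]) and
#' `n_paralogs` collapsed paralogs (two components of 1-8 alleles each),
#' in `n_ind` individuals.  Locus mean depths are gamma(shape 3.2, scale 8);
#' per-genotype depths follow the gamma hierarchy of
#' [sim_genotype_depths()].
#'
#' @param model A [population_model()] giving ploidy, inbreeding,
#'   overdispersion and error rate (benchmark defaults: overdispersion 20,
#'   error rate 0.001).
#' @param n_ind Number of individuals (benchmark: 200).
#' @param n_mendelian,n_paralogs Locus counts (benchmark: 1000 each;
#'   `n_paralogs = 0` skips paralog simulation).
#' @param seed Optional integer seed.
#' @return A list of class `benchmark_cohort`: `mendelian` and `paralogs`
#'   ([depth_dataset()]s, the latter `NULL` when skipped), and
#'   `mendelian_freqs` (list of true frequency vectors, for auditing the
#'   simulated frequency spectrum).
#' @export
sim_benchmark_cohort <- function(model, n_ind = 200, n_mendelian = 1000,
                                 n_paralogs = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mfreqs <- lapply(sample(2:8, n_mendelian, replace = TRUE),
                   sim_allele_frequencies)
  mend <- lapply(mfreqs, function(p)
    sim_locus(p, model, n_ind, rgamma(1, shape = 3.2, scale = 8)))
  names(mend) <- sprintf("mend%04d", seq_len(n_mendelian))
  para <- NULL
  if (n_paralogs > 0) {
    para <- lapply(seq_len(n_paralogs), function(l) {
      p1 <- sim_allele_frequencies(sample(1:8, 1))
      p2 <- sim_allele_frequencies(sample(1:8, 1))
      sim_collapsed_paralog(p1, p2, model, n_ind,
                            rgamma(1, shape = 3.2, scale = 8),
                            rgamma(1, shape = 3.2, scale = 8))
    })
    names(para) <- sprintf("para%04d", seq_len(n_paralogs))
    para <- depth_dataset(para)
  }
  structure(list(mendelian = depth_dataset(mend), paralogs = para,
                 mendelian_freqs = mfreqs),
            class = "benchmark_cohort")
}

#' @method print benchmark_cohort
#' @export
print.benchmark_cohort <- function(x, ...) {
  cat("Benchmark cohort:", length(x$mendelian$loci), "Mendelian loci,",
      if (is.null(x$paralogs)) 0 else length(x$paralogs$loci),
      "collapsed paralogs,", length(x$mendelian$individual_ids),
      "individuals\n")
  invisible(x)
}
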