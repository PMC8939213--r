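## Core statistic.  Per individual and locus, H_ind is the probability that
## two reads sampled without replacement carry different alleles, estimated by
## the bias-corrected Gini-Simpson index of the allelic depth vector.
## Dividing by expected heterozygosity H_E gives a quantity whose expectation,
## (k-1)/k * (1-F), is free of allele frequency and read depth.

## vectorized Gini-Simpson over the rows of a depth matrix; NA where D < 2
.hind_rows <- function(d) {
  D <- rowSums(d)
  h <- (1 - rowSums((d / D)^2)) * D / (D - 1)
  h[D < 2] <- NA_real_
  h
}

#' Within-individual allelic diversity of a read depth vector
#'
#' Estimates the probability that two reads sampled without replacement from
#' one individual at one locus represent different alleles, using the
#' Gini-Simpson index with the finite-sample correction `D/(D - 1)`.
#'
#' @param depths Non-negative integer vector of per-allele read counts for one
#'   individual, or a matrix with individuals in rows.
#' @return A probability in `[0, 1]`, or `NA` when fewer than two reads are
#'   present (a vector when `depths` is a matrix).
#' @examples
#' hind_individual(c(5, 5))   # (1 - 0.5) * 10/9
#' hind_individual(c(10, 0))  # 0
#' hind_individual(c(1, 1))   # 1: two reads, two alleles
#' hind_individual(c(0, 1))   # NA: below the two-read minimum
#' @export
hind_individual <- function(depths) {
  if (is.matrix(depths)) return(.hind_rows(depths))
  if (any(depths < 0) || any(depths != round(depths)))
    stop("depths must be non-negative integers")
  drop(.hind_rows(matrix(depths, nrow = 1)))
}

#' Allele frequencies from within-individual depth ratios
#'
#' Each individual with at least one read contributes its vector of read
#' proportions; frequencies are the unweighted mean of those proportions, so
#' deeply sequenced individuals do not dominate the estimate.
#'
#' @param depths Depth matrix for one locus (individuals x alleles).
#' @return Numeric vector of allele frequencies summing to one.
#' @examples
#' allele_frequencies(rbind(c(10, 0), c(0, 10)))  # 0.5, 0.5
#' allele_frequencies(rbind(c(2, 0), c(2, 0), c(1, 1)))  # 5/6, 1/6
#' @export
allele_frequencies <- function(depths) {
  d <- as.matrix(depths)
  D <- rowSums(d)
  use <- D >= 1
  if (!any(use)) stop("allele frequencies undefined: no individual has reads")
  p <- colMeans(d[use, , drop = FALSE] / D[use])
  setNames(p, colnames(d))
}

#' Expected heterozygosity
#'
#' The Gini-Simpson index of a frequency vector: the probability that two
#' alleles drawn at random from the population differ.
#'
#' @param freqs Numeric vector of allele frequencies summing to one.
#' @return `1 - sum(freqs^2)`.
#' @examples
#' expected_het(c(0.5, 0.5))        # 0.5
#' expected_het(1)                  # 0 (monomorphic)
#' @export
expected_het <- function(freqs) {
  if (abs(sum(freqs) - 1) > 1e-6) stop("freqs must sum to 1")
  1 - sum(freqs^2)
}

#' Compute the H_ind/H_E matrix for a dataset
#'
#' For every individual and locus, divides the within-individual read
#' diversity ([hind_individual()]) by the locus's expected heterozygosity
#' estimated from depth ratios.  Entries are missing where an individual has
#' fewer than two reads or where the locus is monomorphic (`H_E = 0`).
#' Per-locus means flag problem loci (values above the `(k-1)/k * (1-F)`
#' expectation suggest collapsed paralogs; values below suggest null alleles
#' or overdispersion; zero suggests a cytoplasmic marker).  Per-individual
#' means flag unexpected ploidy, interspecific hybrids, or sample mixtures.
#'
#' @param x A [depth_dataset()] or a single depth matrix.
#' @return An object of class `hindhe_result`: list with `values`
#'   (individuals x loci matrix), `locus_means`, `individual_means`,
#'   `locus_depth_means`, and `n_used` (individuals entering each locus mean).
#'   Values above one are reported as-is; they are the paralogy signal.
#' @examples
#' ds <- depth_dataset(list(
#'   fixed = rbind(c(10, 0), c(0, 10)),       # fixed homozygotes: mean 0
#'   allhet = rbind(c(5, 5), c(5, 5))))       # every read pair split: > 1
#' hindhe(ds)$locus_means
#' @export
hindhe <- function(x) {
  ds <- as_depth_dataset(x)
  n <- length(ds$individual_ids)
  L <- length(ds$loci)
  vals <- matrix(NA_real_, n, L,
                 dimnames = list(ds$individual_ids, names(ds$loci)))
  for (l in seq_len(L)) {
    d <- ds$loci[[l]]
    if (all(d == 0L)) next
    he <- expected_het(allele_frequencies(d))
    if (he == 0) next
    vals[, l] <- .hind_rows(d) / he
  }
  new_hindhe_result(vals, vapply(ds$loci, function(m) mean(rowSums(m)), 0))
}

new_hindhe_result <- function(values, locus_depth_means,
                              expected = NULL) {
  fin <- is.finite(values)
  lm <- colMeans(values, na.rm = TRUE)
  lm[colSums(fin) == 0L] <- NA_real_
  im <- rowMeans(values, na.rm = TRUE)
  im[rowSums(fin) == 0L] <- NA_real_
  structure(list(values = values,
                 locus_means = lm,
                 individual_means = im,
                 locus_depth_means = locus_depth_means,
                 n_used = colSums(fin),
                 expected = expected),
            class = "hindhe_result")
}

#' @method print hindhe_result
#' @export
print.hindhe_result <- function(x, ...) {
  cat("H_ind/H_E:", nrow(x$values), "individuals x", ncol(x$values), "loci\n")
  lm <- x$locus_means[is.finite(x$locus_means)]
  if (length(lm))
    cat(sprintf("  locus means: median %.3f  IQR [%.3f, %.3f]  (%d estimable loci)\n",
                median(lm), quantile(lm, 0.25), quantile(lm, 0.75), length(lm)))
  if (!is.null(x$expected))
    cat(sprintf("  expectation under Mendelian behavior: %.4f\n", x$expected))
  invisible(x)
}

#' @export
summary.hindhe_result <- function(object, ...) {
  lm <- object$locus_means
  im <- object$individual_means
  out <- list(
    n_individuals = nrow(object$values),
    n_loci = ncol(object$values),
    n_estimable = sum(is.finite(lm)),
    locus_quartiles = quantile(lm, c(0.05, 0.25, 0.5, 0.75, 0.95), na.rm = TRUE),
    individual_quartiles = quantile(im, c(0.05, 0.25, 0.5, 0.75, 0.95), na.rm = TRUE),
    expected = object$expected)
  class(out) <- "summary.hindhe_result"
  out
}

#' @method print summary.hindhe_result
#' @export
print.summary.hindhe_result <- function(x, ...) {
  cat("H_ind/H_E summary:", x$n_individuals, "individuals x", x$n_loci,
      "loci (", x$n_estimable, "estimable )\n")
  cat("Per-locus means:\n"); print(round(x$locus_quartiles, 4))
  cat("Per-individual means:\n"); print(round(x$individual_quartiles, 4))
  if (!is.null(x$expected))
    cat(sprintf("Mendelian expectation: %.4f\n", x$expected))
  invisible(x)
}

#' @export
as.matrix.hindhe_result <- function(x, ...) x$values

#' Histogram of per-locus means
#'
#' @param x A `hindhe_result`.
#' @param expected Optional expected value to mark with a dashed line (e.g.
#'   [expected_hindhe_value()]); defaults to the value stored in the result,
#'   if any.
#' @param breaks Passed to [graphics::hist()].
#' @param ... Further arguments passed to [graphics::hist()].
#' @return Invisibly, the histogram object.
#' @method plot hindhe_result
#' @export
plot.hindhe_result <- function(x, expected = x$expected, breaks = 50, ...) {
  lm <- x$locus_means[is.finite(x$locus_means)]
  h <- hist(lm, breaks = breaks, main = "Per-locus mean H_ind/H_E",
            xlab = "H_ind/H_E", ...)
  if (!is.null(expected)) abline(v = expected, lty = 2)
  invisible(h)
}

#' Modal per-locus value of the statistic
#'
#' Histogram-bin mode of the finite per-locus means, used to estimate
#' inbreeding (or screen ploidy) from the bulk of well-behaved loci.  Loci
#' with minor allele frequency below about 0.05 are best excluded by the
#' caller before taking the mode, since low-frequency loci are biased upward
#' by sequencing error.
#'
#' @param locus_means Numeric vector of per-locus means (or a
#'   `hindhe_result`).
#' @param binwidth Histogram bin width; the default 0.02 resolves the mode
#'   without chasing noise for a few thousand loci.
#' @return The midpoint of the most populated bin.
#' @export
hindhe_mode <- function(locus_means, binwidth = 0.02) {
  if (inherits(locus_means, "hindhe_result")) locus_means <- locus_means$locus_means
  v <- locus_means[is.finite(locus_means)]
  if (!length(v)) stop("no finite locus means")
  br <- seq(floor(min(v) / binwidth) * binwidth,
            ceiling(max(v) / binwidth) * binwidth + binwidth, by = binwidth)
  h <- hist(v, breaks = br, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Estimate the inbreeding coefficient from the modal statistic
#'
#' Inverts the Mendelian expectation `(k - 1)/k * (1 - F)`: given the modal
#' per-locus value of the statistic at well-behaved markers and the ploidy,
#' returns `F = 1 - mode * k/(k - 1)`, clipped to `[0, 1]`.
#'
#' @param observed_mode Modal per-locus H_ind/H_E (see [hindhe_mode()]),
#'   ideally over loci with minor allele frequency of at least 0.05.
#' @param ploidy Integer ploidy `k`.
#' @return Estimated inbreeding coefficient in `[0, 1]`.  A mode above
#'   `(k - 1)/k` is outside the Mendelian range; it returns 0 with a warning.
#' @examples
#' estimate_inbreeding(0.5, 2)      # 0
#' estimate_inbreeding(0.375, 4)    # 0.5
#' @export
estimate_inbreeding <- function(observed_mode, ploidy) {
  k <- as.integer(ploidy)
  if (is.na(k) || k < 2L) stop("ploidy must be an integer >= 2")
  if (observed_mode < 0) stop("observed_mode must be non-negative")
  if (observed_mode > (k - 1) / k) {
    warning("observed mode exceeds (k-1)/k; returning F = 0")
    return(0)
  }
  min(1, max(0, 1 - observed_mode * k / (k - 1)))
}
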