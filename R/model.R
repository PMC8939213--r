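#' Population model for expectations and simulation
#'
#' Collects the four parameters that determine both the expected value of the
#' statistic and the behavior of the read-depth simulator.
#'
#' @param ploidy Integer ploidy `k >= 2` (disomic or polysomic inheritance).
#' @param inbreeding Inbreeding coefficient `F` in `[0, 1]`: the probability
#'   that two allele copies in an individual are identical by descent.  It
#'   absorbs all sources of identity, including population structure.
#' @param overdispersion Positive concentration parameter of the
#'   Dirichlet-multinomial read-depth model.  Larger values keep allelic read
#'   depth ratios close to the underlying dosage ratios; smaller values make
#'   them noisier.  Typical RAD-seq values are around 10-20.
#' @param error_rate Per-read probability, in `[0, 1)`, that a read is
#'   assigned to a uniformly chosen wrong allele.
#' @return An object of class `population_model`.
#' @examples
#' population_model(ploidy = 4, inbreeding = 0.25)
#' @export
population_model <- function(ploidy = 2L, inbreeding = 0,
                             overdispersion = 20, error_rate = 0.001) {
  ploidy <- as.integer(ploidy)
  if (length(ploidy) != 1L || is.na(ploidy) || ploidy < 2L)
    stop("ploidy must be a single integer >= 2")
  if (inbreeding < 0 || inbreeding > 1) stop("inbreeding must be in [0, 1]")
  if (overdispersion <= 0) stop("overdispersion must be positive")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  structure(list(ploidy = ploidy, inbreeding = inbreeding,
                 overdispersion = overdispersion, error_rate = error_rate),
            class = "population_model")
}

#' @method print population_model
#' @export
print.population_model <- function(x, ...) {
  cat(sprintf(
    "Population model: ploidy %d, inbreeding F = %g, overdispersion = %g, error rate = %g\n",
    x$ploidy, x$inbreeding, x$overdispersion, x$error_rate))
  cat(sprintf("Expected H_ind/H_E for a Mendelian locus: %.4f\n",
              expected_hindhe_value(x)))
  invisible(x)
}

#' Closed-form expectation of the statistic
#'
#' For a Mendelian locus in a diploid or polysomic population the expected
#' ratio is `(k - 1)/k * (1 - F)`: the probability that two reads come from
#' different chromosome copies times the probability that those copies are not
#' identical by descent, normalized by expected heterozygosity.
#'
#' @param model A [population_model()], or a ploidy if `inbreeding` is given.
#' @param inbreeding Inbreeding coefficient, used when `model` is a ploidy.
#' @return The expected value of the per-locus mean statistic.
#' @examples
#' expected_hindhe_value(2)            # 0.5
#' expected_hindhe_value(4)            # 0.75
#' expected_hindhe_value(2, inbreeding = 1)  # 0
#' @export
expected_hindhe_value <- function(model, inbreeding = 0) {
  if (inherits(model, "population_model")) {
    k <- model$ploidy; F <- model$inbreeding
  } else {
    k <- as.integer(model); F <- inbreeding
    if (is.na(k) || k < 2L) stop("ploidy must be an integer >= 2")
    if (F < 0 || F > 1) stop("inbreeding must be in [0, 1]")
  }
  (k - 1) / k * (1 - F)
}
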