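## Mapping populations.  In a biparental cross, expected heterozygosity must
## be replaced by H_E.map: the probability that two locus copies of a progeny
## are different alleles, which depends on the parental genotypes and the
## population design and is obtained by simulating the cross.

#' Describe a biparental cross at one locus
#'
#' @param ploidy Even integer ploidy (gametes carry `ploidy/2` copies formed
#'   by random bivalent pairing; double reduction is not modeled).
#' @param parent1,parent2 Integer allele dosage vectors of the two parents,
#'   each summing to the ploidy (e.g. `c(3, 1)` for a tetraploid simplex
#'   AAAB).  Shorter vectors are zero-padded to a common allele count.
#' @param n_gen_backcross Generations of backcrossing to `parent1` (the
#'   recurrent parent by convention) applied after the F1.
#' @param n_gen_self Generations of self-fertilization applied after any
#'   backcrossing.
#' @return An object of class `cross_design`.
#' @examples
#' cross_design(2, c(1, 1), c(2, 0))             # diploid testcross Aa x aa
#' cross_design(4, c(3, 1), c(4, 0))             # simplex x nulliplex
#' @export
cross_design <- function(ploidy, parent1, parent2,
                         n_gen_backcross = 0L, n_gen_self = 0L) {
  k <- as.integer(ploidy)
  if (is.na(k) || k < 2L || k %% 2L != 0L)
    stop("ploidy must be an even integer >= 2 (bivalent gamete formation)")
  j <- max(length(parent1), length(parent2))
  p1 <- c(as.integer(parent1), integer(j - length(parent1)))
  p2 <- c(as.integer(parent2), integer(j - length(parent2)))
  if (any(p1 < 0) || any(p2 < 0) || sum(p1) != k || sum(p2) != k)
    stop("parental dosages must be non-negative and sum to the ploidy")
  structure(list(ploidy = k, parent1 = p1, parent2 = p2,
                 n_gen_backcross = as.integer(n_gen_backcross),
                 n_gen_self = as.integer(n_gen_self)),
            class = "cross_design")
}

#' @method print cross_design
#' @export
print.cross_design <- function(x, ...) {
  dose <- function(v) paste(v, collapse = "/")
  cat(sprintf("Cross design (ploidy %d): %s x %s", x$ploidy,
              dose(x$parent1), dose(x$parent2)))
  if (x$n_gen_backcross) cat(",", x$n_gen_backcross, "backcross gen.")
  if (x$n_gen_self) cat(",", x$n_gen_self, "selfing gen.")
  cat("\n")
  invisible(x)
}

## expand a dosage vector into allele-id copies, replicated for n individuals
.copies_matrix <- function(dosage, n) {
  matrix(rep(rep.int(seq_along(dosage), dosage), times = n),
         nrow = n, byrow = TRUE)
}

## one gamete per row: k/2 copies sampled without replacement from the k
## copies of each row (random bivalent pairing).  All C(k, k/2) copy subsets
## are equally likely, so we draw a subset index per row.
.sim_gametes <- function(copies) {
  k <- ncol(copies)
  subs <- utils::combn(k, k %/% 2L)
  pick <- subs[, sample.int(ncol(subs), nrow(copies), replace = TRUE),
               drop = FALSE]
  m <- matrix(copies[cbind(rep(seq_len(nrow(copies)), each = nrow(subs)),
                           as.vector(pick))],
              nrow = nrow(copies), byrow = TRUE)
  m
}

## simulate n progeny of the design; returns dosage matrix n x j
.sim_progeny_dosages <- function(design, n) {
  j <- length(design$parent1)
  p1 <- .copies_matrix(design$parent1, n)
  cur <- cbind(.sim_gametes(p1), .sim_gametes(.copies_matrix(design$parent2, n)))
  for (b in seq_len(design$n_gen_backcross))
    cur <- cbind(.sim_gametes(cur), .sim_gametes(p1))
  for (s in seq_len(design$n_gen_self))
    cur <- cbind(.sim_gametes(cur), .sim_gametes(cur))
  g <- matrix(0L, n, j)
  for (i in seq_len(j)) g[, i] <- rowSums(cur == i)
  g
}

#' Expected within-progeny allelic diversity of a cross
#'
#' Monte-Carlo estimate of the probability that two locus copies, sampled
#' without replacement from a random progeny of the cross, are different
#' alleles.  This is the denominator of the mapping-population statistic and
#' is a genotype-level quantity: sequencing error and overdispersion play no
#' role.
#'
#' @param design A [cross_design()].
#' @param n_sim Number of simulated progeny; the default `1e5` gives a
#'   standard error below 0.002 on a probability.
#' @param seed Optional integer seed.
#' @return Estimated probability in `[0, 1]`.
#' @examples
#' he_map(cross_design(2, c(1, 1), c(2, 0)), n_sim = 1e4, seed = 1) # ~0.5
#' @export
he_map <- function(design, n_sim = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_sim < 1) stop("n_sim must be positive")
  k <- design$ploidy
  g <- .sim_progeny_dosages(design, n_sim)
  mean(1 - rowSums(g * (g - 1)) / (k * (k - 1)))
}

#' H_ind/H_E.map for a mapping population
#'
#' Divides each progeny's within-individual read diversity by the cross's
#' expected diversity [he_map()].  Under Mendelian segregation the per-locus
#' mean estimates `(k - 1)/k` for every marker type.
#'
#' @param x A [depth_dataset()] of progeny read depths (or a single depth
#'   matrix).
#' @param designs A single [cross_design()] applied to every locus, or a list
#'   with one design per locus.
#' @param progeny_ids Optional character vector restricting the computation
#'   to progeny rows (parents or outgroups in the dataset are dropped).
#' @param n_sim Progeny simulated per distinct design for [he_map()].
#' @param seed Optional integer seed (he_map simulation only).
#' @return A `hindhe_result` (see [hindhe()]); loci whose cross is
#'   monomorphic (`he_map = 0`) are missing, with a warning.
#' @export
hindhe_mapping <- function(x, designs, progeny_ids = NULL, n_sim = 1e5,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ds <- as_depth_dataset(x)
  if (!is.null(progeny_ids)) {
    keep <- match(progeny_ids, ds$individual_ids)
    if (anyNA(keep)) stop("unknown progeny ids")
    ds$loci <- lapply(ds$loci, function(m) m[keep, , drop = FALSE])
    ds$individual_ids <- progeny_ids
  }
  L <- length(ds$loci)
  if (inherits(designs, "cross_design")) designs <- rep(list(designs), L)
  if (length(designs) != L) stop("need one cross design per locus")
  key <- vapply(designs, function(d) paste(
    d$ploidy, paste(d$parent1, collapse = ","), paste(d$parent2, collapse = ","),
    d$n_gen_backcross, d$n_gen_self, sep = "|"), "")
  hem <- vapply(unique(key), function(kk)
    he_map(designs[[match(kk, key)]], n_sim = n_sim), 0)[key]
  vals <- matrix(NA_real_, length(ds$individual_ids), L,
                 dimnames = list(ds$individual_ids, names(ds$loci)))
  mono <- 0L
  for (l in seq_len(L)) {
    if (hem[l] <= 0) { mono <- mono + 1L; next }
    vals[, l] <- .hind_rows(ds$loci[[l]]) / hem[l]
  }
  if (mono > 0L)
    warning(mono, " locus/loci with a monomorphic cross (he_map = 0) set to missing")
  k <- designs[[1]]$ploidy
  new_hindhe_result(vals, vapply(ds$loci, function(m) mean(rowSums(m)), 0),
                    expected = (k - 1) / k)
}

#' Simulate a biparental F1 (or advanced) mapping population
#'
#' Progeny dosages are simulated from the cross design for each locus
#' independently, then read depths via [sim_allele_depth()].
#'
#' @param design A [cross_design()] shared by all loci.
#' @param model A [population_model()] (ploidy must match the design).
#' @param n_ind Number of progeny.
#' @param n_loci Number of loci.
#' @param mean_depth Locus mean depth (see [sim_genotype_depths()]).
#' @param seed Optional integer seed.
#' @return A [depth_dataset()] of progeny depths.
#' @export
sim_mapping_population <- function(design, model, n_ind, n_loci,
                                   mean_depth = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (model$ploidy != design$ploidy) stop("design and model ploidy differ")
  loci <- lapply(seq_len(n_loci), function(l)
    sim_allele_depth(.sim_progeny_dosages(design, n_ind), mean_depth, model))
  names(loci) <- sprintf("mk%05d", seq_len(n_loci))
  depth_dataset(loci)
}

#' Read per-locus cross designs from a TSV
#'
#' Expects columns `locus`, `parent1`, `parent2`, with dosages encoded as
#' slash-separated integers (e.g. `3/1`); global design parameters are given
#' once.
#'
#' @param path TSV file path.
#' @param ploidy,n_gen_backcross,n_gen_self Global design parameters.
#' @return Named list of [cross_design()] objects keyed by locus.
#' @export
read_cross_designs <- function(path, ploidy, n_gen_backcross = 0L,
                               n_gen_self = 0L) {
  tb <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("locus", "parent1", "parent2")
  if (!all(need %in% names(tb)))
    stop("cross design table needs columns: ", paste(need, collapse = ", "))
  parse_dose <- function(s) as.integer(strsplit(s, "/", fixed = TRUE)[[1]])
  out <- lapply(seq_len(nrow(tb)), function(i)
    cross_design(ploidy, parse_dose(tb$parent1[i]), parse_dose(tb$parent2[i]),
                 n_gen_backcross, n_gen_self))
  names(out) <- tb$locus
  out
}
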