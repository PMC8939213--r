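## Shared data containers: a depth matrix per locus and a dataset of loci that
## share one individual roster.  Depth matrices are plain integer matrices
## (individuals x alleles, dimnames set) so that all numeric code works on
## them directly; the dataset class adds the roster invariant and metadata.

#' Construct a per-locus allelic depth matrix
#'
#' A depth matrix holds the sequencing read counts of one locus: one row per
#' individual, one column per allele.  Rows whose total depth is below two are
#' kept in storage; they are excluded from averaging only when the statistic
#' is computed.
#'
#' @param depths Matrix (or object coercible to one) of non-negative integer
#'   read counts, individuals in rows and alleles in columns.
#' @param allele_ids Optional character vector of allele labels (must be
#'   unique within the locus).  Defaults to existing column names or
#'   `"a1"`, `"a2"`, ...
#' @param individual_ids Optional character vector of sample labels.
#'   Defaults to existing row names or `"ind1"`, `"ind2"`, ...
#' @return An integer matrix with allele and individual labels as dimnames.
#' @examples
#' depth_matrix(rbind(c(5, 5), c(10, 0)))
#' @export
depth_matrix <- function(depths, allele_ids = NULL, individual_ids = NULL) {
  d <- as.matrix(depths)
  if (any(!is.finite(d)) || any(d < 0) || any(d != round(d)))
    stop("depths must be finite, non-negative integers")
  storage.mode(d) <- "integer"
  if (is.null(allele_ids)) {
    allele_ids <- colnames(d)
    if (is.null(allele_ids)) allele_ids <- paste0("a", seq_len(ncol(d)))
  }
  if (anyDuplicated(allele_ids)) stop("allele_ids must be unique within a locus")
  if (is.null(individual_ids)) {
    individual_ids <- rownames(d)
    if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(d)))
  }
  dimnames(d) <- list(individual_ids, allele_ids)
  d
}

#' Bundle depth matrices into a dataset
#'
#' A `depth_dataset` is an ordered collection of per-locus depth matrices that
#' share a single individual roster.  Loci genotyped in a subset of
#' individuals are represented with all-zero rows, which the statistic's
#' depth-two rule handles naturally.
#'
#' @param loci Named list of depth matrices (see [depth_matrix()]).  All must
#'   have the same number of rows and, when row names are present, the same
#'   individuals in the same order.
#' @param individual_ids Optional roster; defaults to the row names of the
#'   first locus.
#' @return An object of class `depth_dataset`: a list with elements `loci`
#'   (the named list of integer matrices) and `info` (a data frame with one
#'   row per locus: `locus`, `n_alleles`, `mean_depth`).
#' @examples
#' loc <- depth_matrix(rbind(c(5, 5), c(10, 0)))
#' depth_dataset(list(locA = loc))
#' @export
depth_dataset <- function(loci, individual_ids = NULL) {
  if (!is.list(loci)) stop("loci must be a list of depth matrices")
  if (length(loci) && (is.null(names(loci)) || anyDuplicated(names(loci))))
    names(loci) <- make.unique(if (is.null(names(loci)))
      paste0("loc", seq_along(loci)) else names(loci))
  loci <- lapply(loci, depth_matrix)
  if (length(loci)) {
    if (is.null(individual_ids)) individual_ids <- rownames(loci[[1]])
    nr <- vapply(loci, nrow, 0L)
    if (any(nr != length(individual_ids)))
      stop("all loci must cover the same individual roster")
    for (i in seq_along(loci)) {
      rn <- rownames(loci[[i]])
      if (!identical(rn, individual_ids)) {
        if (setequal(rn, individual_ids)) loci[[i]] <- loci[[i]][individual_ids, , drop = FALSE]
        else stop("locus ", names(loci)[i], " does not match the individual roster")
      }
    }
  } else if (is.null(individual_ids)) individual_ids <- character(0)
  info <- data.frame(
    locus = names(loci),
    n_alleles = vapply(loci, ncol, 0L),
    mean_depth = vapply(loci, function(m) mean(rowSums(m)), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(loci = loci, individual_ids = individual_ids, info = info),
            class = "depth_dataset")
}

#' @method print depth_dataset
#' @export
print.depth_dataset <- function(x, ...) {
  cat("Allelic depth dataset:", length(x$loci), "loci x",
      length(x$individual_ids), "individuals\n")
  if (nrow(x$info)) {
    cat("  alleles per locus:", paste(range(x$info$n_alleles), collapse = "-"),
        "  mean depth (median across loci):",
        signif(median(x$info$mean_depth), 4), "\n")
  }
  invisible(x)
}

#' @export
length.depth_dataset <- function(x) length(x$loci)

#' @export
`[.depth_dataset` <- function(x, i) {
  depth_dataset(x$loci[i], individual_ids = x$individual_ids)
}

## coerce a lone matrix into a one-locus dataset
as_depth_dataset <- function(x) {
  if (inherits(x, "depth_dataset")) return(x)
  if (is.matrix(x) || is.data.frame(x)) return(depth_dataset(list(locus = x)))
  stop("cannot interpret input as a depth dataset")
}
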