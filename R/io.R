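## Readers and writers.  The statistic needs nothing but allelic read
## depths, so the VCF reader imports only FORMAT/AD (no GT, no qualities),
## and the tabular format is a plain wide TSV with one column per
## locus:allele pair.

#' Read allelic depths from a VCF
#'
#' Imports per-sample allelic depths (FORMAT/AD) from a VCF 4.x file; REF and
#' ALT alleles become the allele columns in record order, and multiallelic
#' records are supported.  Genotype calls, qualities and phasing are ignored.
#' Missing AD entries become all-zero rows: an individual without reads
#' simply contributes nothing, and the statistic's two-read rule excludes it.
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @param min_indiv_with_reads Drop records where fewer than this many
#'   individuals have two or more reads (default 0 keeps everything); the
#'   number of dropped records is reported.
#' @return A [depth_dataset()] with loci named `CHROM_POS` (or the ID field
#'   where present).
#' @export
read_vcf_depths <- function(path, min_indiv_with_reads = 0) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@gt) == 0L) stop("VCF contains no genotype records")
  fmt <- vcf@gt[, 1]
  if (!any(grepl("(^|:)AD(:|$)", fmt)))
    stop("unsupported input: VCF carries no FORMAT/AD (allelic depth) field")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  fix <- vcf@fix
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste(fix[, "CHROM"], fix[, "POS"], sep = "_"), fix[, "ID"])
  ids <- make.unique(ids)
  samples <- colnames(ad)
  loci <- vector("list", nrow(ad))
  for (r in seq_len(nrow(ad))) {
    alleles <- unname(c(fix[r, "REF"],
                        strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]))
    alleles <- alleles[!is.na(alleles) & alleles != "."]
    j <- length(alleles)
    m <- matrix(0L, length(samples), j, dimnames = list(samples, alleles))
    ok <- !is.na(ad[r, ]) & ad[r, ] != "."
    if (any(ok)) {
      parts <- strsplit(ad[r, ok], ",", fixed = TRUE)
      for (s in seq_along(parts)) {
        v <- suppressWarnings(as.integer(parts[[s]]))
        v[is.na(v)] <- 0L
        m[which(ok)[s], seq_len(min(j, length(v)))] <- v[seq_len(min(j, length(v)))]
      }
    }
    loci[[r]] <- m
  }
  names(loci) <- ids
  if (min_indiv_with_reads > 0) {
    enough <- vapply(loci, function(m) sum(rowSums(m) >= 2), 0L)
    drop <- enough < min_indiv_with_reads
    if (any(drop)) {
      message("dropping ", sum(drop), " record(s) with fewer than ",
              min_indiv_with_reads, " individuals at depth >= 2")
      loci <- loci[!drop]
    }
  }
  depth_dataset(loci)
}

#' Read allelic depths from a TSV
#'
#' Accepts either the wide format written by [write_depth_table()] (an
#' `individual` column plus one `locus:allele` column per allele) or a long
#' format with columns `individual`, `locus`, `allele`, `depth`.
#'
#' @param path Path to a tab-separated file.
#' @return A [depth_dataset()].
#' @export
read_depth_table <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(tb) == 0L) {
    warning("empty depth table: returning an empty dataset")
    return(depth_dataset(list()))
  }
  if (all(c("individual", "locus", "allele", "depth") %in% names(tb)))
    return(.dataset_from_long(tb))
  if (names(tb)[1] != "individual" || !all(grepl(":", names(tb)[-1])))
    stop("format error: expected an 'individual' column plus 'locus:allele' ",
         "columns, or long columns individual/locus/allele/depth")
  inds <- as.character(tb$individual)
  if (anyDuplicated(inds)) stop("duplicated individual label in depth table")
  loc <- sub(":.*$", "", names(tb)[-1])
  al <- sub("^[^:]*:", "", names(tb)[-1])
  loci <- lapply(unique(loc), function(L) {
    cols <- which(loc == L) + 1L
    m <- as.matrix(tb[, cols, drop = FALSE])
    depth_matrix(m, allele_ids = al[cols - 1L], individual_ids = inds)
  })
  names(loci) <- unique(loc)
  depth_dataset(loci, individual_ids = inds)
}

.dataset_from_long <- function(tb) {
  if (anyDuplicated(tb[, c("individual", "locus", "allele")]))
    stop("format error: duplicated individual/locus/allele combination")
  inds <- unique(as.character(tb$individual))
  loci <- lapply(split(tb, tb$locus), function(x) {
    al <- unique(as.character(x$allele))
    m <- matrix(0L, length(inds), length(al), dimnames = list(inds, al))
    m[cbind(match(x$individual, inds), match(x$allele, al))] <-
      as.integer(x$depth)
    m
  })
  depth_dataset(loci, individual_ids = inds)
}

#' Write a dataset as a wide depth table
#'
#' One row per individual, one `locus:allele` column per allele; the inverse
#' of [read_depth_table()].  Locus names must not contain `:`.
#'
#' @param dataset A [depth_dataset()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_depth_table <- function(dataset, path) {
  ds <- as_depth_dataset(dataset)
  if (any(grepl(":", names(ds$loci), fixed = TRUE)))
    stop("locus names must not contain ':'")
  blocks <- lapply(names(ds$loci), function(L) {
    m <- ds$loci[[L]]
    colnames(m) <- paste(L, colnames(m), sep = ":")
    m
  })
  wide <- data.frame(individual = ds$individual_ids,
                     do.call(cbind, blocks), check.names = FALSE,
                     stringsAsFactors = FALSE)
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the statistic's results as TSV files
#'
#' Writes three files under a common prefix: `<prefix>_matrix.tsv` (the full
#' individuals x loci matrix), `<prefix>_loci.tsv` (per-locus summary:
#' mean depth, individuals used, mean statistic) and
#' `<prefix>_individuals.tsv` (per-individual summary).  Missing values are
#' written as `NA`.
#'
#' @param result A `hindhe_result` (see [hindhe()]).
#' @param prefix Output path prefix; the directory must exist.
#' @return Invisibly, the three file paths.
#' @export
write_hindhe_results <- function(result, prefix) {
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  paths <- paste0(prefix, c("_matrix.tsv", "_loci.tsv", "_individuals.tsv"))
  mat <- data.frame(individual = rownames(result$values), result$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(mat, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  loci <- data.frame(locus = colnames(result$values),
                     mean_depth = result$locus_depth_means,
                     n_used = result$n_used,
                     mean_hindhe = result$locus_means,
                     stringsAsFactors = FALSE)
  write.table(loci, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  inds <- data.frame(individual = rownames(result$values),
                     n_loci_used = rowSums(is.finite(result$values)),
                     mean_hindhe = result$individual_means,
                     stringsAsFactors = FALSE)
  write.table(inds, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
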