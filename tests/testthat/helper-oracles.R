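## Independent oracles used by the unit and acceptance tests.  These stay
## deliberately naive (explicit enumeration) so they cannot share a bug with
## the vectorized implementation they check.

## probability that two reads drawn without replacement differ, by explicit
## enumeration of all unordered read pairs
pair_oracle <- function(depths) {
  reads <- rep(seq_along(depths), depths)
  if (length(reads) < 2) return(NA_real_)
  pairs <- utils::combn(length(reads), 2)
  mean(reads[pairs[1, ]] != reads[pairs[2, ]])
}

## exhaustive-gamete F1 expectation: all C(k, k/2) copy subsets of each
## parent are equally likely; average the probability that two progeny
## copies sampled without replacement differ
he_map_enum <- function(ploidy, parent1, parent2) {
  k <- ploidy
  copies1 <- rep(seq_along(parent1), parent1)
  copies2 <- rep(seq_along(parent2), parent2)
  g1 <- utils::combn(k, k / 2)
  g2 <- utils::combn(k, k / 2)
  tot <- 0
  for (i in seq_len(ncol(g1))) for (j in seq_len(ncol(g2))) {
    geno <- c(copies1[g1[, i]], copies2[g2[, j]])
    cnt <- tabulate(geno, nbins = max(geno))
    tot <- tot + (1 - sum(cnt * (cnt - 1)) / (k * (k - 1)))
  }
  tot / (ncol(g1) * ncol(g2))
}

## the nine F1 marker types of the mapping experiments: parent dosage pairs
## (count of allele A, count of allele B)
f1_marker_types <- list(
  testcross          = list(k = 2, p1 = c(1, 1), p2 = c(2, 0)),
  f2                 = list(k = 2, p1 = c(1, 1), p2 = c(1, 1)),
  simplex_x_nulliplex = list(k = 4, p1 = c(3, 1), p2 = c(4, 0)),
  duplex_x_nulliplex  = list(k = 4, p1 = c(2, 2), p2 = c(4, 0)),
  triplex_x_nulliplex = list(k = 4, p1 = c(1, 3), p2 = c(4, 0)),
  simplex_x_simplex   = list(k = 4, p1 = c(3, 1), p2 = c(3, 1)),
  simplex_x_duplex    = list(k = 4, p1 = c(3, 1), p2 = c(2, 2)),
  simplex_x_triplex   = list(k = 4, p1 = c(3, 1), p2 = c(1, 3)),
  duplex_x_duplex     = list(k = 4, p1 = c(2, 2), p2 = c(2, 2)))

## write a small VCF with FORMAT/AD in code (text fixture, no binary files)
write_test_vcf <- function(path, with_ad = TRUE) {
  fmt <- if (with_ad) "GT:AD" else "GT"
  gt <- function(g, ad) if (with_ad) paste(g, ad, sep = ":") else g
  lines <- c(
    "##fileformat=VCFv4.3",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (with_ad)
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("chr1", "101", ".", "A", "G", ".", "PASS", ".", fmt,
          gt("0/1", "5,5"), gt("0/0", "10,0"), gt("./.", "."), sep = "\t"),
    paste("chr1", "202", ".", "C", "G,T", ".", "PASS", ".", fmt,
          gt("0/2", "4,0,2"), gt("1/1", "0,7,0"), gt("0/0", "2,0,0"),
          sep = "\t"))
  writeLines(lines, path)
  path
}
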