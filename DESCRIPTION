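Package: hindhe
Title: Read-Depth Diagnostics of Mendelian Behavior for
    Genotyping-by-Sequencing Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes H_ind/H_E, a genotype-call-free statistic of Mendelian
    behavior for genotyping-by-sequencing and RAD-seq markers, from per-sample
    allelic read depths (VCF FORMAT/AD or tabular depth matrices).  For a
    Mendelian locus in a population with ploidy k and inbreeding coefficient F
    the statistic has expectation (k-1)/k * (1-F) regardless of read depth or
    allele frequency, so collapsed paralogs (inflated values), null alleles and
    overdispersed loci (deflated values), cytoplasmic markers (zero), and
    individuals of unexpected ploidy or hybrid status can all be screened
    before any genotype calling.  Includes a Dirichlet-multinomial read-depth
    simulator for deriving dataset-matched filtering thresholds, support for
    biparental mapping populations via simulated cross expectations, and
    comparator statistics (observed/expected heterozygosity with a simple
    empirical-Bayes caller, per-individual haplotype counts, allelic depth
    ratio Z-scores, mean depth) with a paralog-filtering benchmark harness.
License: GPL (>= 2)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
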