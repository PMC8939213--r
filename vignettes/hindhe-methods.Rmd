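---
title: "Read-depth diagnostics of Mendelian behavior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth diagnostics of Mendelian behavior: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(hindhe)
```

## The problem

Genotyping-by-sequencing (GBS/RAD-seq) in species with duplicated genomes
routinely produces *collapsed paralogs*: two loci whose reads are
attributed to a single position, so that apparent heterozygosity is
inflated and downstream genetics (mapping, GWAS, parentage, population
structure) is biased.  The classical screen — call genotypes, then compare
observed with expected heterozygosity — requires the expensive genotyping
step to be run first, and is unreliable at low depth and in polyploids.

This package implements a screen that works directly on allelic read
depths, before any genotype calling.  For individual $m$ at a locus with
allele depths $d_{1m},\dots,d_{jm}$ and total $D_m = \sum_i d_{im}$, define
$H_{ind}$ as the probability that two reads sampled *without replacement*
carry different alleles, estimated by the bias-corrected Gini–Simpson
index

$$\hat H_{ind,m} = \Bigl(1 - \sum_{i=1}^{j} (d_{im}/D_m)^2\Bigr)
  \frac{D_m}{D_m - 1}, \qquad D_m \ge 2 .$$

Dividing by the locus's expected heterozygosity
$\hat H_E = 1 - \sum_i \hat p_i^2$, with $\hat p_i$ the unweighted mean of
within-individual depth ratios over individuals with at least one read,
gives a ratio whose expectation for a Mendelian locus is

$$\mathrm{E}\bigl[H_{ind}/H_E\bigr] = \frac{k-1}{k}\,(1-F),$$

with $k$ the ploidy and $F$ the inbreeding coefficient — independent of
allele frequency, read depth and number of alleles.  That flatness is the
whole point: one number per dataset separates well-behaved loci from
paralogs (values above the expectation, approaching 1 when alleles are
assigned to individuals at random), null alleles and overdispersed loci
(below), and cytoplasmic markers (zero).  Averaged within individuals
instead of within loci, the same matrix flags unexpected ploidy, hybrids
and contaminated samples.

## A worked example

```{r example}
model <- population_model(ploidy = 2, inbreeding = 0, overdispersion = 20,
                          error_rate = 0.001)
panel <- sim_dataset(model, n_ind = 300, n_loci = 400, maf = 0.2,
                     mean_depth = 20, seed = 11)
res <- hindhe(panel)
summary(res)
```

The per-locus means concentrate near
`expected_hindhe_value(model)` = `r expected_hindhe_value(2)` times the
overdispersion deflation discussed below.  A collapsed paralog sits far to
the right:

```{r paralog}
par_locus <- sim_collapsed_paralog(c(0.7, 0.3), c(0.9, 0.1), model,
                                   n = 300, depth1 = 20, depth2 = 20,
                                   seed = 12)
hindhe(par_locus)$locus_means
```

## Parameters that matter

* **`ploidy` (k)** — disomic or polysomic inheritance is assumed; the
  expectation rises as $(k-1)/k$.
* **`inbreeding` (F)** — probability that two allele copies in an
  individual are identical by descent, from any source including
  population structure.  It can itself be estimated from the data by
  inverting the expectation at the modal locus value
  (`estimate_inbreeding(hindhe_mode(res), ploidy)`), preferably over loci
  with minor allele frequency of at least 0.05, because rarer loci are
  biased upward by sequencing error.
* **`overdispersion`** — concentration of the Dirichlet-multinomial read
  model; allelic depth proportions for dosage $g$ are drawn around
  $g/k$ with concentration `od`.  Algebra of the estimator gives
  $\mathrm{E}[\hat H_{ind}] = \frac{od}{od+1}\bigl(1-\sum_i \tau_i^2\bigr)$
  for expected read fractions $\tau$: overdispersion deflates every value
  by the *same* factor $od/(od+1)$ (0.952 at the default 20), which is why
  filtering thresholds should come from matched simulation rather than
  from the idealized expectation.
* **`error_rate`** — per-read probability of landing on a wrong allele
  (default 0.001, a typical Illumina-scale figure after quality
  filtering).  Error inflates the statistic chiefly at minor allele
  frequencies near 0.01.
* **depth** — entries with $D_m < 2$ carry no information about read
  pairing and are excluded from averages; loci with mean depth below
  about 5 are flagged by `filter_loci()` because null alleles and missing
  data dominate them.

## Mapping populations

In a biparental cross, population-level $H_E$ is replaced by
$H_{E.map}$: the probability that two locus copies of a progeny differ,
which depends on parental dosages and the design.  `he_map()` estimates it
by simulating the cross — gametes take $k/2$ copies sampled without
replacement from the parent's $k$ (random bivalent pairing; double
reduction is not modeled, keeping the progeny-mean expectation at
$(k-1)/k$) — with backcross generations (to parent 1, by convention)
applied before selfing generations.  The default 100,000 simulated progeny
put the Monte-Carlo standard error below 0.002.  `hindhe_mapping()` then
divides each progeny's $\hat H_{ind}$ by $H_{E.map}$; every marker type has
expectation $(k-1)/k$, again times $od/(od+1)$.  Marker types with low
progeny heterozygosity (tetraploid simplex crosses) have noticeably wider
per-locus distributions than high-heterozygosity types (triplex crosses),
because the denominator is small relative to the segregation noise.

## The simulator and what it emulates

All fixtures and thresholds in this package come from the same generative
model:

1. **Genotypes.**  Allele copies follow a Pólya-urn with concentration
   $\theta p$, $\theta = (1-F)/F$ — equivalently dosages are
   Dirichlet-multinomial (the Balding–Nichols model generalized to ploidy
   $k$).  Any two copies are identical by descent with probability exactly
   $F$; $F = 0$ is Hardy–Weinberg, $F = 1$ fully autozygous.  For diploids
   this coincides with the familiar mixture
   $(1-F)\,\mathrm{HWE} + F\,\mathrm{homozygote}$; for polyploids it
   distributes partial autozygosity across intermediate dosage classes,
   which we found necessary to reproduce published polyploid filtering
   behavior (an all-or-nothing mixture makes tetraploid genotypes far too
   often carry three or four distinct alleles at high $F$).
2. **Depths.**  A locus's mean depth is either given directly or drawn
   from gamma(shape 3.2, scale 8) in benchmark cohorts; each genotype's
   total depth is then gamma(shape mean/10, scale 10), rounded — a
   deliberately heavy-tailed hierarchy that mimics the strong
   amplification heterogeneity of multiplexed GBS libraries (including
   occasional zero-read individuals).  Allele counts are multinomial with
   Dirichlet-distributed proportions (concentration
   $od \cdot \mathrm{dosage}/k$), and each read is independently
   reassigned to a uniformly chosen other allele with probability
   `error_rate` (applied on the combined allele set for collapsed
   paralogs, where a monomorphic component offers no error target of its
   own).
3. **Problem loci.**  Collapsed paralogs are two independent loci,
   column-concatenated over disjoint allele sets.  Null-allele loci are
   triallelic simulations whose third allele's depth column is discarded.

What the simulator does **not** emulate: linkage between loci, genuine
population structure (the scalar $F$ stands in for it), contamination or
sample mixing, mapping bias, and base-call quality variation.  Green tests
therefore demonstrate correctness of the statistic and its sampling
behavior under this model, not robustness to every artefact of a real
library.

## Dataset-matched thresholds

Because the ratio's variance has no closed form, `expected_hindhe()`
simulates Mendelian loci that *mirror the dataset*: each simulated locus
copies one randomly chosen real locus's estimated allele frequencies and
its per-individual depth column jointly (preserving frequency–depth
associations), re-simulates genotypes and reads under the supplied model,
and the 2.5% and 97.5% quantiles of the simulated per-locus means (for the
default 95% retention) become the filtering interval.  `filter_loci()`
applies the interval together with a mean-depth window.  For benchmark
comparisons, `one_sided_threshold()` takes the 95th percentile of known
Mendelian loci and `run_benchmark()` reports the fraction of collapsed
paralogs exceeding it, alongside four comparator statistics
(observed/expected heterozygosity and a depth-ratio Z-score — both fed by
a deliberately simple single-pass empirical-Bayes caller — plus
per-individual haplotype counts and raw mean depth).

## Numerical choices

* Quantiles use linear interpolation between order statistics (R's
  default type 7); third digits of thresholds depend on this.
* Allele frequencies average depth *ratios* unweighted over individuals
  with $\ge 1$ read (a ratio needs one read; the statistic's average needs
  two), so deep individuals do not dominate.
* Monomorphic-read loci ($H_E = 0$) and all-zero loci are missing, never
  zero; values above 1 are reported as-is — they are the signal.
* The caller breaks posterior ties toward the first enumerated dosage
  vector, and the "most common allele" of the Z-score breaks frequency
  ties toward the lowest allele index.
* Degenerate Dirichlet draws (all-zero gamma underflow at tiny
  concentrations) collapse to a single allele chosen proportionally to the
  concentration — the correct limiting distribution.
* The histogram mode for inbreeding estimation uses a 0.02 bin width:
  fine enough to resolve the peak at a few thousand loci, coarse enough
  not to chase noise.

## Sizes used in the test suite

The acceptance experiments run at the published design sizes: benchmark
cohorts of 1000 Mendelian plus 1000 paralog loci across 200 individuals
per ploidy-by-inbreeding cell (threshold cells average eight replicate
cohorts, since a single cohort's 95th percentile has Monte-Carlo spread
comparable to the comparison band); diversity panels of 5000 loci by
500 individuals; and nine F1 marker types at 5000 loci by 500 offspring.
Unit and property tests use a few hundred loci — enough for the qualitative
contrasts they assert, chosen once alongside each assertion's tolerance.

## Known limitations

* The inbreeding construction for polyploids is one of several that share
  pairwise IBD $= F$; higher-order identity coefficients are not
  separately controllable, and polyploid results at intermediate $F$
  depend mildly on this choice.
* The genotype caller behind the two comparator statistics is a
  single-pass posterior mode, not an iterative genotyping engine;
  comparator rows are meaningful for ranking methods, not as genotyping
  accuracy claims.
* No per-locus uncertainty accompanies the statistic (its variance has no
  closed form); decisions should use the simulated reference distribution.
* The statistic requires allelic depths; it cannot use haplotypes spanning
  multiple sequencing reads, and it inherits any upstream misassignment of
  reads to loci.
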