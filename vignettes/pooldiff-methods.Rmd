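---
title: "Pooled-transcriptome SNP discovery by allelic imbalance: models and design"
author: "pooldiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-transcriptome SNP discovery by allelic imbalance: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pooldiff)
```

# The method

Two pools of RNA — one from fast-growing fish, one from slow-growing fish,
each an equal-mass pool of 10 diploid full sibs — are sequenced at low
coverage (about 0.97X per fish, so roughly 10X per pool) against a
transcriptome reference assembled from a doubled-haploid individual.  The
discovery funnel then has four stages:

1. **Per-pool detection.** At each site, the candidate variant allele is
   the non-reference base with the most reads in that pool (ties broken
   alphabetically).  The pool calls a variant iff three stringency rules
   hold: at least 4 reads support the variant (inclusive), the variant
   fraction of counted reads is strictly greater than 20%, and the
   variant-supporting base quality is strictly greater than Phred 20.  A
   site is a putative SNP when at least one pool calls it (an option
   requires both).
2. **Pooled allele frequencies.** The variant-allele frequency in each
   pool is estimated by counting reads: `f = count(allele) / counted
   A/C/G/T reads`.  With 10 fish per pool at equal mass and, in
   expectation, equal expression, a read is a draw from the pool's sample
   allele frequency, making the estimator unbiased for it.
3. **Imbalance scoring.** The allelic imbalance score is the ratio
   `AI = f_fast / f_slow` on the variant allele.  `AI > 5.0` is classified
   as an amplification, `AI < 0.2` as loss of heterozygosity, both strict;
   boundary values are balanced.  `f_slow = 0` with a detected variant in
   the fast pool yields `AI = +Inf`, an amplification — these are the
   strongest imbalances and are retained.
4. **Paralog removal.** Salmonid genome duplication makes collapsed
   paralogs mimic heterozygous sites.  Two rules flag suspects: (a) the
   site appears in the doubled-haploid reference individual's self-variant
   list (a doubled haploid is fully homozygous, so any self-variant marks
   reference collapse, not polymorphism); (b) both pools show the variant
   at an intermediate fraction (default window 0.3–0.7) *and* the site
   depth exceeds a multiple (default 3) of the median site depth.  Rule
   (b)'s parameters are configuration keys; no operational rule is
   standard, so the defaults encode the usual diagnostic signature of
   collapse — a persistent ~50% alternate fraction at excess depth.

Decisions taken where the method description is open:

* *Quality aggregation.* "Quality score > 20" is interpreted as the mean
  Phred base quality of the variant-supporting reads; whether the upstream
  caller meant per-base, per-read or site-level quality is not knowable,
  so the parser also offers minimum-quality aggregation
  (`qualityAggregation = "min"`).
* *Score orientation.* The numerator is always the fast-growth pool and
  the score is computed on the variant (non-reference) allele.
* *Multi-allelic sites.* Only the top non-reference allele per pool is
  scored.  If the two pools pass detection on different alleles the site
  is excluded with flag `discordant_allele`.
* *Zero coverage in the contrasting pool.* If the pool that did not
  trigger detection has no usable reads, the frequency there is undefined
  (not zero): the site is excluded with flag `no_coverage_other_pool`
  rather than being promoted to an infinite score.  At ~10X pool depth
  this affects a negligible fraction of sites.

# The simulator

`simConfig()` fixes the study conditions: `nSites` candidate sites, 10
fish per pool, 0.97X per fish (pool depth Poisson with mean 9.7), a site
mixture of true SNPs, paralog artifacts and monomorphic sites, a per-base
error rate, and a Normal(35, 5) Phred quality model typical of early
Illumina base calls after filtering.

* **True SNPs** (default 3% of candidate sites) draw a population
  variant-allele frequency per pool from a U-shaped Beta(0.5, 0.5)
  spectrum (or explicit `freqPairs`); each fish's diploid genotype is
  binomial under Hardy–Weinberg at that frequency.  An optional *family
  mode* draws two parents and Mendelian offspring instead, matching the
  full-sib composition of the real pools; the default stays with HWE
  draws, which spread pool frequencies over more values and so exercise
  the imbalance classifier more evenly.
* **Monomorphic sites** carry only the reference allele; alternate reads
  arise from sequencing error alone (each read flips to a uniformly chosen
  other base with probability `errorRate`, default 0.01).
* **Paralog sites** emit an alternate fraction of 0.5 in *both* pools at
  twice the depth — two collapsed loci attract the reads of both copies.
  A fraction of them (default 50%) is exposed in the simulated
  doubled-haploid self-variant list: the DH reference is itself sequenced
  at finite coverage, so its self-variant list is incomplete.
* **Reads** are site-level draws: depth is Poisson, the variant-read count
  binomial at the pool sample frequency, errors are binomially thinned and
  spread over the other three bases.  Read sequences themselves are never
  constructed — per-site counts are sufficient statistics for everything
  downstream, and this keeps 10,000-site runs in seconds.  The stored
  per-base quality summary is drawn from the sampling distribution of a
  mean of Normal(35, 5) qualities, truncated at 2.

With `errorRate = 0` and no paralog sites, an alternate read can only come
from a real alternate allele, so every discovered site is a true SNP — the
simulated validation rate is exactly 1.  Under the default (study-like)
noise settings the validation rate lands in a broad band around the ~70%
success rate that panel genotyping of real pools reports; the acceptance
script logs this value rather than pinning it, because on real data it is
an empirical property of library artifacts and mapping error that the
simulator's two noise knobs (base error, residual paralogy) only
approximate.  What passing these tests shows is that the funnel's
*selectivity ordering* behaves correctly under a known generative model —
not that real transcriptome artifacts are fully captured (RNA editing,
allele-specific expression and mapping bias are absent by design:
equal-mass pooling is taken at face value, so allele-specific expression
would bias pooled frequencies in ways the simulator does not model).

Panel validation is emulated by extracting the per-fish genotypes of both
pools at discovered sites (`panelFromTruth()`); sites whose truth class is
not a true SNP genotype as monomorphic, mirroring how a paralog artifact
or an error call fails individual genotyping.  The pipeline's default 25%
assay-failure rate stands in for assay-design and multiplexing losses;
the validation rate conditions on successful assays, so it is insensitive
to this value.

# The family panel and association stage

`simulateFamilyPanel()` generates the downstream design: 40 full-sib
families with 17 genotyped offspring each plus their parents, 30 nuclear
SNPs (founder minor-allele frequencies uniform on 0.05–0.5, offspring by
Mendelian segregation) and 24 mitochondrial SNPs organised into three
maternally inherited haplotypes with frequencies 0.49 / 0.26 / 0.25, two
of which differ only at two designated markers — so those two markers are
the ones that tag the third haplotype.  Body weights at 170, 218, 282 and
372 days post-hatch follow a multiplicative growth model
`w = mu_t · exp(u_family + u_fish + tank + eps)` (log-scale SDs 0.10,
0.15, 0.02, 0.05; mean weights 60, 150, 400, 850 g chosen as a plausible
trout growth curve), with additive marker and haplotype effects in grams
at the final age scaled by `mu_t / mu_T` at earlier ages, and a
spawning-date age covariate.

The association statistics:

* `alleleCountRegression()` — OLS of trait on allele dosage; slope
  (phenotype units per allele copy), `t = b/SE`, two-sided asymptotic *P*
  with residual df, `R²`.  For the simple regression the identity
  `R² = t²/(t² + df)` is enforced by test to 1e-10.  Covariates enter the
  observed-statistic model only.
* `empiricalP()` — permutation *P* `(1 + #{|t*| ≥ |t|})/(K + 1)`, K =
  20,000 by default for marker data.  The *pooled* scheme permutes the
  trait across all samples; the *within-family* scheme permutes only among
  siblings, preserving family structure under the null.  Both schemes are
  provided because a family-based permutation cannot carry covariates;
  the permuted statistic is therefore the covariate-free *t*.  For
  maternally inherited markers the within-family scheme is degenerate
  (dosage is constant within a family), which is exactly why the pipeline
  tests mitochondrial markers population-based on unrelated subsets —
  `sampleUnrelated()` draws one offspring per family, three independent
  sets of n = 40.
* `bhFdr()` — the standard Benjamini–Hochberg step-up via
  `stats::p.adjust`.  Note that BH adjustment is *not* an idempotent map:
  re-adjusting an adjusted vector inflates it again (re-adjusting
  (0.03, 0.03, 0.04) gives (0.04, 0.04, 0.04)).  What holds, and what the
  tests assert, is monotonicity in the order statistics and the bounds
  `adj_i ∈ [p_i, 1]`.
* `hweExact()` — the biallelic conditional exact test by full enumeration
  of heterozygote counts given allele totals, summing probabilities of
  tables no more probable than the observed one; a Monte Carlo mode
  shuffles the 2n alleles into n pairings K = 20,000 times.  Markers
  failing HWE are reported but never auto-dropped: in a growth-selected
  line, HW deviation can reflect directional selection rather than error.
* `buildMtHaplotypes()` — mitochondrial markers ordered by physical
  position collapse to haplotype strings; samples with at most 2 missing
  calls are rescued when exactly one haplotype is consistent with their
  called alleles, otherwise left unassigned (ambiguity is logged, not
  guessed).

# Numerical and degenerate-input choices

* All stringency and imbalance inequalities are strict except the
  read-count minimum ("at least 4"); boundary tests pin 0.20, Phred 20,
  5.0 and 0.2 exactly.
* `detectVariant()` on a zero-coverage pool returns `pass = FALSE` with
  reason `no_coverage` instead of raising; `poolAlleleFrequency()` on zero
  usable reads *does* raise, because a frequency there is undefined.
* A constant trait gives `b = 0, t = 0, P = 1`; constant dosage is a
  degenerate design (error); an exactly collinear trait sets
  `degenerateSE = TRUE` with `R² = 1`.
* Exact-test tie handling: tables with probability equal to the observed
  one (within relative 1e-12) count toward the P-value.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; sub-seeds for the truth, evidence, panel and
  sampling streams are derived from the run seed so stages are
  independently reproducible.

# Problem sizes

The shipped tests and the acceptance script use desk-scale sizes chosen to
exercise every property well inside a laptop budget: 10,000 sites for the
zero-error and study-like simulations, 2,000 sites per depth for frequency
recovery, every genotype table up to n = 20 for the exact-HWE oracle
comparison, 500 null datasets (K = 199) for permutation-P uniformity, and
a 40 × 17 family panel with K = 200 permutations per marker for the
end-to-end determinism check.

# Known limitations

* Pooled frequencies ignore per-fish expression variation; real
  equal-mass RNA pools still differ in per-gene expression per fish, which
  widens the sampling variance beyond the binomial model.
* The paralog depth heuristic assumes a stable per-site depth scale;
  transcriptome coverage actually tracks expression, so rule (b) is
  deliberately conservative and rule (a) (the doubled-haploid list) does
  most of the work.
* Mixed-model and variance-component association analyses, linkage
  mapping and breeding-value machinery are out of scope; the regression
  and permutation statistics implemented here are the re-derivable core.
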