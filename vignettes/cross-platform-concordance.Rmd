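---
title: "Comparing SNV call sets from two sequencing platforms"
author: "crossvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing SNV call sets from two sequencing platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossvar)
```

## The problem

When the same individual's genome is re-sequenced on two different
platforms — differing in read length, insert size and chemistry — the two
single-nucleotide-variant (SNV) call sets never agree exactly. Some of the
disagreement is genuine platform blind spots (mappability, coverage
dropout), some is genotyping error, concentrated in heterozygous sites
sampled at low depth. `crossvar` quantifies this disagreement and the
benefit of combining the platforms:

1. **Three-way concordance.** Every site called by either platform is
   *concordant* (identical alt allele and zygosity), *discordant* (called
   by both, genotypes disagree) or *platform-specific* (called by exactly
   one).
2. **Chip comparison.** Each platform's genotypes are compared with SNP
   array genotypes at the assayed sites, incorporating the reference base:
   a HOM call for alt allele B implies the unordered genotype {B,B}; a HET
   call implies {ref,B}. The *chip-concordance rate* is
   `100 * n_concordant / (n_concordant + n_discordant)`; array-absent sites
   enter neither numerator nor denominator. The 2x2 *pattern matrix*
   cross-tabulates chip zygosity against sequencing zygosity over
   chip-discordant sites.
3. **Confident heterozygotes.** A heterozygous call is *highly confident*
   when its pileup has strictly more than 20x total coverage and the second
   most frequent base exceeds 30% of it. Because a truly heterozygous site
   needs enough reads to sample both alleles, chip-vs-sequencing
   heterozygous disagreements that pass this filter implicate the chip, not
   the sequencing.
4. **Callability.** Each reference base is classified from per-base depth
   and mean mapping quality (MQ): `NO_COVERAGE` (depth 0), `LOW_COVERAGE`
   (0 < depth < 4), `POOR_MQ` (depth >= 4, MQ < 10), else `CALLABLE`.
   Merging the two platforms' coverage (summed depth, depth-weighted mean
   MQ) rescues bases that neither platform covers adequately alone; the
   *callability gain* is the merged callable fraction minus the mean of the
   per-platform fractions.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 4 reads | callable-depth threshold, inclusive |
| `min_mq` | 10 | callable-MQ threshold, inclusive |
| `het_min_depth` | 20 reads | confident-het coverage bound, strict `>` |
| `het_min_second_fraction` | 0.30 | confident-het second-base bound, strict `>` |

The callability thresholds read "minimum equal to 4/10" literally, so the
boundary values 4 and 10 are callable. The confident-het wording is "more
than" and "greater than", so those comparisons are strict: a pileup of
exactly 20 reads fails, as does a second-base fraction of exactly 0.30.
When two bases tie for most frequent, the second-largest count (with
multiplicity) serves as "the second most frequent base" — the most
permissive reading, so a perfect 50/50 site is never rejected for being too
balanced.

## The synthetic-data generator

No suitable public per-base data accompany this analysis, so the package
ships a seeded simulator whose defaults define the conditions the test
suite and the acceptance script run under:

* **Genome**: 400 kb over 2 contigs, i.i.d. uniform bases, with 30% of the
  genome in tandem-repeat intervals (~500 bp copies of random 2–8 bp
  motifs). Desk-scale rather than genome-scale; every downstream statistic
  is a fraction, so size only sets sampling noise.
* **Truth**: 5,000 variant sites, heterozygous with probability 0.60 — the
  overall heterozygosity rate typical of a human genome's SNV set — alt
  allele uniform over the three non-reference bases.
* **Depth**: Poisson per 25 bp window with means 20 (platform 1) and 35
  (platform 2), echoing the two platforms' reported median depths. A real
  coverage process is autocorrelated and overdispersed; piecewise-constant
  Poisson is the simplest process with both coverage fluctuation and
  locality.
* **Dropout**: 0.5% of windows per platform are zeroed; platform 1's are
  chosen with weight `exp(10 * AT_fraction)` (AT-rich dropout, as
  polymerase-based chemistry shows), platform 2's uniformly. Kept small so
  dropout explains a visible but minor share of platform-specific calls.
* **Het undercalling**: a true HET covered at depth d is miscalled HOM-alt
  with probability `0.6 * exp(-d/4)` — 22% at the 4-read calling floor,
  negligible at 20–35x. Only the direction of the depth dependence is
  established; the exponential form and scale are simulator choices
  recorded in the configuration.
* **Platform-specific calls**: 10% of truth sites are withheld from each
  platform (the union of coverage-lost and deliberately suppressed sites),
  with 70% of each specific set placed in repeat regions. Suppression
  operates on called sites, not reads, because the pipeline consumes calls.
* **Mapping quality**: 60 everywhere except a mask covering half of all
  repeat bases, where it is 5. The mask is shared between platforms —
  mappability is a property of the genome — which also guarantees that
  merged MQ (a depth-weighted mean of equal values) never falls below a
  passing platform's MQ, so merging can only grow the callable set.
* **Chip**: 50% of truth sites assayed; a true HET is reported HOM (one
  allele duplicated at random) with probability 0.10.
* **Pileups**: for each called site, binomial allele counts consistent with
  the emitted genotype (p = 0.5 for HET calls, heavily skewed for HOM
  calls). Pileups are plumbing for the confident-het stage, not an error
  model in their own right.

Each output file draws from its own RNG stream derived from
`(seed, file role)`, so a fixed seed gives a byte-identical bundle and
adding an output never perturbs the others.

What the simulator does **not** emulate: read-level errors and base
qualities, indels and structural variants, GC-dependent coverage waves,
linked-error haplotypes, reference N runs, or sex-chromosome ploidy.
Passing tests therefore demonstrate that the pipeline's arithmetic and
classification logic are correct and that generating parameters are
recovered — not that any particular real genome would yield these numbers.

## Numerical choices

* Percentages are exact ratios internally; rounding (half away from zero,
  2 dp) happens only at report time. Empty denominators render `NA`, never
  `0.00`.
* `callability_gain()` returns the unrounded difference. Applied to
  already-rounded callable fractions (98.30, 98.15, 99.66) it gives exactly
  1.435 percentage points, which sits on a rounding boundary; publishing
  chains that round earlier print 1.43. Keeping the exact value avoids
  compounding rounding of rounded inputs.
* Medians use the mean-of-middle-two convention for even counts, hence
  half-integer medians like 10.5.
* Coverage is evaluated before MQ: a 2-read base with MQ 0 is
  `LOW_COVERAGE`, not `POOR_MQ`, matching the category ordering
  callable > poor MQ > low coverage > no coverage.
* Merged MQ is the depth-weighted mean of per-platform mean MQs (zero-depth
  platforms contribute nothing). Alternatives (min, max) are defensible;
  the weighted mean approximates recomputing mean MQ on a merged alignment.
* The merged call set used for the callable-region comparison keeps, at
  sites called by both platforms, the deeper platform's genotype with the
  summed depth — a stand-in for re-calling genotypes on merged alignments,
  which needs the reads.
* Sites called in both platforms with the same alt but different zygosity
  are discordant; so are different-alt sites (flagged `alt_mismatch`).
  Chip genotypes homozygous for the reference at a sequenced variant site
  count as chip-discordant (the call asserts a variant the chip denies) and
  are flagged `chip_hom_ref`.
* The chi-square comparison of chip-concordance in callable regions uses
  Pearson's statistic without continuity correction (the counts involved
  are large); Yates correction is available via a flag. The odds ratio is
  `(a*d)/(b*c)` with no Haldane correction — a zero cell yields `NA` with a
  warning.
* Since both headline conventions exist in practice, callability reports
  emit the callable-only fraction and the callable-plus-poor-MQ fraction
  side by side.

## Problem sizes

The shipped tests run the full pipeline on 60 kb / 800-site bundles and the
parameter-recovery checks on the default 400 kb / 5,000-site configuration;
property checks use 1,000 random call-set pairs (up to 200 sites each),
1,000 random 2x2 tables and a 10^6-base run-length round trip. These sizes
give binomial standard errors comfortably inside the asserted tolerances
(e.g. +/-0.02 on a 0.60 proportion needs n over ~1,600) while keeping the
whole suite around a minute.

## Limitations

The pipeline consumes calls and per-base tracks, not reads: it cannot
re-genotype, so the merged analysis approximates rather than reproduces
merged-alignment calling. Genome-scale figures from any specific study
depend on the original alignments and are not desk-reproducible; this
package reproduces the *procedure* and verifies it on data whose truth is
known by construction.
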