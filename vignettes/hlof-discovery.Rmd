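---
title: "Discovering homozygous loss-of-function variants in exome cohorts"
author: "hlofscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering homozygous loss-of-function variants in exome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Every human genome carries premature stop-gain and frameshift variants,
and a handful of them are homozygous: natural gene "knockouts" (HLOFs,
homozygous loss-of-function variants). Cataloguing them in healthy,
population-based cohorts maps which genes tolerate complete inactivation.
The obstacle is that raw exome call sets are dominated by artifacts at
exactly these sites: sequencing and mapping errors masquerade as rare
homozygotes, reference-genome errors look fixed in every population,
annotation quirks (late-transcript truncations, codon-sharing SNPs,
frame-restoring indel pairs) produce variants that do not in fact destroy
the protein. `hlofscan` implements the whole discovery analysis — candidate
identification, a conservative artifact-filter cascade, run-of-homozygosity
(ROH) enrichment statistics, gene-set and tissue summaries, and a
burden-versus-extreme-phenotype regression — together with a synthetic
cohort generator that plants ground truth for every filter, so the
pipeline is testable end to end without access to individual-level human
data.

## Candidate identification and consequence model

Biallelic records (multi-allelic sites are decomposed with per-sample
allele dosage conserved) are classified against transcript models. For a
single-nucleotide variant the affected codon is translated strand-aware:
an alternate codon that is a stop while the reference codon is not is a
`stop_gain`. A coding indel whose in-CDS length is not a multiple of
three is a `frameshift`; a multiple of three is always `inframe`, never
loss of function — validation work on real call sets has repeatedly found
apparent frameshifts that in fact remove whole codons. Splice-disrupting
variants are out of scope by design. A *candidate* is any record with at
least one homozygous-alternate carrier and a stop-gain or frameshift
consequence in at least one transcript.

Indels are assumed left-aligned (the VCF convention); the first changed
base defines the affected codon. The relative position of a variant in a
transcript is `(first affected codon − 1) / protein length`, so the start
codon sits at 0 and the boundary of the final 10% of the protein at 0.9.

## The filter cascade

Each filter is a pure predicate evaluated independently on every
candidate; the survivor set is the intersection of the per-filter pass
sets, so the result cannot depend on filter order, and the audit reports
the count surviving each filter applied alone alongside the count
surviving all filters. Defaults:

| filter | rule | default |
|---|---|---|
| `relative_position` | keep variants in the first 90% of *every* coding transcript of the gene | 0.9 |
| `mapability` | drop if the reference span touches a low-alignability region (score < 1) in either track, or a blacklisted interval | — |
| `min_samples` | require genotypes in at least 200 individuals | 200 |
| `capture_intersection` | keep positions inside the padded targets of *both* capture kits | 50 bp pad |
| `ancestral` | stop-gains: drop if any primate carries the human alternate; frameshifts: drop only if ≥ 2 primates align and all match the indel's position, length and type | — |
| `mnp_codon` | drop stop-gains sharing a codon with another called SNP | — |
| `frameshift_rescue` | drop near pairs (< 10 aa) whose signed indel lengths sum to 0 mod 3, and all chains of ≥ 3 near frameshifts | 10 aa |
| `hwe` | drop if any population shows a significant homozygote excess | α = 0.01, ≥ 5× individuals |
| `coverage` | novel variants need one homozygote covered at ≥ 20×; known (previously validated) variants pass | 20× |
| `near_fixed` | drop variants with no homozygous-reference individual and ≤ 1 heterozygote cohort-wide | — |

Two readings of the relative-position rule are defensible; the
conservative one (early in *every* transcript) is the default and the
permissive one (early in at least one) is a switch (`rel_pos_mode`).
Similarly, the minimum-sample rule counts genotyped (non-missing)
individuals by default, and frame-restoration is evaluated per transcript
across the call set, with a per-carrier mode (`rescue_mode = "carrier"`,
interacting only when one individual is homozygous for both frameshifts)
available. Chains for the ≥ 3-frameshift rule link variants whose
consecutive affected codons are under 10 amino acids apart, with distances
measured in affected-codon indices on the linearized CDS. Hemizygous
calls are outside the diploid genotype model; a single-allele call would
have to be encoded as homozygous upstream.

## The exact homozygote-excess test

Genotyping errors at rare sites typically convert heterozygotes into
homozygotes, so the Hardy–Weinberg filter is one-sided. Conditional on
the sample size `n` and the alternate-allele count, the heterozygote
count under Hardy–Weinberg equilibrium follows the Levene–Haldane
distribution; the P-value is the probability of the observed heterozygote
count *or fewer*, summed over counts of matching parity. The exact
conditional formulation is essential here: nearly all candidates are
rare, where the chi-square approximation is badly anticonservative. The
test is applied to each population separately, over individuals covered
at ≥ 5×, and a variant fails when any population rejects at α = 0.01.
The test suite checks the implementation against an independent
dynamic-enumeration oracle on every genotype configuration up to n = 12.

A consequence worth noting: a lone homozygote with no heterozygous
support in a population of a few hundred is itself significant at 0.01
under the exact test. Real singleton HLOFs survive such a filter only
because their allele segregates as heterozygotes in the same population;
the synthetic generator reproduces exactly that structure (below).

## ROH enrichment

Long runs of homozygosity are identical-by-descent segments in which rare
alleles meet as homozygotes. For each surviving variant and homozygous
carrier the package asks whether the position falls inside any of the
carrier's ROH intervals (PLINK-style `.hom` input; 1-based inclusive;
overlapping intervals merged). Per population, the in-ROH fraction of
carrier observations is reported and contrasted between cohorts with
Fisher's exact test. Per variant, one-sided binomial tails at an expected
frequency equal to the overall in-ROH fraction classify it as
`inside_biased` or `outside_biased` at P < 0.1; the allele frequencies of
the two classes (denominator: two chromosomes per ≥ 5×-covered
individual) are compared with a Wilcoxon rank-sum test, flagged
untestable when either class has fewer than three variants. Carriers are
pooled across populations for the per-variant classification (a
per-population expected frequency can be supplied); the per-population
frequencies and Fisher contrasts retain the population structure.

## Enrichment, yield and burden statistics

Gene-set enrichment uses the ratio `(b/n)/(B/N)` over a background of
captured genes with a plain hypergeometric upper-tail P and
Benjamini–Hochberg FDR; threshold-optimising variants of the
hypergeometric statistic used by some web tools are deliberately not
reproduced, since the ratio is the published, testable object.
Tissue summaries take the argmax tissue per gene (ties credited
1/k each) and an "expressed" fraction above a configurable threshold —
the atlas normalisation behind such thresholds is not standardised, so
the matrix is taken as given. Yield is distinct HLOFs per individual
sampled; private LOFs are variants whose allele is confined to one
population, private HLOFs those homozygous in only one population while
segregating elsewhere.

The burden model regresses each individual's count of extreme trait
values (outside the within-population 1%/99% empirical order-statistic
quantiles, ties included, the focal individual included in the
distribution) on their HLOF burden and the number of traits measured,
per population, by ordinary least squares. Variant subsets (deleteriousness
score > 25; olfactory genes excluded) reuse the same machinery.
Rank-deficient designs (constant burden) are flagged rather than fitted.

## The synthetic study generator

`generate_study()` builds a full study from a seeded configuration;
identical seeds give byte-identical output files. The default emulates a
1432-exome design: one cosmopolitan cohort of 844 and four isolates
(193, 197, 98, 100), with per-individual ROH genome fractions of
0.03–0.10, mean ROH lengths of 2.0–2.6 Mb and mean depths of 19–60×
(depth per site ~ rounded Gamma, shape 6). Genes (340 by default, 150–350
codons, 1–3 CDS segments, both strands) sit on synthetic ~5 Mb contigs
with large intergenic gaps so that multi-megabase ROHs span many genes.
173 true HLOFs are planted (stop-gain : frameshift ≈ 94 : 79) along with
a dozen artifacts per filter category, each constructed to fail exactly
its designated filter and pass all others, plus 2000 neutral non-coding
sites for calibration.

Key generator mechanics, all of which are deliberate modelling choices:

* **Autozygosity is mechanistic.** At any drawn site, an individual whose
  ROH covers the position is homozygous (alternate with probability equal
  to the allele frequency); everyone else is drawn under Hardy–Weinberg.
  Heterozygosity inside ROHs is therefore exactly zero, and the
  published rare-inside/common-outside ROH contrast emerges from the
  model rather than being painted on: for a rare allele, almost the only
  way to be homozygous is autozygosity.
* **True variants span the frequency spectrum.** Roughly 70% are rare
  with 2–3 forced carriers in isolate cohorts and a forced covering ROH;
  the rest are intermediate or common (some cosmopolitan-skewed), drawn
  under the autozygosity-coupled Hardy–Weinberg model. This yields a
  median per-individual burden near the published 7–10 range and provides
  both bias classes for the allele-frequency contrast.
* **Planted variants that must pass the HWE filter are drawn
  conditionally.** Forced rare carriers receive heterozygous support in
  their population until the exact test clears 0.10; drawn
  intermediate/common columns are redrawn until every population clears
  0.05. Without this conditioning, chance rejections at α = 0.01 would
  contaminate a truth table that the specification requires to be
  recovered perfectly — and it mirrors the real phenomenon that
  surviving singletons always had heterozygous support. Planted
  genotyping-error variants go the other way: heterozygotes are converted
  to homozygotes until the exact test rejects at 0.01.
* **Calibration is checked on a null cohort.** Autozygosity violates
  Hardy–Weinberg by construction, and at the default cohort size nearly
  every site lies in someone's ROH, so the rejection-rate calibration of
  the filter is evaluated on a cohort generated with
  `roh_genome_fraction = 0` — 2000 neutral sites across five populations,
  where the union rejection rate must stay within three binomial
  standard errors of 5 × 0.01.
* **Phenotypes.** Traits are standard normal with 10% missingness. A
  planted burden effect adds, per individual, Poisson(β × burden) traits
  forced to ~5 SD with random sign, so the expected extreme-trait count
  is linear in burden with slope β. Parameter-recovery experiments use
  867 traits — the largest trait panel in the study design this emulates —
  because with small panels the planted extremes themselves shift the
  empirical 1% quantiles and attenuate the recovered slope.
* **Annotation tables.** Deleteriousness scores (range ~1.4–44, median
  near 20) decrease with carrier count; gene-set annotations place an
  olfactory-receptor-like term and a GPCR-like term preferentially on
  HLOF genes within a universe that includes background-only genes;
  the 16-tissue expression matrix biases a quarter of HLOF genes towards
  a testis maximum; paralogue counts are lower for HLOF genes. These are
  direction-level emulations for exercising the statistics, not
  calibrated reproductions of any real annotation resource.

What the generator does *not* model: linkage disequilibrium, read-level
errors, NMD, splice variation, X-hemizygosity, or real chromosome
geometry. Passing tests therefore demonstrate the correctness and
calibration of the statistical machinery on data with the stated
structure, not performance on real exomes — in particular, the published
absolute per-filter survivor counts depend on the real call set and are
not reproducible from synthetic data.

## Numerical choices

* Coordinates are 1-based inclusive internally; BED I/O converts at the
  boundary. `.hom` interval lengths use the inclusive length
  `(end − start + 1)/1000` kb.
* Extreme-trait thresholds use type-1 (order-statistic) empirical
  quantiles with ties included on both sides.
* Spearman correlations use average ranks for ties; degenerate inputs
  (constant scores, < 3 values) are flagged untestable rather than
  returning NaN.
* Wilcoxon comparisons request the exact distribution and fall back to
  the normal approximation under ties; Fisher tests are two-sided
  hypergeometric with P = 1 whenever a margin is zero.
* The cascade's audit counts a subset-specific filter (frameshift
  rescue) as passing every candidate it never examined, so single-filter
  counts are comparable across rows.

## Problem sizes

The shipped tests and the acceptance script run, per invocation: one
default-scale study (1432 individuals, ~2300 sites) through the full
cascade; nine further default-scale studies for the allele-frequency
direction check; one 2000-site null cohort for filter calibration;
and fifty 500-individual, 867-trait cohorts for burden-effect recovery.
Exact-test oracles cover every configuration up to n = 12 (genotypes),
n = 8 (binomial), and N = 25 (hypergeometric).
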