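---
title: "Statistical methods behind reefcross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind reefcross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the generative model assumed by the `reefcross`
simulator, the statistical methods implemented by each analysis stage,
the rationale for the shipped defaults, and the known limitations of the
per-locus tests.

## The experiment being modelled

Two source populations segregate at `n_loci` biallelic loci: a
hot-adapted population ("PG") and a cool-adapted one ("IO"). Parents are
crossed in a dam × sire design with three family categories — hot
purebreds, cool purebreds, and one-direction hybrids (cool dam × hot
sire). Larvae of every family are split across temperatures and replicate
plates; survival to 60 h is scored, and the survivors of each family ×
temperature are pooled and sequenced.

The default design (`make_cross_design()`) realizes 50 families from 17
sires and 4 dams: 18 PG, 12 IO, 20 PG×IO.

## Simulator

`simulate_populations()` draws ancestral allele frequencies uniformly on
(0.05, 0.95) and perturbs them symmetrically in the two populations
(`divergence` is the standard deviation of that perturbation). Causal
loci instead carry a heat-beneficial derived allele at frequency
`beneficial_freq_hot` / `beneficial_freq_cool`, with a configurable
fraction fixed in the hot population.

Larval survival is Bernoulli with

```
logit p = baseline(T) + scale(T) * (sum_j effect_j * copies_j - anchor)
          + dam_effect + family_effect
```

`scale(27) = 0`, so genetic effects act only under heat; the anchor is
the expected beneficial load of an idealized hybrid larva, which makes
`baseline_survival` interpretable as the survival of an average hybrid.
Non-causal loci are conditionally independent of survival given the
parents, so survivor-pool frequencies at those loci are drawn directly
from each parent's transmission probability — an exact shortcut that
avoids simulating full larval genotypes.

Read counts (`emit_read_counts()`) use Poisson (or negative-binomial)
depth, binomial allele sampling, and uniform base-flip errors.

## Genotyping

`call_parent_genotype()` applies three rules in order: alleles carrying
strictly less than 5% of reads are discarded as sequencing error
(an exactly-5% allele is retained); genotypes are called only when the
remaining coverage is at least 5 reads; more than two surviving alleles
set the site to missing. Scores are distance-from-reference: 0, 0.5, 1.

Pooled frequencies use one *global* minor allele per locus, designated
from the combined ambient pools (`designate_minor_alleles()`), so that
frequencies are comparable across samples and temperatures; a
consequence is that an individual sample's frequency of the global minor
allele may exceed 0.5. Pool calls require 50× coverage and are
scale-free in the counts.

## Heritability

`estimate_heritability()` fits `y = mu + sire + dam + e` with normal
random effects and scaled-inverse-chi-square priors (`nu = 0.002`,
`V = 1`) by a Gibbs sampler written in C++ (all conditionals are
conjugate). Additive genetic variance uses the paternal half-sib
identity `V_A = 4 V_sire`; the dam component absorbs maternal and
common-environment variance. Two heritabilities are reported per draw:
`V_A / (V_A + V_R)` and `V_A / (V_A + V_M + V_R)`. The default chain
(10^5 iterations, 10^4 burn-in, thinning 10) runs in well under a second
at the 150-observation design scale; coverage of the 95% credible
interval was verified by simulation from the model on the realized
design.

## Association scan

For each locus, hot-temperature family survival counts are regressed on
the family's ambient pool frequency with a binomial logistic model, with
parental origin as a fixed covariate, and the frequency slope is tested
by likelihood ratio. Pearson's R between frequency and raw survival
classifies loci (`strong` at |R| ≥ 0.5; `moderate_weak` when nominally
associated); Bonferroni adjustment runs over the loci actually tested.

### Limitation: families are not independent in crossed designs

The per-locus model treats families as independent observations. In a
crossed design they are not: families share parents, so a null locus
whose *parental* genotypes happen to correlate with the parents' causal
load inherits that correlation in every cross, and the chance
correlation floor scales like `1/sqrt(n_parents)` — dominated by the dam
channel when dams are few. The same mechanism applies to any
genotype-independent family-level survival noise (e.g. maternal
effects): with 4 dams, a dam intercept moves survival while every
locus's frequency co-varies with dam identity through inheritance. On
few-parent crossed designs the scan is therefore well calibrated only
under binomial sampling noise; its Bonferroni-significant set should be
read as "associated with survival *or* with a survival-correlated
lineage". This is a property of the method, not of the implementation,
and it is why power studies of the scan in the test-suite use designs
with independent parents per cross.

## Selection scan and hybrid PCA

`scan_selection()` compares minor/major read counts of each family's
heat-exposed pool with its ambient pool after normalizing libraries to
the median total depth, using the closed-form binomial likelihood-ratio
(G) statistic of the temperature term — identical to the binomial-GLM
deviance test. Swapping the temperature labels flips the sign of the
mean shift and leaves p values unchanged. `summarize_selection()`
contrasts fixation (ambient frequency below 0.01) of heat-selected
alleles between the purebred groups.

`hybrid_shift_pca()` projects all pools onto the top two principal
components of the strongly responding hybrid loci (adjusted p below
0.001, under 10% missing data, group-mean imputation, deterministic sign
convention). Under heat selection the hybrid 36 °C centroid moves toward
the hot-purebred centroid. At desk scale the fixed `p < 0.001` filter is
demanding: with ~100 pools at ~120× only a handful of loci pass, so the
PCA degrades gracefully into an informative error naming the binding
filter when fewer than two loci survive.

## Enrichment

`fisher_enrichment()` computes the one-sided hypergeometric tail
`P(X >= k)` for every GO term against the background of genes containing
tested SNPs, flags terms with `p < 0.05` that occur at least 5 times in
the background, and optionally propagates annotations up the ontology
(true-path rule). No multiple-testing correction is applied across
terms.

## Defaults

All thresholds default to the values used throughout the package's
documentation: 5% error frequency and 5× coverage for parents, 50× for
pools, |R| ≥ 0.5 for the strong class, frequency < 0.01 for fixation,
adjusted p < 0.001 and < 10% missingness for the PCA, and GO
significance at p < 0.05 with ≥ 5 background occurrences
(`default_run_config()`). The simulator defaults (2,000 loci, 20 causal,
50 families, 270 larvae per family across 27/33/36 °C, 120× pools)
are sized so the full pipeline completes in seconds on one CPU while
preserving the qualitative behaviour of the full-scale experiment:
origin-level survival ordering, detectable heat selection, and
informative-but-noisy per-locus association.

```{r example}
library(reefcross)
res <- run_pipeline(default_run_config(), tempfile("artifacts"), seed = 1)
summarize_association(res$assoc$scan)
res$phenostats$heritability[["36"]]
```
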