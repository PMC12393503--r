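---
title: "Methods: temporal reprogramming, exposure signatures and the sex discrepancy score"
author: "toxitemporal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal reprogramming, exposure signatures and the sex discrepancy score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxitemporal)
```

## The study design this package models

`toxitemporal` analyses longitudinal multi-omic cohorts of the kind produced
by early-life toxicant-exposure studies in the mouse: offspring exposed from
preconception through weaning, then raised unexposed and profiled at weaning
(3 weeks), young adulthood (5 months) and later adulthood (10 months), in
both sexes, in a target tissue (liver) and a surrogate tissue (blood), under
a vehicle control and nine exposure conditions (arsenic, lead, bisphenol A at
10 µg and 10 mg/kg bw/day, DEHP, TBT, TCDD, and concentrated PM~2.5~ from two
collection sites). `exposureRegistry()` fixes these conditions; age is an
ordered factor (`3wk < 5mo < 10mo`) whose order is set in code, never
inferred from strings.

The pipeline consumes *normalized* values (RPKM-like expression, accessibility
signal, methylation beta fractions), not read counts. All group definitions
come from the seven-column sample table validated by `ExposureExperiment()`;
cells with fewer than `minReplicates = 3` samples are flagged by
`validateDesign()` and excluded from contrasts rather than silently pooled.

## Differential model

For a contrast of an exposed group $B$ against its matched control $A$
(same tissue, sex, age), each feature is tested with Welch's
unequal-variance $t$ on $\log_2(x + 1)$ (expression, accessibility) or raw
$\beta$ (methylation):

$$\hat\delta_g = \bar y_{gB} - \bar y_{gA}, \qquad
t_g = \frac{\hat\delta_g}{\sqrt{s^2_{gA}/n_A + s^2_{gB}/n_B}},$$

with Welch–Satterthwaite degrees of freedom, Benjamini–Hochberg adjustment
*per contrast* (matching the per-exposure semantics of signature
decomposition), and a call rule $q < q_{\max}$ **and**
$|\hat\delta_g| \ge \delta_{\min}$. Defaults are $q_{\max} = 0.05$ and
$\delta_{\min} = 1$ log~2~ unit (2-fold) for expression/accessibility and
$0.1$ $\Delta\beta$ for methylation — conventional values, all overridable.
A simple location test was chosen deliberately over count-model machinery
(negative-binomial GLMs, dispersion shrinkage): the inputs are normalized
continuous values, the test is exactly checkable against an independent
oracle, and the synthetic-cohort calibration below verifies its FDR control
in the regime the pipeline runs in. Degenerate rows (zero variance in both
groups) get $p = 1$ when means agree and $p = 0$ with an explicit
degeneracy flag when they differ.

Signature decomposition classifies each significant feature as
*exposure-specific* (significant in exactly one exposure) or
*multi-response* ($\ge 2$ exposures); the two classes partition the union,
which is enforced by a class validity check. Cross-tissue concordance
partitions jointly significant genes by direction agreement
(common-up, common-down, anticorrelated) plus tissue-exclusive sets.

## Temporal pattern classification

A gene's trajectory across the three ages is summarized by the direction of
change over each age interval (3wk→5mo, 5mo→10mo). A direction is `up`
(resp. `down`) iff the interval change passes **both** a per-interval
BH-adjusted test ($q < 0.05$) and an effect floor
($|\hat\delta| \ge \log_2 1.5 \approx 0.585$); otherwise `flat`. The effect
floor matters: under a pure significance rule, "flat" would shrink with
sample size until every gene "changed", which is a statistical artifact,
not biology. Both thresholds are configurable.

The nine direction pairs map bijectively onto patterns 1–9:

| pattern | 1 | 2 | 3 | 4 | 5 | 6 | 7 | 8 | 9 |
|---|---|---|---|---|---|---|---|---|---|
| 3wk→5mo  | down | up | up | down | up | down | flat | flat | flat |
| 5mo→10mo | down | up | down | up | flat | flat | up | down | flat |

Patterns {1, 6, 8} are net-decreasing, {2, 5, 7} net-increasing, and 9 flat
throughout, matching the field's grouping of liver aging trajectories. The
within-group ordering (e.g. 3 vs 4) is this package's fixed convention.
Patterns are derived per sex, with separate control references for females
and males. Genes with mean expression below `exprFloor = 1` at *every* age
are reported as unclassified rather than defaulted to a pattern, so
noise-dominated genes cannot churn the denominators.

*Reprogramming* is a gene occupying a different pattern under exposure than
in the matched control; `disruptionSummary()` reports per-pattern
percentages over co-classified genes, `transitionMatrix()` the full 9×9
flow (the input to alluvial plots), and `multiExposureDisruption()` the
genes disrupted by at least $k$ exposures (default $k = 4$).

## Embedding and the sex discrepancy score

`fitEmbedding()` computes principal components of $\log_2(x+1)$ data,
centered per gene, **fit on controls only** (one tissue, both sexes, all
ages); exposed samples are projected into this basis rather than refit, so
the basis is not rotated by the exposures being measured. Component signs
are fixed by making the largest-magnitude loading of each column positive —
PCA is otherwise sign-ambiguous and irreproducible across BLAS builds.
Exposure displacement is the Euclidean distance to the age- and sex-matched
control centroid in the first three components.

The *sex discrepancy score* of a sample with coordinates $x$ at age $a$ is

$$s(x) = \frac{(x - \mu_F^{(a)}) \cdot (\mu_M^{(a)} - \mu_F^{(a)})}
              {\lVert \mu_M^{(a)} - \mu_F^{(a)} \rVert^2},$$

the signed scalar projection onto the female-to-male control-centroid axis,
normalized by the centroid span. By construction the female control centroid
scores exactly 0 and the male centroid exactly 1 at every age, making
deviations comparable across ages. Whether such a score should be a signed
projection or an unsigned distance is genuinely open; the projection is the
default because it distinguishes feminization (toward 0) from
masculinization (toward and past 1) in males, and an unsigned variant
(`unsigned = TRUE`) is provided. Scoring uses the full set of fitted
components passed in; the worked examples use 2–3 components, where the sex
axis is well captured in the synthetic cohorts.

Exposure deviation $\Delta = \bar s_{\text{exposed}} - \bar s_{\text{control}}$
(same sex and age) is tested by a two-sided permutation test over
exposure-label shuffles with the add-one estimator
$p = (1 + \#\{|\Delta^\ast| \ge |\Delta|\})/(B + 1)$, $B \ge 1000$, so $p$
is never exactly zero. `feminizationAnalysis()` then classifies each
sex-biased gene (from `sexBiasedGenes()`, a male-vs-female control contrast)
by whether a significant exposure-induced change moves its mean toward or
away from the opposite sex's control mean.

## Chromatin-state switching

Differential regions are annotated against paired (control, exposed)
segmentations by *majority overlap*: the state covering the largest number
of the region's bases wins, with ties broken by the state covering the
leftmost overlapped base — a deterministic, order-independent rule chosen
because overlap conventions differ between tools and none is canonical. A
label change is a *switch*; an active↔inactive class change (under a
user-supplied state→class map, since which states count as "active" is a
modeling choice of the segmentation) is a *class switch*; label-only changes
within a class are reported but not counted as class switches. Regions
overlapping no interval are counted as unannotated, never dropped.

Internally all intervals are `GRanges` (1-based, closed, per Bioconductor
convention); BED files are read and written with BED's 0-based half-open
semantics at the file boundary, so a BED interval of length $L$ always
round-trips with $end - start = L$.

## Over-representation analysis

`ora()` is a one-sided hypergeometric test, $P(X \ge k)$ via `phyper`,
BH-adjusted across the tested sets. The universe is an explicit argument —
conventionally the classified/testable genes of the upstream analysis, not
the whole genome — because conditioning on testability is what makes the
null hypergeometric. Sets are intersected with the universe before testing
and sets smaller than `minSetSize = 5` are skipped. Ranked (GSEA-style)
enrichment is out of scope.

## The synthetic cohort generator

`simulateCohort()` and its siblings generate truth-tracked cohorts with the
statistical structure the analyses assume. The log~2~ expression of gene
$g$ in a sample is

$$\mu_g + \text{pattern steps}(g, \text{age}) + \text{sex offset}(g)
 + \text{exposure effect}(g) + \varepsilon, \quad
 \varepsilon \sim N(0, \sigma^2),$$

and the stored matrix holds $2^{\text{value}} - 1$, clamped at zero.
Defaults encode the emulated study conditions: 2,000 genes, 5 replicates
per cell, interval steps of 2.0 log~2~ units, noise $\sigma = 0.25$
(log-normal noise on the raw scale, matching RPKM-like heteroscedasticity;
$\sigma = 0$ gives an exact noiseless fixture), baselines uniform within
±1 log~2~ unit of 5, and 60 sex-biased genes at 2.0 log~2~ units held
constant across ages (sex differences in liver are established before
puberty and persist, so a constant offset is the simplest conforming
structure). Per-exposure differential signatures are 40 exposure-specific
genes plus a 90-gene pool perturbed by every exposure, planting a
multi-response fraction of exactly $90/(9 \cdot 40 + 90) = 0.20$ of the
nine-exposure union — inside the 15–24% band reported for real cohorts.
Methylation defaults plant 400-of-2000-region shifts of $|\Delta\beta| =
0.3$ with 90% hypomethylation (beta noise 0.05, baselines in 0.35–0.65 so
truncation to $[0,1]$ stays negligible), emulating the strongly
hypomethylation-skewed blood DMR response. Temporal reprogramming is
planted by replacing a gene's interval steps under exposure with the target
pattern's steps — exactly the alluvial semantics the temporal module
measures. An optional `feminization` fraction removes that share of the
sex-biased offset in exposed animals. Paired segmentations differ at
exactly `nStateSwitch` planted regions where the covering state flips
class.

Each modality draws from its own RNG stream derived from the master seed by
a fixed offset, so adding a modality never perturbs another's draws, and
identical configurations are bitwise reproducible.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: litter-correlated noise (real replicates share dams;
the generator's samples are independent), count-level sampling noise,
batch/production-center effects, dose–response structure, and correlation
between omic layers beyond the planted effects. Recovery rates on synthetic
cohorts are upper bounds for real data, where these nuisances bite.

## Numerical choices and degenerate inputs

* BH ties resolve by the standard cumulative-minimum step-up
  (`p.adjust(method = "BH")`); deterministic.
* Zero significant features make direction summaries explicitly undefined
  (`defined = FALSE`), never 0/0; an empty signature union makes the
  multi-response fraction `NA` with a warning.
* `hypergeomTail()` delegates to `phyper`, which works in log space, so
  $p \sim 10^{-300}$ tails are representable.
* Pseudocount 1 before log~2~ keeps zero values finite and planted fold
  changes exact on the transformed scale used throughout.
* The permutation p never reaches 0 (add-one estimator), and
  `scoreDeviation()` refuses fewer than 100 permutations.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
2,000-gene cohorts with 5 replicates per cell for pattern recovery,
reprogramming (600 planted switches, 30%) and cross-tissue concordance
(50 liver DEGs, 40% blood-detectable, 90% same-direction); 200 null
contrasts of 5,000 features for FDR calibration; 1,000 random instances
each for the Welch and SVD oracle comparisons; 20 seeded 400-gene runs for
the feminization permutation power check; and exhaustive enumeration of
every hypergeometric tail with universe size up to 15. These sizes make
every Monte-Carlo criterion stable across seeds while keeping a full run in
well under a minute of CPU.

## Known limitations

* No covariate adjustment, paired designs or random effects; litter
  structure in particular is ignored both in the tests and the generator.
* Exactly three timepoints are assumed; no smooth trajectory modelling.
* The pattern-id convention fixes the within-group ordering of patterns
  {3, 4} and {5, 6, 7, 8}; comparisons with externally numbered pattern
  sets should map via the direction pairs, not the ids.
* Dataset-level counts from real consortium cohorts (total DEGs per sex,
  state-switch tallies at specific exposures) depend on the full portal
  data and its upstream processing and are not targets of this package's
  checks.
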