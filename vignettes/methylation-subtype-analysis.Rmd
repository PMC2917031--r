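---
title: "Methylation profiling of breast cancer molecular subtypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation profiling of breast cancer molecular subtypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methsubtype)
```

## The analysis problem

Array-based methylation assays of the GoldenGate type report, for each of
roughly 1,500 cancer-related CpG sites, a β-value in [0, 1]: the fraction of
fluorescence attributable to the methylated allele. Breast tumours fall into
expression-defined molecular subtypes (basal-like, luminal A, luminal B,
HER2-enriched, normal-like), and the question this package addresses is
whether those subtypes carry characteristic promoter-methylation profiles:
which CpG sites distinguish the subtypes, whether methylation is globally
anti-correlated with expression, and whether polycomb (PRC2) target gene
sets are differentially methylated between subtypes.

`methsubtype` implements the full analysis path: β-value stratification,
per-sample methylation frequencies, mean-centred relative methylation,
variability filtering, unsupervised clustering under Pearson correlation
distance, cluster–annotation association, permutation-based differential
methylation (one-way ANOVA with false-significant-number control, and a
SAM-style two-class test), methylation–expression integration with an exact
binomial sign test, nearest-centroid (SSP) subtype classification, and
gene-set scoring — plus a synthetic-data generator that emits all of the
above with a recorded ground truth.

## The core procedure

**Stratification.** β ≤ 0.3 becomes 0 (unmethylated), 0.3 < β < 0.7 becomes
0.5 (hemimethylated), β ≥ 0.7 becomes 1 (hypermethylated). The boundary
semantics (≤ at the low threshold, ≥ at the high one) are part of the
contract and tested exactly. All downstream analysis uses stratified data.

**Methylation frequency.** A sample's frequency is the fraction of its
informative CpGs with value 1. Missing β-values are excluded from both
numerator and denominator, which is the only convention that keeps the
frequency in [0, 1] under missingness.

**Relative methylation.** Each CpG row is centred by its mean over the
tumour samples. Normal-tissue samples are centred with the same
tumour-derived mean, so their relative levels are comparable to the
tumours'. Rows therefore average zero over tumours (to 1e-9).

**Variability filter.** CpGs with sample standard deviation below 0.3
(denominator n − 1) are dropped before clustering. Because centring shifts a
row by a constant, the filter is indifferent to whether it sees ternary or
relative values, and a property test asserts that.

**Clustering.** Sample–sample distance is `1 − r` (Pearson, over
pairwise-complete positions). Hierarchical clustering is UPGMA (unweighted
average linkage), delegated to `stats::hclust(method = "average")` and
validated in the test suite against a brute-force O(n³) oracle that
recomputes every between-cluster average at every step; tie handling is
therefore `hclust`'s, which is deterministic for a given input (ties have
measure zero for continuous profiles). K-means under correlation distance is
not provided by `stats::kmeans` (Euclidean only), so the package implements
Lloyd iteration directly: assignment to the least-distant centroid, centroid
= per-CpG mean of members, best of `restarts` random starts by total
within-cluster distance, emptied clusters re-seeded from the farthest
sample. A seed is mandatory and the run is bit-reproducible from it; 50
restarts is the default.

**Cluster–annotation association.** For each (cluster, annotation level)
pair a 2×2 table — in/out of cluster × is/is-not level — is tested with
two-sided Fisher's exact test. For molecular subtype, samples labelled
non-classified or non-GEX are excluded entirely by default, mirroring an
analysis restricted to expression-classified tumours.

## Differential methylation

**Permutation ANOVA with FSN control.** Per CpG, the classical one-way F
statistic across the five subtypes; the null comes from sample-label
permutations applied identically to every CpG (1,000 by default), so the
between-CpG correlation structure is preserved. Each CpG's permutation
p-value is the upper-tail fraction of its own null. The *false significant
number* at a candidate cutoff is the mean, over permutations, of the number
of CpGs whose permuted p-value falls at or below the cutoff; the procedure
returns the largest selection whose FSN is at most `fsn_max` (default 10)
and reports the implied FDR = FSN / n selected.

The p-values feeding the sweep can be raw (default) or
Bonferroni-adjusted. The two variants differ in how far the selection
extends into the noise: with raw p-values the sweep keeps admitting CpGs
until the FSN budget is spent, so the implied FDR settles near
`fsn_max` / n selected (a few percent at typical panel sizes); with
adjusted p-values the sweep stops at the permutation floor, the achieved
FSN is essentially zero, and the implied FDR is at the sub-percent level.
When a percent-level FDR is the goal — as in the validation runs of
`scripts/acceptance.R` — the adjusted variant is the appropriate one; note
that a mean-FSN budget of 10 with a few hundred selected CpGs cannot
arithmetically yield an FDR below 1% under the raw rule.

**SAM two-class test.** The relative difference
`d = (mean_in − mean_out) / (s + s0)`, with `s` the pooled standard error
and `s0` the exchangeability factor chosen to minimise the coefficient of
variation of d's spread (median absolute deviation) across 5%-windows of
`s`. Ternary data make many rows exactly constant (zero pooled error), so
when the CV search lands on a zero quantile, `s0` falls back to the 5th
percentile of the positive errors. Observed order statistics are compared
with their permutation expectations; for a threshold Δ the positive cut is
the smallest non-negative `d_(i)` deviating from expectation by at least Δ
(symmetrically for the negative cut), and the reported Δ is the smallest
whose permuted false-call summary, divided by the number of calls, meets the
target FDR (0 by default). The false-call summary is the per-permutation
count of null statistics beyond the cuts, summarised by the median (default)
or the mean. At a target of 0 the two differ materially: the median rule
lets a lone extreme feature through on null data roughly half the time
(its exceedance count has median zero even when its mean is positive),
while the mean rule demands zero *expected* false calls and is call-free on
null data in about 96% of runs. Validation runs use the mean for that
reason; the median remains the default because it is the conventional
SAM summary.

## Integration, classification, gene sets

**Methylation–expression pairs.** CpG sites and expression probes are
matched by gene symbol (upper-cased, whitespace-stripped, no alias
resolution) as a full within-gene cross product. Pairs whose relative
methylation never changes across the shared samples are flagged
`constant-methylation` and carry no correlation — a real phenomenon on
ternary data, not an error. Remaining pairs get Pearson r over
pairwise-complete samples (at least 3 required). The global inverse
association is an exact two-sided binomial test on the number of negative
coefficients among varying pairs at p₀ = 0.5, using the "minlike"
convention of `stats::binom.test` (sum of all outcome probabilities not
exceeding the observed one); r = 0 counts as non-negative, which is
conservative for the inverse-correlation claim.

**SSP classification.** Probes are collapsed to genes (per-gene mean by
default), symbols matched to the centroid table, and each sample assigned to
the centroid with the highest Pearson correlation, or `non-classified` if
every correlation is below 0.2. Classification inherits Pearson's
invariance to positive affine transforms, and raising the cutoff can only
move labels to `non-classified` — both are property-tested. Centroid tables
are an input file: real centroid tables are external data, and the
test suite uses synthetic centroids throughout.

**Gene-set scores.** The methylation score of a set is the unweighted mean
over all matching CpG *sites* (so genes with more CpGs weigh more — the
CpG-level definition), the expression score the mean over matched genes
after probe collapsing. Contrasts across subtypes delegate to the classical
tests (`aov`-equivalent F, t, Wilcoxon); `compare_set_vs_rest` compares
per-CpG mean relative methylation between set and non-set CpGs within a
sample group with a two-sample t-test.

## The synthetic-data generator

`simulate_study()` is first-class, tested code that defines the conditions
under which the pipeline is validated. Its defaults mirror the reference
study design: subtype sizes 43 (basal-like), 46 (lumA), 35 (lumB),
14 (HER2-enriched), 17 (normal-like) plus 4 normal-tissue samples; baseline
per-subtype methylation probabilities 0.276/0.311/0.351/0.278/0.275
(normal tissue 0.273), i.e. the benchmark frequency ordering with lumB
highest and normal tissue lowest; 500 CpGs on 250 genes; 50 planted
differential CpGs at effect 0.4 on the ternary scale; a coupling fraction
of 0.44 so that the expected share of negative methylation–expression
correlations, φ + (1 − φ)/2, is 72%, the benchmark value for this assay class.

β-values are generated as M/(M+U) from two lognormal channel intensities,
honouring the assay's ratio semantics. Each CpG × group carries a latent
state (unmethylated / variable / methylated) whose channel means put the
resulting β below 0.3, across the interior, or above 0.7 with high
probability, so stratification recovers the latent state and the
hypermethylation frequency tracks the planted state frequency (within
±0.03, tested).

Two structural choices deserve emphasis:

* **Comonotone state coupling.** Latent states are driven by a single
  uniform draw per CpG compared against each group's methylation
  probability, so a group with higher probability is methylated at a
  *superset* of CpGs. This preserves the configured frequency ordering and,
  crucially, makes the equal-probability configuration exactly null per
  CpG — which is what the FDR and type-I calibration tests require to be
  honest.
* **Nearest-state planting.** A planted differential CpG moves its target
  subtype to the latent state whose expected stratified value is nearest to
  the other subtypes' value ± the configured effect. A direction that would
  clamp at 0 or 1 (no realisable effect) is swapped for the feasible one,
  and the realised sign is recorded in the truth table; recovery oracles in
  the tests use the recorded truth, never the nominal effect.

Expression is per-gene baseline plus a subtype shift for marker genes
(which define the centroid table), minus `coupling_strength` times the
centred per-gene methylation for coupled genes, plus Gaussian noise;
a fraction of genes carries a second, noisier probe; rows are centred
across tumours. One random stream per output matrix is split from the
master seed, so enlarging one output does not perturb the others.

What the generator does **not** emulate: probe-level chemistry artifacts
(dye bias, bisulfite-conversion failure), CpG–CpG spatial correlation along
promoters, copy-number effects on β, and the heavy-tailed per-sample
heterogeneity of real tumours (states are shared within a subtype, so
within-subtype variance is purely assay noise plus the hemimethylated
state). Passing tests therefore demonstrate correctness of the statistical
machinery under a faithful but idealised model, not robustness to every
artifact of real arrays.

## Numerical choices and degenerate inputs

* Permutation p-values use the add-one convention `(b + 1)/(B + 1)` for
  sampled permutations and the plain fraction for exhaustive enumeration
  (which contains the identity).
* Constant profiles: correlation-undefined vectors raise errors in distance
  computations; in K-means a constant profile is treated as maximally
  distant (d = 2); constant CpG rows get F = 0 and d defined through s0.
* Missing values propagate: a missing β stratifies to missing and is
  excluded from means, SDs, frequencies and correlations with the
  denominator reduced; a CpG with no informative value in the centring set
  becomes all-missing with a warning.
* The Wilcoxon test is exact for groups of at most 25 untied values, and a
  normal approximation with continuity correction otherwise; the t-test is
  Welch by default with a pooled-variance switch.
* Validation problem sizes: 500 CpGs × 155 tumours with 1,000 permutations
  for the ANOVA recovery run; 50–100 seeds of 80 CpGs × 24 samples at 100
  permutations for SAM null specificity; 200 replicates for type-I
  calibration — sizes at which every check completes in seconds while the
  binomial/hypergeometric oracles remain exact.

## Known limitations

* The UPGMA tie rule is whatever `stats::hclust` implements; merge lists
  are reproducible for fixed input but a prescribed lowest-index tie-break
  is not enforced.
* The FSN sweep evaluates candidate cutoffs only at observed p-values, as
  any selection-changing cutoff coincides with one.
* Gene matching is by symbol only; probes or CpGs annotated to aliases of
  the same gene are treated as different genes.
* `read_beta_matrix` expects the deposited tab-delimited layout (id column,
  one gene column, numeric sample columns); IDAT and GEO SOFT formats are
  out of scope.
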