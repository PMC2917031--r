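# methsubtype

Analysis pipeline for array-based CpG methylation profiles of breast
tumours and their expression-defined molecular subtypes (basal-like,
luminal A, luminal B, HER2-enriched, normal-like).

GoldenGate-style methylation arrays report a β-value per CpG site and
sample — the methylated fraction of signal, in [0, 1]. This package
implements the standard analysis path over such data, for researchers who
want the individual steps as tested, composable functions rather than a GUI
workflow:

* **Stratification**: β ≤ 0.3 → 0, 0.3 < β < 0.7 → 0.5, β ≥ 0.7 → 1
  (hypermethylated); per-sample methylation frequency = fraction of CpGs
  at 1; per-CpG mean-centring across tumours to *relative methylation
  levels*; SD ≥ 0.3 variability filter.
* **Unsupervised structure**: UPGMA and K-means clustering of samples under
  Pearson correlation distance d = 1 − r; cluster↔annotation association by
  two-sided Fisher's exact test on 2×2 tables.
* **Differential methylation**: permutation one-way ANOVA with
  false-significant-number (FSN) control — per-CpG F statistics, a shared
  label-permutation null, and the largest selection whose expected number
  of false significants stays within budget; and a SAM-style two-class
  test, d = (mean_in − mean_out)/(s + s₀), with the Tusher s₀ search and a
  Δ threshold tuned to a target permutation FDR.
* **Methylation–expression integration**: within-gene CpG × probe pairing,
  per-pair Pearson correlation, and an exact two-sided binomial sign test
  for the global excess of negative correlations.
* **Subtype classification**: nearest-centroid single-sample predictor
  (SSP) — Pearson correlation of each expression profile to each subtype
  centroid, abstaining below r = 0.2.
* **Gene-set scoring**: average relative methylation (CpG-level) and
  expression (gene-level) of gene sets such as PRC2/SUZ12 target lists,
  with subtype contrasts and set-vs-rest comparisons.
* **Synthetic data**: `simulate_study()` generates β-values (as M/(M+U)
  from lognormal channel intensities), coupled expression, annotations,
  gene sets and centroids with a full ground-truth record, at defaults
  mirroring the reference study design (155 tumours across five subtypes
  plus 4 normals).

I/O covers the deposited-table dialects: tab-delimited β and expression
matrices with a gene-symbol column, annotation and centroid TSVs, and GMT
gene sets.

## Worked example

```r
library(methsubtype)

cfg <- simulation_config(seed = 42)      # reference-size study conditions
sim <- simulate_study(cfg)

tern <- stratify(sim$beta)               # beta -> {0, 0.5, 1}
tumours <- sim$annotation$sample_id[sim$annotation$tissue == "tumour"]

freq <- methylation_frequency(tern)
round(tapply(freq$methylation_frequency,
             sim$truth$sample_subtype[freq$sample_id], mean), 3)
#>    basal-like HER2-enriched          lumA          lumB        normal
#>         0.286         0.286         0.320         0.404         0.288
#>   normal-like
#>         0.282

rel <- centre(tern, centring_samples = tumours)
res <- permutation_anova(subset_samples(rel, tumours),
                         sim$truth$sample_subtype[tumours],
                         n_perm = 1000, seed = 7, adjust = "bonferroni")
cat(sum(res$selected), "CpGs selected; achieved FSN", res$achieved_fsn,
    "; implied FDR", res$implied_fdr, "\n")
#> 154 CpGs selected; achieved FSN 0 ; implied FDR 0

pairs <- pair_correlations(match_pairs(rel, sim$expression),
                           rel, sim$expression)
str(sign_test(pairs))
#> List of 4
#>  $ n_varying        : int 280
#>  $ n_negative       : int 181
#>  $ fraction_negative: num 0.646
#>  $ p_value          : num 1.09e-06
```

The frequency table shows the planted ordering (lumB most methylated,
basal-like least, normal tissue low); the ANOVA run selects the
subtype-differential CpGs with an expected false-significant count of zero;
and the sign test confirms the planted inverse methylation–expression
coupling (181 of 280 varying pairs negative).

See `vignettes/methylation-subtype-analysis.Rmd` for the full account of
the model, parameter defaults, and design decisions.

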