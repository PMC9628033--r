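# methcormap

Cross-tissue DNA methylation correlation mapping in R.

## What this is for

Brain-focused epigenome-wide association studies (EWAS) usually cannot
sample the brain of living participants and assay a surrogate tissue
instead — most often blood, increasingly buccal swabs. Whether a CpG's
methylation in the surrogate tracks its methylation in the brain is a
per-CpG empirical question that can only be answered with paired samples
from the same individuals. methcormap implements, as a tested and reusable
pipeline, the analysis that produces such an answer: a genome-wide
brain–buccal DNAm correlation map with the quality control, confounder
adjustment, genetic (cis-mQTL) analysis and enrichment reporting around it.

For each CpG *j* with paired beta values across *n* individuals, the map
records the Spearman rank correlation
ρ<sub>j</sub> = cor(rank(x<sub>j</sub>), rank(y<sub>j</sub>)), a two-sided
p-value from the t approximation t = ρ√((n−2)/(1−ρ²)) on n−2 df, and a
Benjamini–Hochberg q-value over all tested probes; probes with q < 0.05
are called significantly correlated. Around this core the package
provides:

- **`synthetic data`** — `sim_config()`, `generate_paired_dataset()`: a
  paired-tissue simulator on the latent logit scale with planted
  cross-tissue correlations (calibrated through the Gaussian-copula
  closed form ρ_s = (6/π)·asin(r/2)), cell-mixture / batch / technical
  confounding, cis genetic effects with a planted enrichment among
  correlated CpGs, and a machine-readable truth table.
- **QC** — conversion-efficiency filtering, deterministic PC-based
  outlier scoring, probe blacklists, detection-p masking, NNLS
  cell-composition estimation, probe intersection.
- **Covariate model** — 100 kb bin subsampling, PCA (`prcomp`
  convention), PC retention, Pearson/ANOVA covariate screening at
  p < 0.01, effect-coded OLS removal (`residualize`,
  `combine_and_debatch`), and a direct 3-PC adjustment variant.
- **Correlation map** — `spearman_map()`, `bh_fdr()`,
  `summarize_correlations()`, per-batch replication cross-checks and the
  |ρ| > 0.5 variant.
- **cis-mQTL mapping** — `enumerate_cis_pairs()` (±1 Mb closed window),
  `fit_mqtls()` (additive linear model, FDR over all tests, matrix-eQTL
  style reporting), `mqtl_cpgs()`.
- **Enrichment & overlap** — `enrichment_chisq()`, `mqtl_enrichment()` on
  a bin-matched background, `region_enrichment()` over the eight
  gene-region categories with Pearson residuals, `overlap_report()` and
  `lookup_cpgs()` for set comparisons at printed precision.
- **IO / pipeline** — TSV/CSV/VCF readers and writers, YAML
  configuration, `run_pipeline()` and a thin CLI
  (`inst/scripts/methcormap.R`) with subcommands
  `simulate|qc|adjust|correlate|mqtl|enrich|report|run`.

## Worked example

```r
library(methcormap)

cfg <- sim_config(n_pairs = 120, n_cpgs = 5000, seed = 42)
sim <- generate_paired_dataset(cfg)
sim
#> paired_meth_sim: 5000 CpGs, 120 pairs (44+76), 150 planted correlated, 1552 mQTL CpGs

brain  <- cbind(sim$betas$brain_B1,  sim$betas$brain_B2)
buccal <- cbind(sim$betas$buccal_B1, sim$betas$buccal_B2)
map <- spearman_map(brain, buccal, annotation = sim$annotation)
summarize_correlations(map)
#> correlation map: 5000 tested, 1169 significant (q < 0.05; 23.38%)
#>   positive 1150 (98.37% -> 98%), negative 19 (1.63% -> 2%); |rho| > 0.5: 123

head(map[map$significant, c("cpg_id", "chrom", "pos", "n", "rho", "p", "q")], 3)
#>       cpg_id chrom    pos   n       rho            p            q
#> 1  cg0000001  chr1  35822 120 0.6516355 7.642500e-16 5.970703e-14
#> 11 cg0000011  chr1 253863 120 0.2657476 3.350675e-03 1.811176e-02
#> 16 cg0000016  chr1 398088 120 0.4179804 2.032787e-06 4.381005e-05
```

The 5,000 tested CpGs here are unadjusted simulator output: the 150
planted correlations are joined by CpGs correlated through shared cell
composition, batch structure and shared genetic effects — which is why
the covariate screening/removal stages exist. `run_pipeline()` chains
them end to end and writes every artifact (QC reports, screen tables,
adjusted matrices, the correlation map TSV, mQTL records, enrichment
results, a resolved-config snapshot) to an output directory:

```r
st <- run_pipeline(pipeline_config(seed = 42), out_dir = "out")
```

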