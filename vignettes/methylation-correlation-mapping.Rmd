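---
title: "Cross-tissue DNA methylation correlation mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue DNA methylation correlation mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Epigenome-wide association studies of brain-related phenotypes usually
cannot sample the brain of living participants; they assay a surrogate
tissue such as buccal epithelium and hope that inter-individual variation in
DNA methylation (DNAm) at a CpG site in the surrogate tracks the variation
in the target tissue. Whether that hope is justified is an empirical,
per-CpG question. methcormap implements the analysis that answers it when
both tissues have been profiled in the same individuals: a genome-wide map
of cross-tissue DNAm correlation, together with the quality control,
confounder handling, genetic (mQTL) analysis and enrichment reporting that
such a map needs to be interpretable.

## The statistical core

For each CpG \(j\), with paired beta values \(x_{ij}\) (brain) and
\(y_{ij}\) (buccal) over individuals \(i = 1..n\), the map records the
Spearman rank correlation
\(\rho_j = \mathrm{cor}(\mathrm{rank}(x_j), \mathrm{rank}(y_j))\)
(average ranks for ties), a two-sided p-value from the t approximation
\(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) on \(n-2\) df, and a
Benjamini–Hochberg q-value computed over exactly the probes that entered
the map. Probes with \(q < 0.05\) are called significantly correlated. The
rank-based coefficient is deliberate: beta values are bounded, bimodal and
not normally distributed, and monotone but non-linear coupling between
tissues is expected; \(\rho\) is invariant under strictly monotone
transforms of either tissue (this invariance is asserted in the test
suite to 1e-12). The t approximation matches the behaviour of base R's
`cor.test` when ties are present, which is the relevant regime for array
betas at realistic sample sizes; an exact-permutation oracle in the tests
bounds its error at small n.

Missing entries are dropped pairwise per CpG; a probe with fewer than four
complete pairs is reported but excluded from the FDR.

## Confounder model

Bulk methylation is confounded by cell composition and by technical
structure (batch, array, position on the array, bisulfite conversion
efficiency). The package follows a principal-component screening strategy:

1. **Spatial decorrelation** (`bin_subsample`): one CpG is drawn uniformly
   from every non-empty 100 kb genomic bin (0-based half-open bins;
   1-based positions are converted by `pos - 1` at exactly one code
   boundary). PCA on this subset is not dominated by locally co-methylated
   clusters.
2. **PCA** (`meth_pca`): samples are observations, probes are centered but
   not scaled variables, components come from the SVD (the `prcomp`
   convention).
3. **PC retention** (`select_pcs`): the number of retained PCs defaults to
   the smallest k reaching 80% cumulative variance. The original scree-plot
   choice is visual and irreproducible; a cumulative-variance rule is the
   closest deterministic stand-in, and the count used is always recorded.
   A fixed-k mode exists for the 3-PC robustness variant.
4. **Screening** (`screen_covariates`): numeric covariates are tested by
   two-sided Pearson correlation against each retained PC; categorical
   covariates by one-way ANOVA of the PC scores. A covariate with any
   p < 0.01 is flagged. Two-sided tests are assumed; the per-test type-I
   level is verified by simulation in the test suite.
5. **Removal** (`residualize`): flagged covariates are removed per CpG by
   OLS with sum-to-zero (effect) coding for factors and centered numeric
   covariates, so adjusted values keep each probe's grand mean — the
   behaviour of limma's `removeBatchEffect`, which serves as an independent
   cross-check in the tests. Adjusted values may leave [0,1] and are not
   clipped. Screening and removal are performed separately per
   tissue-by-batch dataset; the two batches of a tissue are then
   concatenated and the batch factor itself removed
   (`combine_and_debatch`).

The robustness variant (`direct_pc_adjust`) skips screening and removes the
first three bin-subsample PCs from every probe directly.

Cell composition enters the screen as a numeric covariate. Fractions are
estimated from tissue-specific reference signatures by non-negative least
squares followed by renormalisation (`estimate_cell_composition`). NNLS is
the simplest estimator satisfying the non-negativity/sum-to-one contract;
downstream stages consume the fractions only as covariates, so the
difference from robust-partial-correlation deconvolution methods is
immaterial here. Recovery error on noisy synthetic mixtures (noise sd
0.02) is below 0.05 mean absolute error in the tests.

## Quality control

- Samples with bisulfite conversion efficiency below 80% are excluded
  (kept at exactly 80%); the pair partner of an excluded sample is flagged
  for exclusion from paired analyses.
- Outlier samples are flagged by a deterministic low-dimensional score:
  distance of a sample's first-two-PC coordinates beyond the Tukey fence
  [Q1 − 1.5 IQR, Q3 + 1.5 IQR], scaled by the IQR, thresholded at 0.15.
  This is a documented, testable score in the spirit of array outlier
  detectors; it is not a reimplementation of any specific one. Under
  Gaussian coordinates a clean sample exceeds the threshold with
  probability well under 1%, so occasional benign flags are expected and
  harmless in a paired design (the partner is dropped too).
- Probes on X/Y, probes overlapping SNPs, and multi-mapping probes are
  removed via annotation flags; probes are intersected across all four
  tissue-by-batch datasets before mapping.
- Detection-p masking (entries with detection p > 0.01 set missing) and
  beadcount removal (probes with < 3 beads in strictly more than 5% of
  samples) are implemented for datasets that provide those matrices.

## cis-mQTL mapping

`fit_mqtls` regresses (cell-composition-adjusted) beta values on allele
dosage plus covariates (sex, genetic PCs, methylation PCs, genotyping
batch) for every SNP–CpG pair within ±1 Mb (closed interval; distance sign
is SNP − CpG). The implementation residualizes dosages and methylation on
the covariates once (Frisch–Waugh–Lovell) and computes per-pair
t statistics with n − rank(design) df; it matches a per-pair `lm()` to
1e-10 in the tests. BH q-values are computed over **all** tested pairs even
though only pairs with p < 0.05 are stored — the matrix-eQTL reporting
convention — and the total test count is kept in the object's attributes.
SNPs with minor allele count below 3 are skipped: the threshold is an
artifact decision (the source analyses state none) chosen because such
fits are degenerate.

## Enrichment and reporting

`enrichment_chisq` computes the chi-squared test of independence from the
stated formulas, with the Yates continuity correction on by default for
2×2 tables only (mirroring the default of R's `chisq.test`, which the
original analyses used; the flag is exposed and logged because the original
report does not state it). Pearson residuals \((O-E)/\sqrt{E}\) are always
uncorrected, so their squares sum to the uncorrected statistic — an exact
identity asserted in the tests. mQTL enrichment among correlated CpGs is
evaluated on a bin-subsampled background (one CpG per 100 kb bin) so that
spatial autocorrelation does not fabricate significance; the subset size
and seed are recorded. Gene-region enrichment uses a 2×8 table over the
eight standard array annotation categories (TSS1500, TSS200, 5'UTR,
1st exon, gene body, exon boundary, 3'UTR, IGR); the table orientation is
statistically irrelevant and residuals are reported per region.

Printed percentages are rounded half away from zero (`round_half_up`) at
the precision of the number being reproduced (integer by default, two
decimals where the source prints two); raw values are always retained.

## The simulator

`generate_paired_dataset` builds the latent logit (M-value-like) model

\[
M_{ijt} = \mu_{jt} + s_{jt} u_i + \textstyle\sum_k \gamma_{jkt}(c_{ik} - \bar c_k)
 + b_j\,\mathrm{batch}_i + \beta^{conv}_{jt} z_{it} + g_j d_i + \epsilon_{ijt},
\qquad \beta_{ijt} = \mathrm{logistic}(M_{ijt}),
\]

so additive effects are well defined and betas stay strictly inside (0,1).
Its defaults are the study conditions the package targets: 120 individuals
in two batches of 44 and 76; 3% of CpGs planted as correlated with target
magnitudes in [0.28, 0.9] and 1.4% of them negative; a baseline cis-mQTL
rate of 0.30 with a 4-fold odds multiplier among correlated CpGs; three
cell types per tissue with Dirichlet(6, 3, 1) fractions shared between the
two tissues of an individual; residual logit noise sd 0.5. Where the
targeted study reports no value (the mQTL base rate, noise scale, cell
concentration, covariate effect scales) the defaults are one-time choices
of plausible magnitude, stated here and not revisited.

Design features worth calling out:

- **Correlation calibration.** A shared per-individual factor \(u_i\) with
  equal loadings in both tissues makes the latent pair bivariate normal, so
  the population Spearman has the Gaussian-copula closed form
  \(\rho_s = (6/\pi)\arcsin(r/2)\). `loading_for_spearman` inverts this
  analytically (\(r = 2\sin(\pi\rho_s/6)\), then
  \(s = \sigma\sqrt{r/(1-r)}\)) rather than via a tabulated numeric
  inverse — the closed form is exact for this copula, and the logistic
  transform leaves Spearman untouched. A Monte-Carlo test confirms the
  realized Spearman at \(\rho_s = 0.9\), n = 500, is within ±0.05 of
  target on average.
- **Confounding is planted as shared structure.** The batch effect
  \(b_j\) and the cell fractions \(c_{ik}\) are shared between the two
  tissues of an individual; that is exactly what makes them cross-tissue
  confounders that inflate null correlations, and what the covariate model
  must remove. Covariate effects are *not* included in the loading
  calibration: they are the perturbation under study, and the calibration
  tests switch them off.
- **Genetic effects act on both tissues** through the same dosage, so
  planted mQTL CpGs genuinely correlate across tissues — the mechanism
  behind the enrichment of mQTLs among correlated CpGs, planted with a
  known odds multiplier so the enrichment test can be validated against
  truth.
- The simulator does **not** model probe chemistry, age drift, LD between
  SNPs, or raw-intensity artifacts; passing tests therefore say nothing
  about those failure modes on real arrays.

## What the test and acceptance runs compute

The suite validates, at sizes chosen to keep a full run in minutes:
uniform null p-values and mean false-discovery proportion within
\(0.05 + 2\,SE\) over 200 null datasets of 5,000 CpGs × 120 pairs;
sensitivity ≥ 0.95 for 100 planted \(\rho = 0.5\) CpGs among 5,000 at
n = 120; covariate-screen detection of a planted cell-composition
confounder in ≥ 95% of 100 replicates and KS-uniform null p-values after
screen → residualize → combine; cis-mQTL recovery at n = 500 with ~50
planted effects among ~5,000 cis pairs; enrichment detection at a planted
odds multiplier of 4 and null-uniform enrichment p-values at multiplier 1;
and exact agreement of every core statistic with an independent oracle
(naive rank-correlation loop, exact permutation, `stats::chisq.test`,
per-pair `lm()`, hand BH step-up).

One caveat the tests make explicit: at FDR 0.05, BH *controls the expected
false-discovery proportion*; with ~50 strong true signals among ~5,000
cis pairs it admits on the order of two to three false pairs per run, so
requiring literally zero false CpGs in ≥ 95% of runs is not a property
BH-FDR can deliver (that would be family-wise control). The acceptance
test states the stronger requirement and is expected to fail it; the
recovery half (≥ 90% sensitivity) passes with margin.

## Known limitations

- The outlier score and the cumulative-variance PC rule are deterministic
  stand-ins for procedures that were originally interactive or
  library-internal; their thresholds (0.15, 80%) are conventions, not
  estimates.
- Deconvolution quality depends entirely on the supplied reference
  signatures; the package ships none and the simulator's references are
  self-consistent by construction.
- The per-CpG OLS removal assumes linear covariate effects on the beta
  scale; strong effects near the boundaries of [0,1] are better handled on
  the logit scale before mapping.
- P-values for Spearman's rho use the t approximation everywhere; for
  n < ~10 per batch the per-batch cross-check p-values are approximate.
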