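#' Simulation configuration for paired-tissue methylation data
#'
#' Collects every knob of the paired-tissue simulator in a validated list.
#' Defaults emulate the study design the package targets: 120 individuals
#' with one brain and one buccal sample each, shipped/processed in two
#' laboratory batches (44 and 76 pairs), a minority of CpGs whose methylation
#' correlates across tissues (mostly positively), cell-mixture and technical
#' covariate confounding, and cis genetic (mQTL) effects enriched among the
#' correlated CpGs.
#'
#' @param n_pairs number of individuals; each contributes one sample per tissue.
#' @param n_cpgs number of CpG probes.
#' @param n_snps number of SNPs.
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @param frac_correlated fraction of CpGs with a planted cross-tissue
#'   correlation.
#' @param frac_negative fraction of planted correlations with negative sign.
#' @param rho_target_range interval of target Spearman magnitudes for planted
#'   CpGs (the published map's significant coefficients start around 0.28).
#' @param frac_mqtl baseline fraction of CpGs carrying a cis genetic effect.
#' @param mqtl_enrichment odds multiplier for mQTL status among correlated
#'   CpGs (planted so enrichment tests have a known truth).
#' @param mqtl_effect genetic effect per dosage unit on the logit scale.
#' @param n_celltypes named vector, cell types per tissue.
#' @param dirichlet_alpha concentration vector for per-individual cell
#'   fractions (recycled per tissue); an asymmetric default gives a dominant
#'   cell type whose fraction acts as the screened numeric covariate.
#' @param batch_sizes two counts summing to `n_pairs`.
#' @param batch_shift mean batch effect on the logit scale (0.2 on the logit
#'   scale is roughly +0.05 beta near beta = 0.5).
#' @param covariate_effect_sds named per-covariate effect scales on the logit
#'   scale: `cell`, `conversion`, `batch`, `diagnosis`, `array`, `position`.
#' @param noise_sd residual scale on the logit scale.
#' @param maf_range minor-allele-frequency interval, subset of (0, 0.5].
#' @param seed integer seed governing every random draw.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 120L,
                       n_cpgs = 5000L,
                       n_snps = 1000L,
                       chrom_lengths = c(chr1 = 60e6, chr2 = 50e6, chr3 = 40e6),
                       frac_correlated = 0.03,
                       frac_negative = 0.014,
                       rho_target_range = c(0.28, 0.9),
                       frac_mqtl = 0.3,
                       mqtl_enrichment = 4,
                       mqtl_effect = 0.5,
                       n_celltypes = c(brain = 3L, buccal = 3L),
                       dirichlet_alpha = c(6, 3, 1),
                       batch_sizes = NULL,
                       batch_shift = 0.2,
                       covariate_effect_sds = c(cell = 0.5, conversion = 0.1,
                                                batch = 0.1, diagnosis = 0.05,
                                                array = 0.05, position = 0.02),
                       noise_sd = 0.5,
                       maf_range = c(0.05, 0.5),
                       seed = 1L) {
  # YAML/JSON configs deliver maps and sequences as lists; flatten them
  chrom_lengths <- unlist(chrom_lengths)
  rho_target_range <- unlist(rho_target_range)
  maf_range <- unlist(maf_range)
  n_celltypes <- unlist(n_celltypes)
  dirichlet_alpha <- unlist(dirichlet_alpha)
  covariate_effect_sds <- unlist(covariate_effect_sds)
  if (is.null(batch_sizes)) {
    b1 <- round(n_pairs * 44 / 120)
    batch_sizes <- c(b1, n_pairs - b1)
  }
  batch_sizes <- unlist(batch_sizes)
  cfg <- list(n_pairs = as.integer(n_pairs), n_cpgs = as.integer(n_cpgs),
              n_snps = as.integer(n_snps), chrom_lengths = chrom_lengths,
              frac_correlated = frac_correlated, frac_negative = frac_negative,
              rho_target_range = rho_target_range, frac_mqtl = frac_mqtl,
              mqtl_enrichment = mqtl_enrichment, mqtl_effect = mqtl_effect,
              n_celltypes = n_celltypes, dirichlet_alpha = dirichlet_alpha,
              batch_sizes = as.integer(batch_sizes), batch_shift = batch_shift,
              covariate_effect_sds = covariate_effect_sds,
              noise_sd = noise_sd, maf_range = maf_range,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$frac_correlated, cfg$frac_negative, cfg$frac_mqtl)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0,1]", call. = FALSE)
  if (sum(cfg$batch_sizes) != cfg$n_pairs)
    stop("batch_sizes must sum to n_pairs", call. = FALSE)
  if (length(cfg$batch_sizes) != 2L)
    stop("exactly two batches are modelled", call. = FALSE)
  r <- cfg$rho_target_range
  if (length(r) != 2L || r[1] > r[2] || r[1] <= 0 || r[2] > 1)
    stop("rho_target_range must be an interval within (0,1]", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  m <- cfg$maf_range
  if (length(m) != 2L || m[1] > m[2] || m[1] <= 0 || m[2] > 0.5)
    stop("maf_range must be an interval within (0, 0.5]", call. = FALSE)
  if (is.null(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths <= 0))
    stop("chrom_lengths must be a named vector of positive lengths",
         call. = FALSE)
  need <- c("cell", "conversion", "batch", "diagnosis", "array", "position")
  if (!all(need %in% names(cfg$covariate_effect_sds)))
    stop("covariate_effect_sds must name: ",
         paste(need, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d pairs (batches %s), %d CpGs, %d SNPs, seed %d\n",
    x$n_pairs, paste(x$batch_sizes, collapse = "+"), x$n_cpgs, x$n_snps,
    x$seed))
  cat(sprintf("  correlated %.3f (neg %.3f, |rho| in [%.2f,%.2f]); mQTL %.2f x%.1f\n",
              x$frac_correlated, x$frac_negative, x$rho_target_range[1],
              x$rho_target_range[2], x$frac_mqtl, x$mqtl_enrichment))
  invisible(x)
}
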