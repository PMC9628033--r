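REGION_CATEGORIES <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                       "ExonBnd", "3'UTR", "IGR")

#' Construct / validate a probe annotation table
#'
#' @param df data.frame with columns `cpg_id`, `chrom`, `pos` (1-based),
#'   `region` (one of the eight gene-region categories), and logical
#'   blacklist flags `flag_xy`, `flag_snp`, `flag_multimap`.
#' @return validated data.frame of class `probe_annotation`.
#' @export
probe_annotation <- function(df) {
  need <- c("cpg_id", "chrom", "pos", "region",
            "flag_xy", "flag_snp", "flag_multimap")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$cpg_id)) stop("duplicate cpg_id", call. = FALSE)
  if (anyDuplicated(df[c("chrom", "pos")]))
    stop("duplicate (chrom, pos) in annotation", call. = FALSE)
  if (nrow(df) && !all(df$region %in% REGION_CATEGORIES))
    stop("unknown region category", call. = FALSE)
  if (nrow(df) && any(df$pos < 1)) stop("positions must be 1-based >= 1",
                                        call. = FALSE)
  class(df) <- c("probe_annotation", "data.frame")
  df
}

#' Simulate probe annotation
#'
#' Draws CpG positions uniformly per chromosome (count proportional to
#' chromosome length), assigns each probe one of the eight gene-region
#' categories, and sets blacklist flags (X/Y, SNP-overlapping, multi-mapping)
#' by independent Bernoulli draws.
#'
#' @param config [sim_config()].
#' @param region_probs optional length-8 probability vector over
#'   `TSS1500, TSS200, 5'UTR, 1stExon, Body, ExonBnd, 3'UTR, IGR`; the default
#'   is a plausible array-like mix dominated by gene body and IGR.
#' @param flag_probs named vector of blacklist-flag probabilities
#'   (`xy`, `snp`, `multimap`); default 0 so downstream counts are exact.
#' @return `probe_annotation` data.frame sorted by (chrom, pos).
#' @export
generate_probe_annotation <- function(config, region_probs = NULL,
                                      flag_probs = c(xy = 0, snp = 0,
                                                     multimap = 0)) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(region_probs))
    region_probs <- c(0.13, 0.08, 0.09, 0.03, 0.30, 0.005, 0.025, 0.34)
  stopifnot(length(region_probs) == 8L, abs(sum(region_probs) - 1) < 1e-8)
  n <- config$n_cpgs
  if (n == 0L)
    return(probe_annotation(data.frame(
      cpg_id = character(), chrom = character(), pos = integer(),
      region = character(), flag_xy = logical(), flag_snp = logical(),
      flag_multimap = logical(), stringsAsFactors = FALSE)))
  if (n > sum(config$chrom_lengths))
    stop("n_cpgs exceeds total assignable positions", call. = FALSE)
  with_seed(config$seed, {
    chroms <- sort(names(config$chrom_lengths))
    chr <- sample(chroms, n, replace = TRUE,
                  prob = config$chrom_lengths[chroms] / sum(config$chrom_lengths))
    pos <- integer(n)
    for (c0 in chroms) {
      idx <- which(chr == c0)
      len <- config$chrom_lengths[[c0]]
      if (length(idx) > len)
        stop("n_cpgs exceeds assignable positions on ", c0, call. = FALSE)
      # sample without replacement so (chrom, pos) never duplicates
      pos[idx] <- if (len <= 1e7) sample.int(len, length(idx))
                  else sample_int_norep(len, length(idx))
    }
    region <- sample(REGION_CATEGORIES, n, replace = TRUE, prob = region_probs)
    ord <- order(chr, pos)
    df <- data.frame(
      cpg_id = sprintf("cg%07d", seq_len(n)),
      chrom = chr[ord], pos = pos[ord], region = region[ord],
      flag_xy = runif(n) < flag_probs[["xy"]],
      flag_snp = runif(n) < flag_probs[["snp"]],
      flag_multimap = runif(n) < flag_probs[["multimap"]],
      stringsAsFactors = FALSE)
    probe_annotation(df)
  })
}

# Uniform draw of k distinct integers in 1..n for large n without allocating n.
sample_int_norep <- function(n, k) {
  out <- unique(ceiling(runif(k * 1.2 + 10) * n))
  while (length(out) < k)
    out <- unique(c(out, ceiling(runif(k) * n)))
  out[seq_len(k)]
}

#' Simulate SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Allele frequencies are uniform on `maf_range`; dosages are
#' Binomial(2, freq) per individual.
#'
#' @param config [sim_config()].
#' @return object of class `genotype_matrix`: list with `info`
#'   (snp_id, chrom, pos, freq) and `dosage` (SNPs x individuals, values
#'   in 0/1/2, columns named by individual id).
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    n <- config$n_snps
    chroms <- sort(names(config$chrom_lengths))
    chr <- sample(chroms, n, replace = TRUE,
                  prob = config$chrom_lengths[chroms] / sum(config$chrom_lengths))
    pos <- integer(n)
    for (c0 in chroms) {
      idx <- which(chr == c0)
      pos[idx] <- sample.int(config$chrom_lengths[[c0]], length(idx))
    }
    freq <- runif(n, config$maf_range[1], config$maf_range[2])
    ids <- individual_ids(config$n_pairs)
    dose <- matrix(rbinom(n * config$n_pairs, 2L, rep(freq, config$n_pairs)),
                   nrow = n, ncol = config$n_pairs,
                   dimnames = list(sprintf("snp%06d", seq_len(n)), ids))
    ord <- order(chr, pos)
    genotype_matrix(
      info = data.frame(snp_id = rownames(dose), chrom = chr, pos = pos,
                        freq = freq, stringsAsFactors = FALSE)[ord, ],
      dosage = dose[ord, , drop = FALSE])
  })
}

#' @rdname generate_genotypes
#' @param info SNP info data.frame (snp_id, chrom, pos, freq).
#' @param dosage integer matrix SNPs x samples with values in \{0,1,2\}.
#' @export
genotype_matrix <- function(info, dosage) {
  stopifnot(is.data.frame(info), all(c("snp_id", "chrom", "pos") %in% names(info)),
            nrow(info) == nrow(dosage))
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  rownames(dosage) <- info$snp_id
  rownames(info) <- NULL
  structure(list(info = info, dosage = dosage), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d samples\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

individual_ids <- function(n) sprintf("ind%04d", seq_len(n))

#' Shared-factor loading that yields a target Spearman correlation
#'
#' For two latent logit variables \eqn{M_t = s_t u + e_t} with a shared
#' standard normal factor \eqn{u} and independent Gaussian noise of scale
#' `noise_sd`, the pair is bivariate normal with Pearson correlation
#' \eqn{\rho = s_1 s_2 / \sqrt{(s_1^2+\sigma^2)(s_2^2+\sigma^2)}}, and its
#' Spearman correlation is the Gaussian-copula closed form
#' \eqn{\rho_s = (6/\pi) \arcsin(\rho/2)}. Because the logistic transform to
#' the beta scale is strictly monotone, the beta-scale Spearman equals the
#' latent one. This function inverts the two relations: given a target
#' Spearman magnitude it returns the equal loading
#' \eqn{s = \sigma \sqrt{\rho/(1-\rho)}} with \eqn{\rho = 2\sin(\pi\rho_s/6)}.
#'
#' @param rho_s target Spearman magnitude in (0, 1).
#' @param noise_sd independent noise scale.
#' @return positive loading `s`.
#' @export
loading_for_spearman <- function(rho_s, noise_sd) {
  stopifnot(all(rho_s > 0), all(rho_s < 1), noise_sd > 0)
  r <- pmin(2 * sin(pi * rho_s / 6), 1 - 1e-9)
  noise_sd * sqrt(r / (1 - r))
}

#' @rdname loading_for_spearman
#' @param s loading(s).
#' @return the population Spearman implied by equal loadings `s`.
#' @export
spearman_for_loading <- function(s, noise_sd) {
  r <- s^2 / (s^2 + noise_sd^2)
  (6 / pi) * asin(r / 2)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

#' Simulate a paired-tissue methylation dataset with known truth
#'
#' Generates beta matrices for two tissues x two batches of paired samples on
#' a latent logit (M-value-like) scale:
#' \deqn{M_{ijt} = \mu_{jt} + s_{jt} u_i + \sum_k \gamma_{jkt}(c_{ik} - \bar c_k)
#'   + b_j \mathrm{batch}_i + \beta_{jt}^{(conv)} z_i + g_j d_i + \epsilon_{ijt}}
#' where `u_i` is a shared per-individual factor driving planted cross-tissue
#' correlation (loadings calibrated by [loading_for_spearman()]; opposite
#' signs for negative targets; zero for non-planted CpGs), `c_ik` are
#' Dirichlet cell-type fractions mixing tissue-specific reference signatures,
#' `b_j` is a batch effect shared between tissues, `d_i` a SNP dosage acting
#' on both tissues at planted mQTL CpGs, and categorical effects for
#' diagnosis, array id and array position are added analogously. Betas are
#' `plogis(M)`, hence strictly inside (0,1).
#'
#' @param config [sim_config()].
#' @param annotation optional [probe_annotation()]; generated from `config`
#'   when `NULL`.
#' @param genotypes optional [genotype_matrix()]; generated when `NULL`.
#' @return list of class `paired_meth_sim` with elements `betas` (named list
#'   of four CpG x sample matrices: `brain_B1`, `brain_B2`, `buccal_B1`,
#'   `buccal_B2`), `sheet` (sample sheet), `truth` (truth table),
#'   `cell_reference` (per-tissue signature matrices, beta scale),
#'   `cell_fractions` (per-tissue true fractions), `annotation`, `genotypes`,
#'   `config`.
#' @export
generate_paired_dataset <- function(config, annotation = NULL,
                                    genotypes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(annotation)) annotation <- generate_probe_annotation(config)
  if (is.null(genotypes)) genotypes <- generate_genotypes(config)
  if (nrow(annotation) != config$n_cpgs)
    stop("annotation inconsistent with config (n_cpgs)", call. = FALSE)
  n <- config$n_pairs
  J <- config$n_cpgs
  if (ncol(genotypes$dosage) != n)
    stop("genotypes inconsistent with config (n_pairs)", call. = FALSE)
  ids <- individual_ids(n)
  tissues <- c("brain", "buccal")
  sds <- config$covariate_effect_sds

  with_seed(config$seed + 2L, {
    batch <- rep(c("B1", "B2"), times = config$batch_sizes)
    batch_ind <- as.numeric(batch == "B2")
    diagnosis <- sample(c("AD", "PD", "CTRL"), n, replace = TRUE,
                        prob = c(0.45, 0.2, 0.35))
    sex <- sample(c("F", "M"), n, replace = TRUE)

    # baseline: bimodal across CpGs (mostly clearly methylated/unmethylated)
    comp <- sample(1:3, J, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    mu0 <- rnorm(J, mean = c(-3, 3, 0)[comp], sd = 1)
    mu <- list(brain = mu0 + rnorm(J, 0, 0.5),
               buccal = mu0 + rnorm(J, 0, 0.5))

    # planted cross-tissue correlation
    n_corr <- round(config$frac_correlated * J)
    corr_idx <- if (n_corr > 0) sort(sample.int(J, n_corr)) else integer()
    rho_mag <- runif(n_corr, config$rho_target_range[1],
                     pmin(config$rho_target_range[2], 0.99))
    rho_sign <- ifelse(runif(n_corr) < config$frac_negative, -1, 1)
    s_brain <- s_buccal <- numeric(J)
    if (n_corr > 0) {
      s <- loading_for_spearman(rho_mag, config$noise_sd)
      s_brain[corr_idx] <- s
      s_buccal[corr_idx] <- s * rho_sign
    }
    u <- rnorm(n)

    # mQTL status: baseline odds multiplied for correlated CpGs
    p0 <- config$frac_mqtl
    p1 <- if (p0 > 0 && p0 < 1) {
      odds <- config$mqtl_enrichment * p0 / (1 - p0)
      odds / (1 + odds)
    } else p0
    pm <- rep(p0, J); pm[corr_idx] <- p1
    is_mqtl_cpg <- runif(J) < pm
    mqtl_snp <- rep(NA_character_, J)
    mqtl_beta <- numeric(J)
    gi <- genotypes$info
    for (j in which(is_mqtl_cpg)) {
      same <- which(gi$chrom == annotation$chrom[j] &
                    abs(gi$pos - annotation$pos[j]) <= 1e6)
      if (!length(same)) { is_mqtl_cpg[j] <- FALSE; next }
      k <- same[which.min(abs(gi$pos[same] - annotation$pos[j]))]
      mqtl_snp[j] <- gi$snp_id[k]
      mqtl_beta[j] <- sample(c(-1, 1), 1) * config$mqtl_effect
    }
    g_dose <- matrix(0, J, n)
    has_q <- which(!is.na(mqtl_snp))
    if (length(has_q))
      g_dose[has_q, ] <- mqtl_beta[has_q] *
        genotypes$dosage[mqtl_snp[has_q], ids, drop = FALSE]

    # shared cell fractions (one draw per individual, used in both tissues
    # when the tissues have the same number of cell types)
    same_k <- length(unique(config$n_celltypes)) == 1L
    frac_shared <- if (same_k)
      rdirichlet(n, rep_len(config$dirichlet_alpha, config$n_celltypes[[1]]))
    else NULL

    conv <- pmin(99.9, pmax(60, 100 - rgamma(2L * n, shape = 2, scale = 2)))
    names(conv) <- paste(rep(ids, 2), rep(tissues, each = n), sep = "_")

    # batch effect shared between tissues: that is what makes an uncorrected
    # batch a cross-tissue confounder
    b_shared <- rnorm(J, config$batch_shift, sds[["batch"]])

    # two extraction days per batch, assigned at random so the factor is not
    # collinear with array position
    ext_day <- sample(c("01", "15"), n, replace = TRUE)

    betas <- list(); sheets <- list()
    cell_ref <- list(); cell_frac <- list()
    for (t in tissues) {
      K <- config$n_celltypes[[t]]
      alpha <- rep_len(config$dirichlet_alpha, K)
      Cf <- if (same_k) frac_shared else rdirichlet(n, alpha)
      colnames(Cf) <- paste0(t, "_ct", seq_len(K))
      rownames(Cf) <- ids
      delta <- matrix(rnorm(J * K, 0, sds[["cell"]]), J, K)
      mean_frac <- alpha / sum(alpha)
      cell_contrib <- delta %*% (t(Cf) - mean_frac)

      sample_id <- paste(ids, t, sep = "_")
      conv_t <- conv[sample_id]
      zc <- if (sd(conv_t) > 0) as.numeric(scale(conv_t)) else rep(0, n)
      slope_conv <- rnorm(J, 0, sds[["conversion"]])

      # categorical technical effects (per tissue)
      array_id <- paste0(t, "_", batch, "_A",
                         stats::ave(seq_len(n), batch,
                                    FUN = function(i) ceiling(seq_along(i) / 8)))
      position <- sprintf("R%02dC01",
                          stats::ave(seq_len(n), array_id,
                                     FUN = function(i) seq_along(i)))
      eff_cat <- function(lv_vec, sd_eff) {
        lv <- unique(lv_vec)
        if (sd_eff <= 0 || length(lv) < 2) return(matrix(0, J, n))
        E <- matrix(rnorm(J * length(lv), 0, sd_eff), J, length(lv))
        E <- E - rowMeans(E)
        E[, match(lv_vec, lv), drop = FALSE]
      }
      M <- mu[[t]] +
        outer(if (t == "brain") s_brain else s_buccal, u) +
        cell_contrib +
        outer(b_shared, batch_ind) +
        outer(slope_conv, zc) +
        eff_cat(diagnosis, sds[["diagnosis"]]) +
        eff_cat(array_id, sds[["array"]]) +
        eff_cat(position, sds[["position"]]) +
        g_dose +
        matrix(rnorm(J * n, 0, config$noise_sd), J, n)
      B <- stats::plogis(clamp_logit(M))
      dimnames(B) <- list(annotation$cpg_id, sample_id)
      for (b in c("B1", "B2"))
        betas[[paste(t, b, sep = "_")]] <- B[, batch == b, drop = FALSE]

      ref <- stats::plogis(clamp_logit(mu[[t]] + delta))
      dimnames(ref) <- list(annotation$cpg_id, colnames(Cf))
      cell_ref[[t]] <- ref
      cell_frac[[t]] <- Cf
      sheets[[t]] <- data.frame(
        sample_id = sample_id, individual_id = ids, tissue = t, batch = batch,
        diagnosis = diagnosis, conversion_efficiency = as.numeric(conv_t),
        array_id = array_id, array_position = position,
        extraction_date = paste0("2019-0", ifelse(batch == "B1", 3, 9), "-",
                                 ext_day),
        sex = sex, genotyping_batch = batch, stringsAsFactors = FALSE)
    }
    truth <- data.frame(
      cpg_id = annotation$cpg_id,
      is_correlated = seq_len(J) %in% corr_idx,
      rho_target = { r <- numeric(J); r[corr_idx] <- rho_mag * rho_sign; r },
      mqtl_snp = mqtl_snp, mqtl_beta = mqtl_beta,
      region = annotation$region, stringsAsFactors = FALSE)
    structure(list(betas = betas, sheet = do.call(rbind, unname(sheets)),
                   truth = truth, cell_reference = cell_ref,
                   cell_fractions = cell_frac, annotation = annotation,
                   genotypes = genotypes, config = config),
              class = "paired_meth_sim")
  })
}

#' @export
print.paired_meth_sim <- function(x, ...) {
  cat(sprintf("paired_meth_sim: %d CpGs, %d pairs (%s), %d planted correlated, %d mQTL CpGs\n",
              x$config$n_cpgs, x$config$n_pairs,
              paste(x$config$batch_sizes, collapse = "+"),
              sum(x$truth$is_correlated), sum(!is.na(x$truth$mqtl_snp))))
  invisible(x)
}
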