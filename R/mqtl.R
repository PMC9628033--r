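#' Enumerate cis SNP-CpG pairs
#'
#' All (SNP, CpG) pairs on the same chromosome with
#' `|pos_snp - pos_cpg| <= window` (closed interval). Distance is signed
#' `pos_snp - pos_cpg`.
#'
#' @param annotation [probe_annotation()].
#' @param genotypes [genotype_matrix()].
#' @param window cis window in bp (default 1 Mb).
#' @return data.frame: snp_id, cpg_id, distance.
#' @export
enumerate_cis_pairs <- function(annotation, genotypes, window = 1e6) {
  stopifnot(is.data.frame(annotation), inherits(genotypes, "genotype_matrix"))
  gi <- genotypes$info
  out <- list()
  for (chrom in intersect(unique(annotation$chrom), unique(gi$chrom))) {
    cp <- annotation[annotation$chrom == chrom, c("cpg_id", "pos")]
    sp <- gi[gi$chrom == chrom, c("snp_id", "pos")]
    sp <- sp[order(sp$pos), ]
    lo <- findInterval(cp$pos - window - 1L, sp$pos) + 1L
    hi <- findInterval(cp$pos + window, sp$pos)
    keep <- hi >= lo
    if (!any(keep)) next
    idx <- which(keep)
    reps <- hi[idx] - lo[idx] + 1L
    snp_rows <- sequence(reps) + rep(lo[idx], reps) - 1L
    out[[chrom]] <- data.frame(
      snp_id = sp$snp_id[snp_rows],
      cpg_id = rep(cp$cpg_id[idx], reps),
      distance = sp$pos[snp_rows] - rep(cp$pos[idx], reps),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(snp_id = character(), cpg_id = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit cis-mQTL additive linear models
#'
#' Per SNP-CpG pair, an ordinary least squares fit of the (cell-composition
#' adjusted) beta value on an intercept, the allele dosage, and the supplied
#' covariates. The dosage t statistic uses `n - rank(design)` degrees of
#' freedom. Benjamini-Hochberg q-values are computed over all tested pairs;
#' only pairs with `p < report_p` are returned (the total test count is kept
#' in the attributes, matrix-eQTL style). SNPs with minor allele count below
#' `min_mac` in the analysed samples are skipped and counted.
#'
#' @param betas CpG x sample matrix.
#' @param genotypes [genotype_matrix()]; dosage columns are matched to beta
#'   columns by name, or via `sample_map`.
#' @param pairs data.frame from [enumerate_cis_pairs()].
#' @param covariates optional data.frame aligned to the beta columns (sex,
#'   genetic PCs, methylation PCs, genotyping batch, ...).
#' @param report_p store only pairs with p below this (default 0.05).
#' @param min_mac minimum minor allele count (default 3).
#' @param sample_map optional named vector mapping beta column names to
#'   genotype column names.
#' @return data.frame of class `mqtl_records`: snp_id, cpg_id, distance,
#'   beta_hat, t_stat, p, q. Attributes: `n_tests`, `n_skipped_snps`.
#' @export
fit_mqtls <- function(betas, genotypes, pairs, covariates = NULL,
                      report_p = 0.05, min_mac = 3L, sample_map = NULL) {
  stopifnot(is.matrix(betas), inherits(genotypes, "genotype_matrix"),
            is.data.frame(pairs))
  geno_cols <- if (is.null(sample_map)) colnames(betas)
               else unname(sample_map[colnames(betas)])
  if (!all(geno_cols %in% colnames(genotypes$dosage)))
    stop("beta samples missing from genotype matrix", call. = FALSE)
  G <- genotypes$dosage[, geno_cols, drop = FALSE]
  n <- ncol(betas)

  D <- if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L)
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  else cbind(`(Intercept)` = 1, encode_nuisance(as.data.frame(covariates)))
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("rank-deficient covariate design", call. = FALSE)
  df <- n - qrD$rank - 1L
  if (df < 1) stop("not enough samples for the covariate design", call. = FALSE)

  pairs <- pairs[pairs$cpg_id %in% rownames(betas) &
                 pairs$snp_id %in% rownames(G), , drop = FALSE]
  # skip (near-)monomorphic SNPs: degenerate fits
  snps <- unique(pairs$snp_id)
  ac <- rowSums(G[snps, , drop = FALSE], na.rm = TRUE)
  mac <- pmin(ac, 2 * n - ac)
  poly <- snps[mac >= min_mac]
  n_skipped <- length(snps) - length(poly)
  pairs <- pairs[pairs$snp_id %in% poly, , drop = FALSE]

  if (nrow(pairs) == 0L) {
    res <- data.frame(snp_id = character(), cpg_id = character(),
                      distance = integer(), beta_hat = numeric(),
                      t_stat = numeric(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE)
    attr(res, "n_tests") <- 0L
    attr(res, "n_skipped_snps") <- n_skipped
    class(res) <- c("mqtl_records", "data.frame")
    return(res)
  }

  if (anyNA(G) || anyNA(betas)) {
    # pairwise-complete fallback: per-pair OLS on the complete samples
    np <- nrow(pairs)
    beta_hat <- t_stat <- p <- rep(NA_real_, np)
    for (k in seq_len(np)) {
      g <- G[pairs$snp_id[k], ]
      y <- betas[pairs$cpg_id[k], ]
      ok <- !is.na(g) & !is.na(y)
      Dk <- D[ok, , drop = FALSE]
      fit_qr <- qr(cbind(Dk, dose = g[ok]))
      dfk <- sum(ok) - fit_qr$rank
      if (dfk < 1 || fit_qr$rank < ncol(Dk) + 1L) next
      cf <- qr.coef(fit_qr, y[ok])
      res <- qr.resid(fit_qr, y[ok])
      gt <- qr.resid(qr(Dk), g[ok])
      se <- sqrt(sum(res^2) / dfk / sum(gt^2))
      beta_hat[k] <- cf["dose"]
      t_stat[k] <- cf["dose"] / se
      p[k] <- 2 * stats::pt(-abs(t_stat[k]), df = dfk)
    }
    q <- bh_fdr(p)
    keep <- !is.na(p) & p < report_p
    res <- data.frame(snp_id = pairs$snp_id, cpg_id = pairs$cpg_id,
                      distance = pairs$distance, beta_hat = beta_hat,
                      t_stat = t_stat, p = p, q = q,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "n_tests") <- sum(!is.na(p))
    attr(res, "n_skipped_snps") <- n_skipped
    class(res) <- c("mqtl_records", "data.frame")
    return(res)
  }

  # Frisch-Waugh-Lovell: residualize dosage and methylation on the
  # covariates once, then per-pair simple regressions on the residuals.
  Gt <- qr.resid(qrD, t(G[poly, , drop = FALSE]))       # n x S
  cpgs <- unique(pairs$cpg_id)
  Yt <- qr.resid(qrD, t(betas[cpgs, , drop = FALSE]))   # n x C
  gss <- colSums(Gt^2)
  yss <- colSums(Yt^2)

  si <- match(pairs$snp_id, poly)
  ci <- match(pairs$cpg_id, cpgs)
  npairs <- nrow(pairs)
  beta_hat <- t_stat <- numeric(npairs)
  chunk <- 200000L
  for (start in seq(1L, npairs, by = chunk)) {
    k <- start:min(start + chunk - 1L, npairs)
    cross <- colSums(Gt[, si[k], drop = FALSE] * Yt[, ci[k], drop = FALSE])
    g2 <- gss[si[k]]
    b <- cross / g2
    rss <- pmax(yss[ci[k]] - cross^2 / g2, 0)
    se <- sqrt(rss / df / g2)
    beta_hat[k] <- b
    t_stat[k] <- ifelse(se > 0, b / se, sign(b) * Inf)
  }
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  q <- bh_fdr(p)
  keep <- p < report_p
  res <- data.frame(snp_id = pairs$snp_id, cpg_id = pairs$cpg_id,
                    distance = pairs$distance, beta_hat = beta_hat,
                    t_stat = t_stat, p = p, q = q,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tests") <- npairs
  attr(res, "n_skipped_snps") <- n_skipped
  attr(res, "df") <- df
  class(res) <- c("mqtl_records", "data.frame")
  res
}

#' CpGs under significant genetic control
#'
#' @param records [fit_mqtls()] output.
#' @param q_thresh FDR threshold.
#' @return character vector of CpG ids with at least one cis-mQTL at
#'   `q < q_thresh`.
#' @export
mqtl_cpgs <- function(records, q_thresh = 0.05) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) return(character())
  sort(unique(records$cpg_id[!is.na(records$q) & records$q < q_thresh]))
}
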