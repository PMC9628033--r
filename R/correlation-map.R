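rank_rows <- function(X) t(apply(X, 1, rank, ties.method = "average"))

spearman_p <- function(rho, n) {
  # two-sided p from the t approximation, n-2 df
  ifelse(is.na(rho) | n < 4, NA_real_, {
    r2 <- pmin(rho^2, 1 - 1e-15)
    tt <- abs(rho) * sqrt((n - 2) / (1 - r2))
    2 * stats::pt(-tt, df = n - 2)
  })
}

#' Genome-wide cross-tissue Spearman correlation map
#'
#' For every CpG, computes the Spearman rank correlation of beta values
#' between the two tissues across paired individuals (average ranks for
#' ties; two-sided p from the t approximation with n-2 df, the behaviour of
#' `cor.test` in the presence of ties), applies Benjamini-Hochberg FDR over
#' all testable probes, and calls significance at `q < q_thresh`.
#'
#' Missing values are dropped pairwise per CpG; probes with fewer than 4
#' complete pairs get `NA` p/q and are excluded from the FDR.
#'
#' @param brain,buccal CpG x sample matrices over the same probe set.
#' @param pairing optional data.frame with columns `individual_id`,
#'   `brain_sample`, `buccal_sample`; when `NULL`, columns are paired by
#'   shared individual prefix `"<individual>_<tissue>"` or identical column
#'   names.
#' @param annotation optional [probe_annotation()] contributing chrom/pos.
#' @param q_thresh FDR threshold for the significance call.
#' @return data.frame of class `correlation_map`: cpg_id, chrom, pos, n,
#'   rho, p, q, significant; sorted by (chrom, pos) when annotated.
#' @export
spearman_map <- function(brain, buccal, pairing = NULL, annotation = NULL,
                         q_thresh = 0.05) {
  stopifnot(is.matrix(brain), is.matrix(buccal))
  if (!identical(rownames(brain), rownames(buccal)))
    stop("probe sets must be identical (run intersect_probes first)",
         call. = FALSE)
  if (is.null(pairing)) {
    if (identical(colnames(brain), colnames(buccal))) {
      pairing <- data.frame(individual_id = colnames(brain),
                            brain_sample = colnames(brain),
                            buccal_sample = colnames(buccal))
    } else {
      ind_b <- sub("_[^_]+$", "", colnames(brain))
      ind_c <- sub("_[^_]+$", "", colnames(buccal))
      common <- intersect(ind_b, ind_c)
      if (!setequal(ind_b, ind_c) || anyDuplicated(ind_b) ||
          anyDuplicated(ind_c))
        stop("unpaired sample(s): every individual needs exactly one sample per tissue",
             call. = FALSE)
      pairing <- data.frame(
        individual_id = common,
        brain_sample = colnames(brain)[match(common, ind_b)],
        buccal_sample = colnames(buccal)[match(common, ind_c)])
    }
  }
  if (anyDuplicated(pairing$individual_id))
    stop("unpaired sample(s): duplicated individual in pairing", call. = FALSE)
  X <- brain[, pairing$brain_sample, drop = FALSE]
  Y <- buccal[, pairing$buccal_sample, drop = FALSE]
  n_pairs <- ncol(X)

  has_na <- anyNA(X) || anyNA(Y)
  rho <- n_used <- rep(NA_real_, nrow(X))
  if (!has_na) {
    RX <- rank_rows(X); RY <- rank_rows(Y)
    cx <- RX - rowMeans(RX); cy <- RY - rowMeans(RY)
    denom <- sqrt(rowSums(cx^2) * rowSums(cy^2))
    rho <- ifelse(denom > 0, rowSums(cx * cy) / denom, NA_real_)
    n_used <- rep(n_pairs, nrow(X))
  } else {
    for (j in seq_len(nrow(X))) {
      ok <- !is.na(X[j, ]) & !is.na(Y[j, ])
      n_used[j] <- sum(ok)
      if (n_used[j] >= 4) {
        rx <- rank(X[j, ok]); ry <- rank(Y[j, ok])
        sx <- sd(rx); sy <- sd(ry)
        rho[j] <- if (sx > 0 && sy > 0) stats::cor(rx, ry) else NA_real_
      }
    }
  }
  p <- spearman_p(rho, n_used)
  q <- bh_fdr(p)
  out <- data.frame(cpg_id = rownames(X), chrom = NA_character_,
                    pos = NA_integer_, n = as.integer(n_used), rho = rho,
                    p = p, q = q,
                    significant = !is.na(q) & q < q_thresh,
                    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    m <- match(out$cpg_id, annotation$cpg_id)
    out$chrom <- annotation$chrom[m]
    out$pos <- annotation$pos[m]
    out <- out[order(out$chrom, out$pos), ]
    rownames(out) <- NULL
  }
  class(out) <- c("correlation_map", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`q_(i) = min_(j>=i) p_(j) * m / j`, capped at
#' 1), returned in input order. `NA` p-values stay `NA` and do not count
#' towards `m`.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Summarise a correlation map
#'
#' Counts tested and significant probes, splits significant probes by sign,
#' and reports percentages both raw and rounded half-up to the integer, plus
#' the count of significant probes with `|rho|` above `rho_thresh`.
#'
#' @param records [spearman_map()] output (or any data.frame with rho/q).
#' @param q_thresh significance threshold on q.
#' @param rho_thresh magnitude threshold for the strong-correlation variant.
#' @return list of class `correlation_summary`.
#' @export
summarize_correlations <- function(records, q_thresh = 0.05,
                                   rho_thresh = 0.5) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  tested <- !is.na(records$q)
  sig <- tested & records$q < q_thresh
  n_sig <- sum(sig)
  n_pos <- sum(sig & records$rho > 0)
  n_neg <- sum(sig & records$rho < 0)
  pct <- function(k) if (n_sig == 0) NA_real_ else 100 * k / n_sig
  structure(list(
    n_tested = sum(tested), n_significant = n_sig,
    n_positive = n_pos, n_negative = n_neg,
    pct_positive = pct(n_pos), pct_negative = pct(n_neg),
    pct_positive_rounded = round_half_up(pct(n_pos)),
    pct_negative_rounded = round_half_up(pct(n_neg)),
    pct_significant = 100 * n_sig / max(sum(tested), 1),
    n_abs_rho_above_threshold = sum(sig & abs(records$rho) > rho_thresh),
    q_thresh = q_thresh, rho_thresh = rho_thresh),
    class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf(
    "correlation map: %d tested, %d significant (q < %g; %.2f%%)\n",
    x$n_tested, x$n_significant, x$q_thresh, x$pct_significant))
  if (x$n_significant > 0)
    cat(sprintf("  positive %d (%.2f%% -> %d%%), negative %d (%.2f%% -> %d%%); |rho| > %g: %d\n",
                x$n_positive, x$pct_positive, x$pct_positive_rounded,
                x$n_negative, x$pct_negative, x$pct_negative_rounded,
                x$rho_thresh, x$n_abs_rho_above_threshold))
  invisible(x)
}

#' Per-batch replication of the combined correlation map
#'
#' Among CpGs significant in the combined analysis, counts those nominally
#' correlated (`p < p_thresh`) in each batch-specific analysis and in both.
#'
#' @param records_all combined-map records (significance already called).
#' @param records_batch1,records_batch2 per-batch records.
#' @param p_thresh nominal replication threshold.
#' @return list with counts and fractions.
#' @export
per_batch_crosscheck <- function(records_all, records_batch1, records_batch2,
                                 p_thresh = 0.05) {
  sig <- records_all$cpg_id[records_all$significant %in% TRUE]
  hit <- function(rec) {
    ok <- rec$cpg_id[!is.na(rec$p) & rec$p < p_thresh]
    sig %in% ok
  }
  in1 <- hit(records_batch1); in2 <- hit(records_batch2)
  n <- length(sig)
  fr <- function(k) if (n == 0) NA_real_ else k / n
  list(n_significant = n,
       n_batch1 = sum(in1), n_batch2 = sum(in2), n_both = sum(in1 & in2),
       frac_batch1 = fr(sum(in1)), frac_batch2 = fr(sum(in2)),
       frac_both = fr(sum(in1 & in2)), p_thresh = p_thresh)
}
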