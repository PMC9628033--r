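#' Exclude samples with low bisulfite conversion efficiency
#'
#' Samples whose conversion efficiency falls below the threshold are
#' excluded; samples kept at exactly the threshold. When one member of a
#' brain/buccal pair is excluded, its partner is flagged (kept in the data
#' but marked for exclusion from paired analyses).
#'
#' @param sheet sample sheet with columns `sample_id`,
#'   `conversion_efficiency`, and (for partner flagging) `individual_id`.
#' @param threshold percent; samples with efficiency >= threshold are kept.
#' @return list with `kept` (sample ids), `flagged_partners` (ids kept but
#'   flagged because their pair partner failed) and `report` (qc_report).
#' @export
filter_samples_by_conversion <- function(sheet, threshold = 80) {
  stopifnot(is.data.frame(sheet))
  if (nrow(sheet) == 0L)
    return(list(kept = character(), flagged_partners = character(),
                report = qc_report(data.frame(id = character(),
                                              reason = character()), 0L, 0L)))
  eff <- sheet$conversion_efficiency
  if (is.null(eff) || anyNA(eff))
    stop("missing conversion efficiency for sample(s): ",
         paste(sheet$sample_id[is.na(eff)], collapse = ", "), call. = FALSE)
  drop <- eff < threshold
  kept <- sheet$sample_id[!drop]
  flagged <- character()
  if (any(drop) && !is.null(sheet$individual_id)) {
    bad_ind <- sheet$individual_id[drop]
    flagged <- setdiff(sheet$sample_id[sheet$individual_id %in% bad_ind],
                       sheet$sample_id[drop])
  }
  rep <- qc_report(
    data.frame(id = sheet$sample_id[drop],
               reason = sprintf("conversion efficiency %.1f%% < %g%%",
                                eff[drop], threshold),
               stringsAsFactors = FALSE),
    nrow(sheet), length(kept))
  list(kept = kept, flagged_partners = flagged, report = rep)
}

#' Flag outlier samples from low-dimensional structure
#'
#' A deterministic outlier score: principal components are computed on a
#' spatially decorrelated probe subset (one CpG per genomic bin when an
#' annotation is supplied, otherwise all probes), and each sample is scored
#' on the first two components by its distance beyond the Tukey fence
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, scaled by the IQR. The score is the
#' maximum over the two components; samples with score > `threshold` are
#' flagged.
#'
#' @param betas CpG x sample beta matrix.
#' @param threshold outlyingness score cutoff (default 0.15).
#' @param annotation optional [probe_annotation()] enabling bin subsampling.
#' @param bin_size bin width in bp for the subsample.
#' @param seed seed for the bin subsample.
#' @return list with `outliers` (sample ids), `scores` (named numeric) and
#'   `report`.
#' @export
detect_outlier_samples <- function(betas, threshold = 0.15, annotation = NULL,
                                   bin_size = 1e5, seed = 1L) {
  stopifnot(is.matrix(betas))
  if (ncol(betas) < 4L) stop("need at least 4 samples", call. = FALSE)
  X <- if (!is.null(annotation)) {
    keep <- intersect(bin_subsample(annotation, bin_size, seed),
                      rownames(betas))
    betas[keep, , drop = FALSE]
  } else betas
  n <- ncol(X)
  scores <- setNames(rep(0, n), colnames(X))
  if (all(abs(X - rowMeans(X)) < 1e-12)) {
    # identical columns: nothing to flag
    return(list(outliers = character(), scores = scores,
                report = qc_report(data.frame(id = character(),
                                              reason = character()), n, n)))
  }
  pc <- stats::prcomp(t(X), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  for (i in seq_len(k)) {
    x <- pc$x[, i]
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[2] + 1.5 * iqr
    excess <- pmax(0, lo - x, x - hi)
    s <- if (iqr > 0) excess / iqr else ifelse(excess > 0, Inf, 0)
    scores <- pmax(scores, s)
  }
  out <- names(scores)[scores > threshold]
  list(outliers = out, scores = scores,
       report = qc_report(
         data.frame(id = out,
                    reason = sprintf("outlyingness score %.3g > %g",
                                     scores[out], threshold),
                    stringsAsFactors = FALSE),
         n, n - length(out)))
}

#' Remove blacklisted probes
#'
#' Drops probes on the X or Y chromosome, probes overlapping SNPs, and
#' probes mapping to multiple genomic locations, per the annotation flags.
#'
#' @param annotation [probe_annotation()] with flag columns.
#' @return list with `kept` (cpg ids) and `report`.
#' @export
filter_probes <- function(annotation) {
  stopifnot(is.data.frame(annotation))
  flags <- cbind(xy = annotation$flag_xy, snp = annotation$flag_snp,
                 multimap = annotation$flag_multimap)
  if (is.null(flags) || anyNA(flags))
    stop("blacklist flags must be present and non-missing", call. = FALSE)
  bad <- rowSums(flags) > 0
  reasons <- apply(flags[bad, , drop = FALSE], 1, function(f)
    paste(c("X/Y chromosome", "SNP-overlapping",
            "multi-mapping")[as.logical(f)], collapse = "; "))
  list(kept = annotation$cpg_id[!bad],
       report = qc_report(
         data.frame(id = annotation$cpg_id[bad], reason = unname(reasons),
                    stringsAsFactors = FALSE),
         nrow(annotation), sum(!bad)))
}

#' Mask values by detection p-value and remove low-beadcount probes
#'
#' Entries with detection p-value above `p_thresh` are set to `NA`; probes
#' where fewer than `min_beads` beads were observed in strictly more than
#' `max_fail_frac` of samples are removed entirely.
#'
#' @param betas,detp,beadcount dimension-aligned CpG x sample matrices.
#' @param p_thresh detection p-value cutoff.
#' @param min_beads minimum bead count.
#' @param max_fail_frac tolerated fraction of low-bead samples per probe.
#' @return list with `betas` (masked, probes possibly removed) and `report`.
#' @export
mask_by_detection <- function(betas, detp, beadcount, p_thresh = 0.01,
                              min_beads = 3, max_fail_frac = 0.05) {
  if (!all(dim(betas) == dim(detp)) || !all(dim(betas) == dim(beadcount)))
    stop("betas, detp and beadcount must be dimension-aligned", call. = FALSE)
  if (!is.null(rownames(betas)) && !is.null(rownames(detp)) &&
      !identical(rownames(betas), rownames(detp)))
    stop("betas and detp probe ids differ", call. = FALSE)
  masked <- betas
  masked[detp > p_thresh] <- NA
  fail_frac <- rowMeans(beadcount < min_beads)
  drop <- fail_frac > max_fail_frac
  out <- masked[!drop, , drop = FALSE]
  ids <- rownames(betas) %||% as.character(seq_len(nrow(betas)))
  list(betas = out,
       report = qc_report(
         data.frame(id = ids[drop],
                    reason = sprintf("< %g beads in %.1f%% of samples",
                                     min_beads, 100 * fail_frac[drop]),
                    stringsAsFactors = FALSE),
         nrow(betas), nrow(out)))
}

#' Reference-based cell-composition estimation
#'
#' Non-negative least squares deconvolution: for each sample, fractions `w`
#' minimise `||m - R w||^2` subject to `w >= 0` over the reference CpGs,
#' then are renormalised to sum to one.
#'
#' @param betas CpG x sample beta matrix (reference CpGs must be present).
#' @param reference CpG x cell-type signature matrix (beta scale).
#' @return list with `fractions` (sample x cell-type matrix, rows sum to 1)
#'   and `residual_norm` (per-sample residual of the NNLS fit).
#' @export
estimate_cell_composition <- function(betas, reference) {
  stopifnot(is.matrix(betas), is.matrix(reference))
  ref_cpgs <- rownames(reference)
  if (!all(ref_cpgs %in% rownames(betas)))
    stop("reference CpGs must be a subset of the beta matrix probes",
         call. = FALSE)
  if (qr(reference)$rank < ncol(reference))
    stop("reference signature matrix is rank-deficient", call. = FALSE)
  M <- betas[ref_cpgs, , drop = FALSE]
  K <- ncol(reference)
  frac <- matrix(NA_real_, ncol(M), K,
                 dimnames = list(colnames(M), colnames(reference)))
  rn <- setNames(numeric(ncol(M)), colnames(M))
  for (i in seq_len(ncol(M))) {
    ok <- !is.na(M[, i])
    fit <- pracma::lsqnonneg(reference[ok, , drop = FALSE], M[ok, i])
    w <- fit$x
    if (sum(w) <= 0) {
      warning("all-zero NNLS solution; returning uniform fractions")
      w <- rep(1 / K, K)
    }
    frac[i, ] <- w / sum(w)
    rn[i] <- sqrt(sum(fit$resid.norm))
  }
  list(fractions = frac, residual_norm = rn)
}

#' Intersect probe sets across matrices
#'
#' @param matrices list of beta matrices (or character vectors of probe ids).
#' @return common probe ids, in the order of the first element.
#' @export
intersect_probes <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  sets <- lapply(matrices, function(m)
    if (is.character(m)) m else rownames(m))
  common <- Reduce(intersect, sets[-1], sets[[1]])
  common <- sets[[1]][sets[[1]] %in% common]
  if (!length(common))
    stop("no probes shared by all matrices: nothing to analyse", call. = FALSE)
  common
}
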