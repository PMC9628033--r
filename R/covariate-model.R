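#' Draw one CpG per genomic bin
#'
#' Divides each chromosome into half-open bins of `bin_size` bp on 0-based
#' coordinates (1-based positions are converted by `pos - 1`) and draws one
#' CpG uniformly at random (seeded) from every non-empty bin. The result is a
#' spatially decorrelated probe subset used for PCA and as the background of
#' enrichment tests.
#'
#' @param annotation [probe_annotation()].
#' @param bin_size bin width in bp.
#' @param seed integer seed; ties within a bin are resolved by a uniform
#'   seeded choice.
#' @return character vector of CpG ids sorted by (chrom, pos).
#' @export
bin_subsample <- function(annotation, bin_size = 1e5, seed = 1L) {
  stopifnot(is.data.frame(annotation), nrow(annotation) > 0)
  bin <- (annotation$pos - 1) %/% bin_size
  key <- paste(annotation$chrom, bin, sep = ":")
  with_seed(seed, {
    picked <- vapply(split(seq_len(nrow(annotation)), key), function(idx) {
      if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
    }, integer(1))
    picked <- sort(unname(picked))
    ord <- order(annotation$chrom[picked], annotation$pos[picked])
    annotation$cpg_id[picked[ord]]
  })
}

#' PCA of a beta matrix over a probe subset
#'
#' Samples are observations, probes are variables; variables are centered but
#' not scaled; components come from the singular value decomposition.
#'
#' @param betas CpG x sample matrix.
#' @param subset optional CpG ids to use (e.g. from [bin_subsample()]);
#'   default all probes.
#' @return object of class `meth_pca`: `scores` (samples x components),
#'   `loadings`, `eigenvalues`, `variance_explained`, `n_selected` (NA until
#'   [select_pcs()] is applied), `subset_cpgs`.
#' @export
meth_pca <- function(betas, subset = NULL) {
  stopifnot(is.matrix(betas))
  if (ncol(betas) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (!is.null(subset)) {
    if (!all(subset %in% rownames(betas)))
      stop("subset contains probes absent from the matrix", call. = FALSE)
    betas <- betas[subset, , drop = FALSE]
  }
  X <- t(betas)
  if (all(abs(sweep(X, 2, colMeans(X))) < 1e-300) ||
      sum(apply(X, 2, stats::var)) == 0)
    stop("constant matrix: PCA undefined", call. = FALSE)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  structure(list(scores = pr$x, loadings = pr$rotation, eigenvalues = ev,
                 variance_explained = ev / sum(ev), n_selected = NA_integer_,
                 subset_cpgs = subset %||% rownames(betas)),
            class = "meth_pca")
}

#' @export
print.meth_pca <- function(x, ...) {
  cat(sprintf("meth_pca: %d samples x %d probes; top variance fractions: %s\n",
              nrow(x$scores), length(x$subset_cpgs),
              paste(sprintf("%.2f", utils::head(x$variance_explained, 5)),
                    collapse = " ")))
  invisible(x)
}

#' Choose the number of principal components to retain
#'
#' `method = "cumvar"` retains the smallest k whose cumulative variance
#' explained reaches `frac` (a reproducible stand-in for a visual scree-plot
#' choice); `method = "fixed"` retains exactly `k` (e.g. the 3-PC direct
#' adjustment variant).
#'
#' @param pca [meth_pca()] result.
#' @param method `"cumvar"` or `"fixed"`.
#' @param frac cumulative variance target for `"cumvar"`.
#' @param k component count for `"fixed"`.
#' @return the `meth_pca` object with `n_selected` set.
#' @export
select_pcs <- function(pca, method = c("cumvar", "fixed"), frac = 0.8,
                       k = NULL) {
  stopifnot(inherits(pca, "meth_pca"), length(pca$eigenvalues) > 0)
  method <- match.arg(method)
  n <- switch(method,
    fixed = {
      if (is.null(k)) stop("method 'fixed' needs k", call. = FALSE)
      as.integer(k)
    },
    cumvar = {
      cv <- cumsum(pca$variance_explained)
      as.integer(which(cv >= frac - 1e-12)[1])
    })
  if (is.na(n) || n < 1 || n > length(pca$eigenvalues))
    stop("invalid number of PCs selected", call. = FALSE)
  pca$n_selected <- n
  pca
}

#' Screen covariates against retained principal components
#'
#' For numeric covariates, a two-sided Pearson correlation test (t with n-2
#' df) between the covariate and each retained PC score vector; for
#' categorical covariates, a one-way ANOVA of the PC scores grouped by level.
#' A covariate is flagged when its minimum p-value over the retained PCs is
#' below `alpha`.
#'
#' @param pca [meth_pca()] with `n_selected` set (see [select_pcs()]).
#' @param sheet data.frame of covariates, rows aligned to `pca$scores` rows
#'   (matched by rownames/sample_id when available).
#' @param covariates character vector of column names to screen.
#' @param alpha per-test significance threshold.
#' @return list of class `covariate_screen`: `table` (covariate, pc, test,
#'   statistic, p), `flagged`, `alpha`, `n_pcs`.
#' @export
screen_covariates <- function(pca, sheet, covariates, alpha = 0.01) {
  stopifnot(inherits(pca, "meth_pca"))
  if (is.na(pca$n_selected))
    stop("run select_pcs() first (n_selected unset)", call. = FALSE)
  stopifnot(is.data.frame(sheet), all(covariates %in% names(sheet)))
  if (!is.null(sheet$sample_id) && !is.null(rownames(pca$scores))) {
    if (!setequal(sheet$sample_id, rownames(pca$scores)))
      stop("sample sheet does not match PCA samples", call. = FALSE)
    sheet <- sheet[match(rownames(pca$scores), sheet$sample_id), ,
                   drop = FALSE]
  } else if (nrow(sheet) != nrow(pca$scores))
    stop("covariates not aligned to PCA samples", call. = FALSE)
  n <- nrow(pca$scores)
  rows <- list()
  for (cv in covariates) {
    x <- sheet[[cv]]
    numeric_cov <- is.numeric(x)
    if (numeric_cov && stats::var(x) == 0) {
      warning("covariate '", cv, "' has zero variance; skipped")
      next
    }
    if (!numeric_cov) {
      x <- factor(x)
      if (nlevels(droplevels(x)) < 2L) {
        warning("covariate '", cv, "' has a single level; skipped")
        next
      }
      x <- droplevels(x)
    }
    for (i in seq_len(pca$n_selected)) {
      pc <- pca$scores[, i]
      if (numeric_cov) {
        r <- stats::cor(x - mean(x), pc - mean(pc))
        tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
        p <- 2 * stats::pt(-abs(tt), df = n - 2)
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cv, pc = i, test = "pearson", statistic = r, p = p,
          stringsAsFactors = FALSE)
      } else {
        a <- stats::anova(stats::aov(pc ~ x))
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cv, pc = i, test = "anova",
          statistic = a[["F value"]][1], p = a[["Pr(>F)"]][1],
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(covariate = character(), pc = integer(),
                         test = character(), statistic = numeric(),
                         p = numeric(), stringsAsFactors = FALSE)
  minp <- tapply(tab$p, tab$covariate, min)
  flagged <- names(minp)[minp < alpha]
  structure(list(table = tab, flagged = flagged %||% character(),
                 alpha = alpha, n_pcs = pca$n_selected),
            class = "covariate_screen")
}

#' @export
print.covariate_screen <- function(x, ...) {
  cat(sprintf("covariate screen over %d PCs (alpha = %g): flagged %s\n",
              x$n_pcs, x$alpha,
              if (length(x$flagged)) paste(x$flagged, collapse = ", ")
              else "<none>"))
  invisible(x)
}

# Encode a nuisance data.frame into a design block: numeric columns centered,
# factors expanded with sum-to-zero contrasts (no intercept column). With
# this coding, subtracting the fitted nuisance contribution keeps the grand
# mean of each probe.
encode_nuisance <- function(design) {
  stopifnot(is.data.frame(design))
  blocks <- list()
  for (nm in names(design)) {
    x <- design[[nm]]
    if (is.numeric(x)) {
      blocks[[nm]] <- matrix(x - mean(x), ncol = 1,
                             dimnames = list(NULL, nm))
    } else {
      f <- droplevels(factor(x))
      if (nlevels(f) < 2L)
        stop("nuisance factor '", nm, "' has a single level", call. = FALSE)
      mm <- stats::model.matrix(~ f, contrasts.arg = list(f = "contr.sum"))
      mm <- mm[, -1, drop = FALSE]
      colnames(mm) <- paste0(nm, seq_len(ncol(mm)))
      blocks[[nm]] <- mm
    }
  }
  do.call(cbind, blocks)
}

#' Remove nuisance covariate effects from a beta matrix by linear regression
#'
#' Per CpG, an ordinary least squares fit of the beta values on an intercept
#' plus the encoded nuisance covariates; the fitted nuisance contribution is
#' subtracted. Categorical covariates are effect-coded (sum-to-zero) so the
#' adjusted values keep the grand mean; numeric covariates are centered.
#' Adjusted values may leave \[0,1\] and are not clipped.
#'
#' @param betas CpG x sample matrix.
#' @param design data.frame of nuisance covariates aligned to the columns of
#'   `betas` (zero columns = identity).
#' @return adjusted matrix of the same shape.
#' @export
residualize <- function(betas, design) {
  stopifnot(is.matrix(betas))
  if (is.null(design) || (is.data.frame(design) && ncol(design) == 0L))
    return(betas)
  if (nrow(design) != ncol(betas))
    stop("design rows must match beta matrix columns", call. = FALSE)
  Z <- encode_nuisance(design)
  D <- cbind(`(Intercept)` = 1, Z)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    aliased <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("rank-deficient nuisance design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  B <- qr.coef(qrD, t(betas))          # coefficients x CpGs
  fitted_nuis <- Z %*% B[-1, , drop = FALSE]
  out <- betas - t(fitted_nuis)
  dimnames(out) <- dimnames(betas)
  out
}

#' Combine two batches and remove the batch effect
#'
#' Column-concatenates two beta matrices sharing the same probe set, then
#' residualizes every probe on the batch factor (see [residualize()]).
#'
#' @param batch1,batch2 CpG x sample matrices with identical probe sets and
#'   disjoint samples.
#' @param labels length-2 batch labels.
#' @return list with `betas` (combined, batch-adjusted) and `batch` (factor).
#' @export
combine_and_debatch <- function(batch1, batch2, labels = c("B1", "B2")) {
  stopifnot(is.matrix(batch1), is.matrix(batch2))
  if (ncol(batch1) == 0L || ncol(batch2) == 0L)
    stop("each batch must contain at least one sample", call. = FALSE)
  if (!identical(rownames(batch1), rownames(batch2)))
    stop("probe sets differ between batches (run intersect_probes first)",
         call. = FALSE)
  if (length(intersect(colnames(batch1), colnames(batch2))))
    stop("batches share sample ids", call. = FALSE)
  combined <- cbind(batch1, batch2)
  batch <- factor(rep(labels, c(ncol(batch1), ncol(batch2))))
  list(betas = residualize(combined, data.frame(batch = batch)),
       batch = batch)
}

#' Adjust a beta matrix directly for its leading principal components
#'
#' Robustness variant of the covariate model: computes a PCA on the
#' bin-subsampled probes and residualizes all probes on the first `k` PC
#' score vectors.
#'
#' @param betas CpG x sample matrix.
#' @param annotation [probe_annotation()] for bin subsampling.
#' @param k number of PCs to remove (`k = 0` returns the input unchanged).
#' @param bin_size,seed passed to [bin_subsample()].
#' @return adjusted matrix.
#' @export
direct_pc_adjust <- function(betas, annotation, k = 3, bin_size = 1e5,
                             seed = 1L) {
  stopifnot(is.matrix(betas))
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  if (k == 0) return(betas)
  if (k > ncol(betas) - 1L)
    stop("k must be at most n_samples - 1", call. = FALSE)
  subset <- intersect(bin_subsample(annotation, bin_size, seed),
                      rownames(betas))
  pc <- meth_pca(betas, subset)
  scores <- as.data.frame(pc$scores[, seq_len(k), drop = FALSE])
  residualize(betas, scores)
}
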