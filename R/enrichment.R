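#' Chi-squared test of independence on a contingency table
#'
#' Expected counts from the margins (`E = row * col / total`); statistic
#' `sum((|O - E| - c)^2 / E)` with `c = 0.5` for 2x2 tables when `yates`
#' (the continuity-correction default of R's `chisq.test`), else `c = 0`;
#' df `(r-1)(c-1)`; upper-tail chi-squared p. Pearson residuals
#' `(O - E)/sqrt(E)` are always computed without continuity correction, so
#' their squares sum to the uncorrected statistic.
#'
#' @param table numeric matrix of counts, at least 2x2.
#' @param yates apply the continuity correction for 2x2 tables.
#' @return list of class `enrichment_result`: observed, expected, chi2, df,
#'   p, residuals, yates.
#' @export
enrichment_chisq <- function(table, yates = TRUE) {
  O <- as.matrix(table)
  if (nrow(O) < 2 || ncol(O) < 2)
    stop("need at least a 2x2 table", call. = FALSE)
  if (any(O < 0) || anyNA(O)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0))
    stop("zero margin in contingency table", call. = FALSE)
  E <- outer(rs, cs) / sum(O)
  corr <- if (yates && all(dim(O) == 2L)) pmin(0.5, abs(O - E)) else 0
  chi2 <- sum((abs(O - E) - corr)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  structure(list(observed = O, expected = E, chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 residuals = (O - E) / sqrt(E),
                 yates = yates && all(dim(O) == 2L)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("chi-squared = %.4g on %d df, p = %.3g%s\n", x$chi2, x$df, x$p,
              if (x$yates) " (Yates-corrected)" else ""))
  invisible(x)
}

#' mQTL enrichment among correlated CpGs on a bin-matched background
#'
#' Draws a spatially decorrelated background (one CpG per genomic bin, see
#' [bin_subsample()]) from the probe universe, cross-tabulates correlation
#' status against mQTL status on that subset, and runs [enrichment_chisq()].
#'
#' @param correlated,mqtl CpG id sets (subsets of `universe`).
#' @param universe CpG ids defining the tested probe universe.
#' @param annotation [probe_annotation()] covering the universe.
#' @param bin_size,seed background subsampling parameters.
#' @param yates continuity correction flag (2x2 table).
#' @return `enrichment_result` with extra fields `subset_size` and `seed`.
#' @export
mqtl_enrichment <- function(correlated, mqtl, universe, annotation,
                            bin_size = 1e5, seed = 1L, yates = TRUE) {
  if (!all(correlated %in% universe) || !all(mqtl %in% universe))
    stop("correlated and mqtl sets must be subsets of the universe",
         call. = FALSE)
  ann <- annotation[annotation$cpg_id %in% universe, , drop = FALSE]
  sub <- bin_subsample(ann, bin_size, seed)
  tab <- table(correlated = factor(sub %in% correlated, c(FALSE, TRUE)),
               mqtl = factor(sub %in% mqtl, c(FALSE, TRUE)))
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("zero margin in contingency table", call. = FALSE)
  if (any(outer(rs, cs) / sum(tab) < 1))
    stop("expected count below 1: background subset too small for a valid ",
         "chi-squared test; enlarge the universe or the bins", call. = FALSE)
  res <- enrichment_chisq(unclass(tab), yates = yates)
  res$subset_size <- length(sub)
  res$seed <- seed
  res
}

#' Gene-region enrichment of a CpG set
#'
#' Cross-tabulates membership in `correlated` against the eight gene-region
#' categories over the universe and tests the distribution shift with an
#' uncorrected chi-squared test. Per-region Pearson residuals of the
#' correlated row give the enrichment (positive) / depletion (negative)
#' signs.
#'
#' @param correlated CpG id set.
#' @param universe CpG ids (denominator population).
#' @param annotation [probe_annotation()] with a `region` for every CpG.
#' @return `enrichment_result` with `region_residuals` (named, correlated
#'   row).
#' @export
region_enrichment <- function(correlated, universe, annotation) {
  ann <- annotation[annotation$cpg_id %in% universe, , drop = FALSE]
  if (!all(correlated %in% universe))
    stop("correlated set must be a subset of the universe", call. = FALSE)
  region <- factor(ann$region, levels = REGION_CATEGORIES)
  present <- table(region) > 0
  if (!all(present)) {
    warning("region categor(ies) absent from universe, dropped: ",
            paste(names(present)[!present], collapse = ", "))
    region <- droplevels(region)
  }
  tab <- table(correlated = factor(ann$cpg_id %in% correlated,
                                   c(FALSE, TRUE)),
               region = region)
  res <- enrichment_chisq(unclass(tab), yates = FALSE)
  res$region_residuals <- res$residuals["TRUE", ]
  res
}

#' Multi-set overlap report with declared denominators
#'
#' Computes set sizes, all pairwise intersections, the three-way
#' intersection (when three or more sets are given), unions, and
#' complements, and reports each count as a percentage of a declared
#' denominator, raw and rounded half-up at the configured precision.
#'
#' @param sets named list of CpG id vectors (>= 2 sets).
#' @param denominator name of the set used as percentage denominator
#'   (default the first set).
#' @param digits decimal places for the rounded percentage.
#' @return data.frame of class `overlap_report`: quantity, count,
#'   denominator, pct, pct_rounded.
#' @export
overlap_report <- function(sets, denominator = names(sets)[1], digits = 0) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  den_n <- length(sets[[denominator]])
  rows <- list()
  add <- function(quantity, ids) {
    k <- length(ids)
    pct <- if (den_n == 0) NA_real_ else 100 * k / den_n
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, count = k, denominator = den_n, pct = pct,
      pct_rounded = round_half_up(pct, digits), stringsAsFactors = FALSE)
  }
  nm <- names(sets)
  for (a in nm) add(a, sets[[a]])
  for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j) {
    add(paste(nm[i], nm[j], sep = " & "),
        intersect(sets[[nm[i]]], sets[[nm[j]]]))
    add(paste(nm[i], nm[j], sep = " | "), union(sets[[nm[i]]], sets[[nm[j]]]))
  }
  if (length(nm) >= 3L) {
    add(paste(nm[1:3], collapse = " & "),
        Reduce(intersect, sets[nm[1:3]]))
    add(paste(nm[1:3], collapse = " | "), Reduce(union, sets[nm[1:3]]))
  }
  # complement of the other sets within the denominator set
  others <- setdiff(nm, denominator)
  add(paste0(denominator, " \\ (", paste(others, collapse = " | "), ")"),
      setdiff(sets[[denominator]], Reduce(union, sets[others])))
  out <- do.call(rbind, rows)
  class(out) <- c("overlap_report", "data.frame")
  out
}

#' Look up CpGs in a correlation map
#'
#' Returns, per query CpG, whether it was tested, its rho/p/q, significance
#' at `q < 0.05` and nominal `p < 0.05`, and membership in each supplied
#' mQTL set. Unknown ids get `tested = FALSE`.
#'
#' @param records [spearman_map()] output.
#' @param query CpG ids to look up.
#' @param mqtl_sets named list of CpG id sets (one logical column each).
#' @return data.frame, one row per query id.
#' @export
lookup_cpgs <- function(records, query, mqtl_sets = list()) {
  m <- match(query, records$cpg_id)
  out <- data.frame(cpg_id = query, tested = !is.na(m),
                    rho = records$rho[m], p = records$p[m],
                    q = records$q[m],
                    significant_q05 = !is.na(records$q[m]) &
                      records$q[m] < 0.05,
                    nominal_p05 = !is.na(records$p[m]) &
                      records$p[m] < 0.05,
                    stringsAsFactors = FALSE)
  for (nm in names(mqtl_sets))
    out[[paste0("in_", nm)]] <- query %in% mqtl_sets[[nm]]
  out
}
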