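pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulate = list(),            # arguments passed to sim_config()
    q_thresh = 0.05,              # FDR threshold for the correlation map
    alpha = 0.01,                 # covariate screen threshold
    rho_thresh = 0.5,             # strong-correlation variant
    cis_window = 1e6,
    conversion_threshold = 80,
    outlier_threshold = 0.15,
    detection_p = 0.01,
    min_beads = 3,
    max_fail_frac = 0.05,
    bin_size = 1e5,
    pc_method = "cumvar",
    pc_frac = 0.8,
    direct_pc_k = 3,
    n_meth_pcs_mqtl = 10,
    n_genetic_pcs = 5,
    run_mqtl = TRUE,
    mqtl_tissue = "buccal",
    report_p = 0.05,
    yates = TRUE,
    inputs = list()               # beta_tsv (named list of 4), sample_sheet,
                                  # annotation_tsv, genotypes_tsv
  )
}

#' Build / validate a pipeline configuration
#'
#' Merges user settings over the documented defaults; unknown keys are
#' rejected. Configurations can be read from YAML/JSON via
#' [read_pipeline_config()]; every [run_pipeline()] call writes a resolved
#' snapshot next to its outputs.
#'
#' @param ... settings overriding the defaults (see `pipeline_defaults`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  defs <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defs))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defs, user)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML (or JSON) configuration file.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

log_msg <- function(...) message(sprintf(...))

#' Run the paired-tissue correlation pipeline
#'
#' Executes the stages `simulate -> qc -> adjust -> combine -> correlate ->
#' mqtl -> enrich -> report`, writing every artifact (beta matrices,
#' QC reports, screen results, correlation map, mQTL records, enrichment
#' results, summary, resolved configuration) under `out_dir`. With
#' `"simulate"` among the stages the input data come from the built-in
#' simulator; otherwise beta matrices, sample sheet, annotation and
#' genotypes are read from the paths in `config$inputs`.
#'
#' @param config [pipeline_config()].
#' @param out_dir output directory (created).
#' @param stages character subset of the stage names, in pipeline order.
#' @return invisible list with the main in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "methcormap_out",
                         stages = c("simulate", "qc", "adjust", "combine",
                                    "correlate", "mqtl", "enrich", "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "qc", "adjust", "combine", "correlate", "mqtl",
                  "enrich", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- list(config = config)

  if ("simulate" %in% stages) {
    log_msg("[simulate] generating paired dataset (seed %d)", config$seed)
    scfg <- do.call(sim_config, utils::modifyList(list(seed = config$seed),
                                                  config$simulate))
    sim <- generate_paired_dataset(scfg)
    st$betas <- sim$betas
    st$sheet <- sim$sheet
    st$annotation <- sim$annotation
    st$genotypes <- sim$genotypes
    st$cell_reference <- sim$cell_reference
    st$truth <- sim$truth
    for (nm in names(sim$betas))
      write_beta_tsv(sim$betas[[nm]], file.path(out_dir,
                                                paste0("betas_", nm, ".tsv")))
    data.table::fwrite(sim$sheet, file.path(out_dir, "sample_sheet.csv"))
    write_annotation_tsv(sim$annotation, file.path(out_dir, "annotation.tsv"))
    write_genotypes_tsv(sim$genotypes, file.path(out_dir, "genotypes.tsv"))
    data.table::fwrite(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t")
  } else {
    inp <- config$inputs
    if (is.null(inp$beta_tsv) || length(inp$beta_tsv) != 4L)
      stop("config$inputs$beta_tsv must name four tissue_batch TSVs",
           call. = FALSE)
    st$betas <- lapply(inp$beta_tsv, read_beta_tsv)
    st$sheet <- read_sample_sheet(inp$sample_sheet)
    st$annotation <- read_annotation_tsv(inp$annotation_tsv)
    if (!is.null(inp$genotypes_tsv))
      st$genotypes <- read_genotypes(inp$genotypes_tsv, "dosage_tsv")
  }
  dataset_names <- names(st$betas)
  tissues <- unique(sub("_[^_]+$", "", dataset_names))

  if ("qc" %in% stages) {
    conv <- filter_samples_by_conversion(st$sheet, config$conversion_threshold)
    log_msg("[qc] conversion filter: %d -> %d samples",
            conv$report$n_before, conv$report$n_after)
    st$betas <- lapply(st$betas, function(m)
      m[, colnames(m) %in% conv$kept, drop = FALSE])
    for (nm in dataset_names) {
      if (ncol(st$betas[[nm]]) >= 4) {
        out <- detect_outlier_samples(st$betas[[nm]], config$outlier_threshold,
                                      st$annotation, config$bin_size,
                                      config$seed)
        if (length(out$outliers)) {
          log_msg("[qc] %s: removing outlier(s) %s", nm,
                  paste(out$outliers, collapse = ", "))
          st$betas[[nm]] <- st$betas[[nm]][,
            !colnames(st$betas[[nm]]) %in% out$outliers, drop = FALSE]
        }
      }
    }
    pf <- filter_probes(st$annotation)
    common <- intersect_probes(c(list(pf$kept), unname(st$betas)))
    log_msg("[qc] probes: %d flagged, %d in all datasets",
            pf$report$n_before - pf$report$n_after, length(common))
    st$betas <- lapply(st$betas, function(m) m[common, , drop = FALSE])
    st$annotation <- st$annotation[match(common, st$annotation$cpg_id), ]
    # drop individuals that lost a sample anywhere so pairing stays bijective
    kept_samples <- unlist(lapply(st$betas, colnames))
    sheet_kept <- st$sheet[st$sheet$sample_id %in% kept_samples, ]
    full <- names(which(table(sheet_kept$individual_id) == 2L))
    keep_ids <- sheet_kept$sample_id[sheet_kept$individual_id %in% full]
    st$betas <- lapply(st$betas, function(m)
      m[, colnames(m) %in% keep_ids, drop = FALSE])
    st$sheet <- st$sheet[st$sheet$sample_id %in% keep_ids, ]
    utils::write.table(conv$report$excluded,
                       file.path(out_dir, "qc_excluded_samples.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if ("adjust" %in% stages) {
    st$screens <- list()
    for (nm in dataset_names) {
      m <- st$betas[[nm]]
      tissue <- sub("_[^_]+$", "", nm)
      sheet_d <- st$sheet[match(colnames(m), st$sheet$sample_id), ]
      covs <- sheet_d[, c("conversion_efficiency", "diagnosis", "array_id",
                          "array_position", "extraction_date"),
                      drop = FALSE]
      if (!is.null(st$cell_reference[[tissue]])) {
        cc <- estimate_cell_composition(m, st$cell_reference[[tissue]])
        covs$cell_frac_dominant <- cc$fractions[, 1]
      }
      covs$sample_id <- sheet_d$sample_id
      sub <- intersect(bin_subsample(st$annotation, config$bin_size,
                                     config$seed), rownames(m))
      pc <- select_pcs(meth_pca(m, sub), config$pc_method,
                       frac = config$pc_frac, k = config$direct_pc_k)
      scr <- screen_covariates(pc, covs,
                               setdiff(names(covs), "sample_id"),
                               alpha = config$alpha)
      log_msg("[adjust] %s: %d PCs, flagged: %s", nm, pc$n_selected,
              paste(scr$flagged, collapse = ", "))
      st$screens[[nm]] <- scr
      if (length(scr$flagged))
        st$betas[[nm]] <- residualize(m, covs[, scr$flagged, drop = FALSE])
      utils::write.table(scr$table,
                         file.path(out_dir, paste0("screen_", nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  if ("combine" %in% stages) {
    st$combined <- list()
    for (t in tissues) {
      parts <- st$betas[grep(paste0("^", t, "_"), dataset_names, value = TRUE)]
      st$combined[[t]] <- combine_and_debatch(parts[[1]], parts[[2]])$betas
      log_msg("[combine] %s: %d samples after batch removal", t,
              ncol(st$combined[[t]]))
    }
  }

  if ("correlate" %in% stages) {
    st$map <- spearman_map(st$combined[[tissues[1]]],
                           st$combined[[tissues[2]]],
                           annotation = st$annotation,
                           q_thresh = config$q_thresh)
    st$summary <- summarize_correlations(st$map, config$q_thresh,
                                         config$rho_thresh)
    log_msg("[correlate] %d tested, %d significant",
            st$summary$n_tested, st$summary$n_significant)
    maps_b <- lapply(c("B1", "B2"), function(b) {
      spearman_map(st$betas[[paste0(tissues[1], "_", b)]],
                   st$betas[[paste0(tissues[2], "_", b)]],
                   annotation = st$annotation, q_thresh = config$q_thresh)
    })
    st$crosscheck <- per_batch_crosscheck(st$map, maps_b[[1]], maps_b[[2]])
    data.table::fwrite(as.data.frame(st$map),
                       file.path(out_dir, "correlation_map.tsv"), sep = "\t")
  }

  if ("mqtl" %in% stages && isTRUE(config$run_mqtl) &&
      !is.null(st$genotypes)) {
    t <- config$mqtl_tissue
    parts <- st$betas[grep(paste0("^", t, "_"), dataset_names, value = TRUE)]
    raw <- cbind(parts[[1]], parts[[2]])
    sheet_t <- st$sheet[match(colnames(raw), st$sheet$sample_id), ]
    # adjust for cell composition only, mirroring an mQTL-database build
    if (!is.null(st$cell_reference[[t]])) {
      cc <- estimate_cell_composition(raw, st$cell_reference[[t]])
      raw <- residualize(raw, as.data.frame(
        cc$fractions[, -ncol(cc$fractions), drop = FALSE]))
    }
    sub <- intersect(bin_subsample(st$annotation, config$bin_size,
                                   config$seed), rownames(raw))
    k_pc <- min(config$n_meth_pcs_mqtl, ncol(raw) - 2L)
    mpc <- meth_pca(raw, sub)$scores[, seq_len(k_pc), drop = FALSE]
    gpc <- stats::prcomp(t(st$genotypes$dosage))$x[
      , seq_len(min(config$n_genetic_pcs,
                    ncol(st$genotypes$dosage) - 1L)), drop = FALSE]
    ind <- sub("_[^_]+$", "", colnames(raw))
    covs <- data.frame(sex = sheet_t$sex,
                       genotyping_batch = sheet_t$genotyping_batch,
                       mpc, gpc[ind, , drop = FALSE])
    covs <- covs[, vapply(covs, function(x)
      is.numeric(x) || length(unique(x)) > 1, logical(1)), drop = FALSE]
    pairs <- enumerate_cis_pairs(st$annotation, st$genotypes,
                                 config$cis_window)
    colnames(raw) <- ind
    st$mqtl <- fit_mqtls(raw, st$genotypes, pairs, covs,
                         report_p = config$report_p)
    st$mqtl_set <- mqtl_cpgs(st$mqtl, config$q_thresh)
    log_msg("[mqtl] %d cis pairs tested, %d reported, %d mQTL CpGs",
            attr(st$mqtl, "n_tests"), nrow(st$mqtl), length(st$mqtl_set))
    data.table::fwrite(as.data.frame(st$mqtl),
                       file.path(out_dir, "mqtl_records.tsv"), sep = "\t")
  }

  if ("enrich" %in% stages && !is.null(st$map)) {
    universe <- st$map$cpg_id[!is.na(st$map$q)]
    corr <- st$map$cpg_id[st$map$significant %in% TRUE]
    st$enrich <- list()
    if (!is.null(st$mqtl_set) && length(corr) && length(st$mqtl_set)) {
      st$enrich$mqtl <- tryCatch(
        mqtl_enrichment(corr, st$mqtl_set, universe, st$annotation,
                        config$bin_size, config$seed, config$yates),
        error = function(e) {
          log_msg("[enrich] mQTL enrichment skipped: %s", conditionMessage(e))
          NULL
        })
      if (!is.null(st$enrich$mqtl))
        log_msg("[enrich] mQTL chi2 = %.2f, p = %.3g",
                st$enrich$mqtl$chi2, st$enrich$mqtl$p)
      st$overlap <- overlap_report(list(correlated = corr,
                                        mqtl = st$mqtl_set))
    }
    if (length(corr) >= 1)
      st$enrich$region <- region_enrichment(corr, universe, st$annotation)
  }

  if ("report" %in% stages) {
    snap <- unclass(config)
    yaml::write_yaml(snap, file.path(out_dir, "resolved_config.yaml"))
    rep <- list(
      n_tested = st$summary$n_tested %||% NA,
      n_significant = st$summary$n_significant %||% NA,
      pct_positive = st$summary$pct_positive %||% NA,
      n_strong = st$summary$n_abs_rho_above_threshold %||% NA,
      crosscheck_frac_both = st$crosscheck$frac_both %||% NA,
      n_mqtl_cpgs = length(st$mqtl_set %||% character()),
      mqtl_enrichment_p = if (!is.null(st$enrich$mqtl)) st$enrich$mqtl$p
                          else NA,
      region_enrichment_p = if (!is.null(st$enrich$region))
        st$enrich$region$p else NA)
    jsonlite::write_json(rep, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_msg("[report] summary written to %s", file.path(out_dir,
                                                        "summary.json"))
  }
  invisible(st)
}
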