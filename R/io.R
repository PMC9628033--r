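#' Read / write beta matrices as TSV
#'
#' Canonical dialect: tab-separated, header row of sample ids, first column
#' `cpg_id`, missing values encoded `NA`. Round trip preserves values to 10
#' significant digits.
#'
#' @param path file path.
#' @return CpG x sample numeric matrix with dimnames.
#' @export
read_beta_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE)
  if (ncol(dt) < 2L) stop("beta TSV needs cpg_id plus sample columns",
                          call. = FALSE)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids))
    stop("duplicate probe id at line ",
         which(duplicated(ids))[1] + 1L, call. = FALSE)
  if (anyDuplicated(names(dt)[-1]))
    stop("duplicate sample id in header", call. = FALSE)
  vals <- dt[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric cells in column(s): ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' @rdname read_beta_tsv
#' @param matrix CpG x sample matrix.
#' @export
write_beta_tsv <- function(matrix, path) {
  stopifnot(is.matrix(matrix))
  dt <- data.table::data.table(cpg_id = rownames(matrix),
                               signif(matrix, 10))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a sample sheet (CSV)
#' @param path CSV file with a `sample_id` column.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!"sample_id" %in% names(df))
    stop("sample sheet needs a sample_id column", call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id", call. = FALSE)
  df
}

#' Read genotypes from dosage TSV or VCF
#'
#' Dosage TSV layout: `snp_id`, `chrom`, `pos`, then one column per sample
#' with dosages in 0/1/2 (`NA` allowed). VCF: bi-allelic records only
#' (multi-allelic records are skipped with a message); GT is converted to
#' the count of alternate alleles, `./.` to missing; positions are the VCF
#' POS (1-based). VCF reading requires the vcfR package.
#'
#' @param path file path.
#' @param format `"dosage_tsv"` or `"vcf"`.
#' @return [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("dosage_tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "dosage_tsv") {
    df <- data.table::fread(path, sep = "\t", data.table = FALSE)
    need <- c("snp_id", "chrom", "pos")
    if (!all(need %in% names(df)))
      stop("dosage TSV needs columns snp_id, chrom, pos", call. = FALSE)
    dose <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
    rownames(dose) <- df$snp_id
    af <- rowMeans(dose, na.rm = TRUE) / 2
    return(genotype_matrix(
      data.frame(snp_id = df$snp_id, chrom = df$chrom, pos = df$pos,
                 freq = af, stringsAsFactors = FALSE), dose))
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF reading requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi))
    message(sum(!bi), " multi-allelic record(s) skipped")
  v <- v[bi, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    sum(strsplit(g, "[/|]")[[1]] == "1")
  })
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  rownames(dose) <- ids
  genotype_matrix(
    data.frame(snp_id = ids, chrom = fix[, "CHROM"],
               pos = as.integer(fix[, "POS"]),
               freq = rowMeans(dose, na.rm = TRUE) / 2,
               stringsAsFactors = FALSE),
    dose)
}

#' @rdname read_genotypes
#' @param genotypes [genotype_matrix()].
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dt <- data.table::data.table(genotypes$info[c("snp_id", "chrom", "pos")],
                               genotypes$dosage)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Minimal VCF export of a genotype matrix
#'
#' Writes a VCFv4.2 file with GT-only genotypes (0/0, 0/1, 1/1, ./.) and
#' placeholder REF/ALT alleles; sufficient for round-tripping dosages.
#'
#' @param genotypes [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(genotypes$dosage)),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  ord <- order(genotypes$info$chrom, genotypes$info$pos)
  for (i in ord) {
    d <- genotypes$dosage[i, ]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    writeLines(paste(c(genotypes$info$chrom[i], genotypes$info$pos[i],
                       genotypes$info$snp_id[i], "A", "G", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write probe annotation TSV
#' @param path file path.
#' @return [probe_annotation()].
#' @export
read_annotation_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  for (f in c("flag_xy", "flag_snp", "flag_multimap"))
    if (f %in% names(df)) df[[f]] <- as.logical(df[[f]])
  probe_annotation(df)
}

#' @rdname read_annotation_tsv
#' @param annotation [probe_annotation()].
#' @export
write_annotation_tsv <- function(annotation, path) {
  data.table::fwrite(as.data.frame(annotation), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}
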