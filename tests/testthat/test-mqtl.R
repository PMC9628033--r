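make_genotypes <- function(pos, dosage, chrom = "chr1") {
  n_snp <- length(pos)
  genotype_matrix(
    data.frame(snp_id = sprintf("snp%03d", seq_len(n_snp)),
               chrom = rep_len(chrom, n_snp), pos = pos,
               freq = rowMeans(dosage) / 2, stringsAsFactors = FALSE),
    dosage)
}

test_that("cis pair enumeration: closed window boundary, chromosomes, oracle", {
  ann <- make_annotation(pos = 2e6, chrom = "chr1")
  dose <- matrix(rep(0:2, 4), 2, 6, byrow = TRUE,
                 dimnames = list(NULL, sprintf("i%d", 1:6)))
  g <- make_genotypes(c(1e6, 3000001), dose)
  pr <- enumerate_cis_pairs(ann, g, window = 1e6)
  expect_equal(nrow(pr), 1)                       # 3,000,001 is 1 bp too far
  expect_equal(pr$distance, -1000000)             # snp - cpg sign convention

  g2 <- make_genotypes(2e6, dose[1, , drop = FALSE], chrom = "chr2")
  expect_equal(nrow(enumerate_cis_pairs(ann, g2)), 0)

  # brute-force double-loop oracle
  set.seed(10)
  ann_b <- make_annotation(pos = sort(sample.int(8e6, 50)))
  pos_s <- sort(sample.int(8e6, 50))
  dose_b <- matrix(rbinom(50 * 8, 2, 0.4), 50, 8,
                   dimnames = list(NULL, sprintf("i%d", 1:8)))
  g_b <- make_genotypes(pos_s, dose_b)
  pr_b <- enumerate_cis_pairs(ann_b, g_b, window = 1e6)
  oracle <- expand.grid(s = seq_len(50), c = seq_len(50))
  oracle <- oracle[abs(pos_s[oracle$s] - ann_b$pos[oracle$c]) <= 1e6, ]
  expect_equal(nrow(pr_b), nrow(oracle))
  key <- paste(pr_b$snp_id, pr_b$cpg_id)
  key_o <- paste(g_b$info$snp_id[oracle$s], ann_b$cpg_id[oracle$c])
  expect_setequal(key, key_o)
})

test_that("mQTL coefficients equal an independent lm() oracle", {
  set.seed(15)
  n <- 60
  ids <- sprintf("i%02d", 1:n)
  dose <- matrix(rbinom(20 * n, 2, 0.3), 20, n, dimnames = list(NULL, ids))
  g <- make_genotypes(seq(1e5, 2e6, length.out = 20), dose)
  betas <- matrix(rnorm(20 * n, 0.5, 0.1), 20, n,
                  dimnames = list(sprintf("cg%05d", 1:20), ids))
  covs <- data.frame(sex = sample(c("F", "M"), n, TRUE), pc1 = rnorm(n))
  pairs <- data.frame(snp_id = g$info$snp_id, cpg_id = rownames(betas),
                      distance = 0L)
  rec <- fit_mqtls(betas, g, pairs, covs, report_p = 1)
  expect_equal(nrow(rec), 20)
  for (k in sample(20, 10)) {
    i <- which(rec$snp_id == g$info$snp_id[k])
    fit <- lm(betas[k, ] ~ dose[k, ] + covs$sex + covs$pc1)
    co <- summary(fit)$coefficients["dose[k, ]", ]
    expect_equal(rec$beta_hat[i], unname(co["Estimate"]), tolerance = 1e-10)
    expect_equal(rec$t_stat[i], unname(co["t value"]), tolerance = 1e-8)
    expect_equal(rec$p[i], unname(co["Pr(>|t|)"]), tolerance = 1e-8)
  }
})

test_that("no-covariate fit matches the closed-form simple-regression t", {
  set.seed(16)
  n <- 40
  ids <- sprintf("i%02d", 1:n)
  dose <- matrix(rbinom(n, 2, 0.4), 1, n, dimnames = list(NULL, ids))
  y <- matrix(rnorm(n), 1, n, dimnames = list("cg1", ids))
  rec <- fit_mqtls(y, make_genotypes(100, dose),
                   data.frame(snp_id = "snp001", cpg_id = "cg1",
                              distance = 0L), report_p = 1)
  r <- cor(dose[1, ], y[1, ])
  t_closed <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(rec$t_stat, t_closed, tolerance = 1e-10)
})

test_that("monomorphic SNPs are skipped and missing dosages handled pairwise", {
  set.seed(17)
  n <- 30
  ids <- sprintf("i%02d", 1:n)
  dose <- rbind(snpA = rbinom(n, 2, 0.4), snpB = rep(0L, n))
  colnames(dose) <- ids
  g <- genotype_matrix(data.frame(snp_id = c("snpA", "snpB"), chrom = "chr1",
                                  pos = c(100, 200), freq = c(0.4, 0)), dose)
  y <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("cg1", "cg2"), ids))
  pairs <- data.frame(snp_id = c("snpA", "snpB"), cpg_id = c("cg1", "cg2"),
                      distance = 0L)
  rec <- fit_mqtls(y, g, pairs, report_p = 1)
  expect_equal(attr(rec, "n_skipped_snps"), 1L)
  expect_equal(rec$snp_id, "snpA")

  # NA dosages: pairwise-complete path agrees with lm on complete cases
  dose_na <- dose; dose_na["snpA", 1:4] <- NA
  g_na <- genotype_matrix(g$info, dose_na)
  rec_na <- fit_mqtls(y, g_na, pairs, report_p = 1)
  ok <- !is.na(dose_na["snpA", ])
  fit <- lm(y[1, ok] ~ dose_na["snpA", ok])
  expect_equal(rec_na$beta_hat[1], unname(coef(fit)[2]), tolerance = 1e-10)
})

test_that("FDR over all tests is consistent with a report_p = 1 run", {
  set.seed(18)
  n <- 50
  ids <- sprintf("i%02d", 1:n)
  dose <- matrix(rbinom(30 * n, 2, 0.3), 30, n, dimnames = list(NULL, ids))
  g <- make_genotypes(seq(1000, 3e6, length.out = 30), dose)
  betas <- matrix(rnorm(30 * n, 0.5, 0.1), 30, n,
                  dimnames = list(sprintf("cg%05d", 1:30), ids))
  pairs <- enumerate_cis_pairs(make_annotation(
    pos = seq(1000, 3e6, length.out = 30)), g, window = 5e5)
  pairs$cpg_id <- sprintf("cg%05d", match(pairs$cpg_id,
                                          make_annotation(
    pos = seq(1000, 3e6, length.out = 30))$cpg_id))
  full <- fit_mqtls(betas, g, pairs, report_p = 1)
  part <- fit_mqtls(betas, g, pairs, report_p = 0.05)
  expect_equal(attr(full, "n_tests"), attr(part, "n_tests"))
  m <- match(paste(part$snp_id, part$cpg_id), paste(full$snp_id, full$cpg_id))
  expect_equal(part$q, full$q[m], tolerance = 1e-12)
})

test_that("null dosage assocations stay small; mqtl_cpgs dedups", {
  set.seed(19)
  n <- 200
  ids <- sprintf("i%03d", 1:n)
  reps <- 300
  tmax <- numeric(reps)
  for (r in seq_len(reps)) {
    dose <- matrix(rbinom(n, 2, 0.3), 1, n, dimnames = list(NULL, ids))
    y <- matrix(rnorm(n), 1, n, dimnames = list("cg1", ids))
    rec <- fit_mqtls(y, make_genotypes(1, dose),
                     data.frame(snp_id = "snp001", cpg_id = "cg1",
                                distance = 0L), report_p = 1)
    tmax[r] <- abs(rec$t_stat)
  }
  expect_gt(mean(tmax < 4), 0.99)

  expect_identical(mqtl_cpgs(data.frame()[0, ]), character())
  rec <- data.frame(snp_id = c("s1", "s2"), cpg_id = c("cgA", "cgA"),
                    q = c(0.01, 0.2))
  expect_identical(mqtl_cpgs(rec), "cgA")
})

test_that("planted genetic effects are recovered near the local beta/logit slope", {
  cfg <- null_config(n_pairs = 500L, n_cpgs = 150L, n_snps = 150L,
                     frac_mqtl = 0.4, mqtl_effect = 0.3, noise_sd = 0.2,
                     maf_range = c(0.3, 0.3), seed = 23L)
  sim <- generate_paired_dataset(cfg)
  planted <- !is.na(sim$truth$mqtl_snp)
  expect_gt(sum(planted), 20)
  buccal <- cbind(sim$betas$buccal_B1, sim$betas$buccal_B2)
  colnames(buccal) <- sub("_[^_]+$", "", colnames(buccal))
  pairs <- data.frame(snp_id = sim$truth$mqtl_snp[planted],
                      cpg_id = sim$truth$cpg_id[planted], distance = 0L)
  rec <- fit_mqtls(buccal, sim$genotypes, pairs, report_p = 1)
  m <- match(rec$cpg_id, sim$truth$cpg_id)
  # expected beta-scale effect: planted logit effect times the local
  # derivative of the logistic at the CpG's mean beta
  mean_beta <- rowMeans(buccal)[rec$cpg_id]
  slope <- mean_beta * (1 - mean_beta)
  expected <- sim$truth$mqtl_beta[m] * slope
  expect_gt(cor(rec$beta_hat, expected), 0.95)
  expect_lt(median(abs(rec$beta_hat - expected) / abs(expected)), 0.35)
})
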