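as_row <- function(x, id = "cg1") matrix(x, 1, length(x),
                                         dimnames = list(id, paste0("i", seq_along(x))))

test_that("spearman map handles monotone and anti-monotone inputs", {
  m <- spearman_map(as_row(1:5), as_row(c(2, 4, 6, 8, 10)))
  expect_equal(m$rho, 1, tolerance = 1e-12)
  expect_lt(m$p, 1e-10)
  m2 <- spearman_map(as_row(1:3), as_row(c(3, 2, 1)))
  expect_equal(m2$rho, -1, tolerance = 1e-12)
  # rows with fewer than 4 complete pairs excluded from the FDR
  b <- rbind(as_row(1:5), cg2 = c(1, 2, NA, NA, NA))
  u <- rbind(as_row(5:1), cg2 = c(2, 1, NA, NA, NA))
  m3 <- spearman_map(b, u)
  expect_true(is.na(m3$p[2]) && is.na(m3$q[2]))
  expect_equal(m3$n[2], 2L)
})

test_that("rho and t-approximation p agree with an exact permutation oracle", {
  x <- c(1, 2, 2, 4, 5, 6, 7)  # one tie
  y <- c(2, 1, 4, 3, 7, 5, 6)
  m <- spearman_map(as_row(x), as_row(y))
  expect_equal(m$rho, naive_spearman(x, y), tolerance = 1e-12)
  # exact two-sided permutation p over all 5040 orderings of y
  perms <- all_perms(7)
  obs <- abs(naive_spearman(x, y))
  null_rho <- apply(perms, 1, function(pm) naive_spearman(x, y[pm]))
  p_exact <- mean(abs(null_rho) >= obs - 1e-12)
  expect_lt(abs(m$p - p_exact), 0.05)
})

test_that("spearman map equals the naive double-loop oracle on a 20x10 matrix", {
  set.seed(20)
  B <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("cg%02d", 1:20), sprintf("i%02d", 1:10)))
  U <- matrix(rnorm(200), 20, 10, dimnames = dimnames(B))
  m <- spearman_map(B, U)
  for (j in 1:20)
    expect_equal(m$rho[m$cpg_id == rownames(B)[j]],
                 naive_spearman(B[j, ], U[j, ]), tolerance = 1e-12)
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(2)
  B <- matrix(runif(150, 0.05, 0.95), 15, 10,
              dimnames = list(sprintf("cg%02d", 1:15), sprintf("i%02d", 1:10)))
  U <- matrix(runif(150, 0.05, 0.95), 15, 10, dimnames = dimnames(B))
  base <- spearman_map(B, U)$rho
  expect_equal(spearman_map(exp(B), U)$rho, base, tolerance = 1e-12)
  expect_equal(spearman_map(B, qlogis(U))$rho, base, tolerance = 1e-12)
})

test_that("unpaired samples are rejected", {
  B <- matrix(0.1, 2, 3, dimnames = list(c("a", "b"),
                                         c("i1_brain", "i2_brain", "i3_brain")))
  U <- matrix(0.1, 2, 3, dimnames = list(c("a", "b"),
                                         c("i1_buccal", "i4_buccal", "i5_buccal")))
  expect_error(spearman_map(B, U), "unpaired")
})

test_that("BH adjustment matches the hand step-up and an independent oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  # frozen hand computation: p = (.01,.02,.03,.04,.05), m = 5
  # q_(i) = min_{j>=i} p_(j)*5/j = 0.05 everywhere
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5),
               tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
  set.seed(6)
  for (i in 1:5) {
    p <- runif(50)
    q <- bh_fdr(p)
    expect_equal(q, hand_bh(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("summary reproduces printed-percentage arithmetic", {
  # published-count arithmetic: 24,636 positive of 24,980 significant
  rec <- data.frame(
    cpg_id = sprintf("cg%07d", 1:30000),
    rho = c(rep(0.6, 24636), rep(-0.6, 344), rep(0.01, 5020)),
    q = c(rep(0.01, 24980), rep(0.5, 5020)))
  rec$p <- rec$q / 10
  rec$significant <- rec$q < 0.05
  s <- summarize_correlations(rec)
  expect_equal(s$n_significant, 24980)
  expect_equal(round(s$pct_positive, 2), 98.62)
  expect_equal(s$pct_positive_rounded, 99)
  expect_equal(s$pct_negative_rounded, 1)
  expect_equal(s$n_abs_rho_above_threshold, 24980)

  # sign splits and the strong-correlation count
  rec2 <- data.frame(cpg_id = c("a", "b", "c"), rho = c(0.6, -0.6, 0.3),
                     q = c(0.01, 0.01, 0.01))
  s2 <- summarize_correlations(rec2)
  expect_equal(s2$n_abs_rho_above_threshold, 2)
  expect_equal(s2$pct_positive, 100 * 2 / 3)
  rec3 <- data.frame(cpg_id = "a", rho = -0.2, q = 0.01)
  expect_equal(summarize_correlations(rec3)$pct_positive, 0)
  # zero significant: undefined markers, not 0/0
  rec4 <- data.frame(cpg_id = "a", rho = 0.2, q = 0.9)
  expect_true(is.na(summarize_correlations(rec4)$pct_positive))
})

test_that("per-batch crosscheck counts replication fractions", {
  all_rec <- data.frame(cpg_id = c("a", "b", "c", "d"),
                        significant = c(TRUE, TRUE, TRUE, FALSE))
  b1 <- data.frame(cpg_id = c("a", "b", "c", "d"), p = c(0.01, 0.2, 0.03, 0.9))
  b2 <- data.frame(cpg_id = c("a", "b", "c", "d"), p = c(0.02, 0.01, 0.9, 0.9))
  cc <- per_batch_crosscheck(all_rec, b1, b2)
  expect_equal(cc$n_significant, 3)
  expect_equal(cc$frac_batch1, 2 / 3)
  expect_equal(cc$frac_both, 1 / 3)
  # identical analyses -> 1; disjoint -> 0
  same <- data.frame(cpg_id = c("a", "b", "c"), p = rep(0.001, 3))
  expect_equal(per_batch_crosscheck(all_rec, same, same)$frac_both, 1)
  none <- data.frame(cpg_id = c("a", "b", "c"), p = rep(0.5, 3))
  expect_equal(per_batch_crosscheck(all_rec, none, none)$frac_both, 0)
})

test_that("batch replication is high for well-powered planted correlation", {
  cfg <- null_config(n_pairs = 100L, n_cpgs = 600L, batch_sizes = c(50L, 50L),
                     frac_correlated = 0.2, frac_negative = 0,
                     rho_target_range = c(0.6, 0.6), seed = 31L)
  sim <- generate_paired_dataset(cfg)
  comb <- function(t) cbind(sim$betas[[paste0(t, "_B1")]],
                            sim$betas[[paste0(t, "_B2")]])
  map_all <- spearman_map(comb("brain"), comb("buccal"))
  m1 <- spearman_map(sim$betas$brain_B1, sim$betas$buccal_B1)
  m2 <- spearman_map(sim$betas$brain_B2, sim$betas$buccal_B2)
  cc <- per_batch_crosscheck(map_all, m1, m2)
  expect_gt(cc$frac_both, 0.8)
})

test_that("adjustment pipeline restores null uniformity under a planted batch shift", {
  cfg <- null_config(n_pairs = 80L, n_cpgs = 2000L, batch_shift = 0.2,
                     covariate_effect_sds = c(cell = 0.4, conversion = 0,
                                              batch = 0.1, diagnosis = 0,
                                              array = 0, position = 0),
                     seed = 41L)
  sim <- generate_paired_dataset(cfg)
  # unadjusted: shared batch + cell confounding inflates small p-values
  comb_raw <- function(t) cbind(sim$betas[[paste0(t, "_B1")]],
                                sim$betas[[paste0(t, "_B2")]])
  raw_p <- spearman_map(comb_raw("brain"), comb_raw("buccal"))$p
  ks_raw <- suppressWarnings(stats::ks.test(raw_p, "punif"))

  adj <- list()
  for (t in c("brain", "buccal")) {
    parts <- lapply(c("B1", "B2"), function(b) {
      m <- sim$betas[[paste0(t, "_", b)]]
      fr <- sim$cell_fractions[[t]][sub("_[^_]+$", "", colnames(m)), 1]
      residualize(m, data.frame(cell = fr))
    })
    adj[[t]] <- combine_and_debatch(parts[[1]], parts[[2]])$betas
  }
  adj_p <- spearman_map(adj$brain, adj$buccal)$p
  ks_adj <- suppressWarnings(stats::ks.test(adj_p, "punif"))
  expect_gt(ks_adj$p.value, 0.01)
  expect_gt(ks_adj$p.value, ks_raw$p.value)
})
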