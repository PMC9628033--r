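test_that("bin subsampling uses 0-based half-open 100 kb bins", {
  ann <- make_annotation(pos = c(10, 50020, 100001))
  sub <- bin_subsample(ann, bin_size = 1e5, seed = 1)
  expect_length(sub, 2)
  # one of the first two CpGs (bin 0) plus the third (bin 1)
  expect_true(sub[1] %in% ann$cpg_id[1:2])
  expect_identical(sub[2], ann$cpg_id[3])

  # singleton bins: identity regardless of seed
  ann1 <- make_annotation(pos = c(5, 100005, 200005))
  expect_identical(bin_subsample(ann1, 1e5, seed = 1),
                   bin_subsample(ann1, 1e5, seed = 99))
  expect_identical(bin_subsample(ann1, 1e5, seed = 1), ann1$cpg_id)

  # determinism under a fixed seed
  dense <- make_annotation(pos = sort(sample.int(1e6, 500)))
  expect_identical(bin_subsample(dense, 1e5, seed = 42),
                   bin_subsample(dense, 1e5, seed = 42))
})

test_that("PCA matches an independent SVD oracle and conserves variance", {
  set.seed(4)
  X <- matrix(rnorm(20), 4, 5,
              dimnames = list(sprintf("cg%d", 1:4), sprintf("s%d", 1:5)))
  p <- meth_pca(X)
  # oracle: eigenvalues of centered cross-product via svd
  Xc <- scale(t(X), center = TRUE, scale = FALSE)
  ev_oracle <- svd(Xc)$d^2 / (nrow(Xc) - 1)
  expect_equal(unname(p$eigenvalues[seq_along(ev_oracle)]),
               ev_oracle, tolerance = 1e-8)
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  expect_equal(unname(colMeans(p$scores)), rep(0, ncol(p$scores)),
               tolerance = 1e-10)

  # two samples -> exactly one nonzero eigenvalue
  p2 <- meth_pca(X[, 1:2])
  expect_equal(sum(p2$eigenvalues > 1e-12), 1)

  expect_error(meth_pca(matrix(0.5, 4, 5)), "constant")
})

test_that("PC selection by cumulative variance and fixed count", {
  p <- structure(list(eigenvalues = c(5, 3, 1, 1),
                      variance_explained = c(0.5, 0.3, 0.1, 0.1)),
                 class = "meth_pca")
  expect_equal(select_pcs(p, "cumvar", frac = 0.8)$n_selected, 2L)
  expect_equal(select_pcs(p, "fixed", k = 3)$n_selected, 3L)
  expect_equal(select_pcs(p, "cumvar", frac = 1.0)$n_selected, 4L)
  expect_error(select_pcs(p, "nope"), "arg")
})

test_that("covariate screen: identity, closed-form ANOVA, skip rules", {
  set.seed(8)
  X <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(sprintf("cg%02d", 1:50), sprintf("s%02d", 1:12)))
  p <- select_pcs(meth_pca(X), "fixed", k = 2)

  sheet <- data.frame(sample_id = colnames(X),
                      cov_pc1 = p$scores[, 1],
                      constant = 1,
                      single = "only")
  res <- suppressWarnings(
    screen_covariates(p, sheet, c("cov_pc1", "constant", "single")))
  expect_true("cov_pc1" %in% res$flagged)
  r1 <- res$table$statistic[res$table$covariate == "cov_pc1" &
                            res$table$pc == 1]
  expect_equal(r1, 1, tolerance = 1e-12)
  expect_false(any(c("constant", "single") %in% res$table$covariate))

  # hand-computed one-way ANOVA oracle: groups (1,2,3) vs (2,3,4)
  # SSB = 1.5 (MSB 1.5), SSW = 4 (MSW 1) -> F = 1.5 on (1,4) df
  scores <- matrix(c(1, 2, 3, 2, 3, 4), ncol = 1)
  fake <- structure(list(scores = scores, eigenvalues = 1,
                         variance_explained = 1, n_selected = 1L),
                    class = "meth_pca")
  grp <- data.frame(g = rep(c("a", "b"), each = 3))
  res2 <- screen_covariates(fake, grp, "g")
  expect_equal(res2$table$statistic, 1.5, tolerance = 1e-12)
  expect_equal(res2$table$p, pf(1.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("screen type-I error matches the per-test alpha under the null", {
  # 300 replicates of an independent covariate against k = 2 PCs:
  # flag probability should be close to 1 - (1 - alpha)^2
  set.seed(301)
  k <- 2L; n <- 40L; reps <- 300L
  X <- matrix(rnorm(60 * n), 60, n,
              dimnames = list(NULL, sprintf("s%02d", 1:n)))
  p <- select_pcs(meth_pca(X), "fixed", k = k)
  hits <- 0L
  for (i in seq_len(reps)) {
    sheet <- data.frame(z = rnorm(n))
    res <- screen_covariates(p, sheet, "z", alpha = 0.01)
    hits <- hits + length(res$flagged)
  }
  expected <- 1 - (1 - 0.01)^k
  se <- sqrt(expected * (1 - expected) / reps)
  expect_lt(hits / reps, expected + 4 * se + 0.01)
})

test_that("residualization: hand OLS example, orthogonality, projection", {
  batch <- rep(c("b1", "b2"), each = 4)
  beta <- matrix(0.5 + 0.1 * (batch == "b2"), 1, 8,
                 dimnames = list("cg1", sprintf("s%d", 1:8)))
  adj <- residualize(beta, data.frame(batch = batch))
  expect_equal(unname(adj[1, ]), rep(0.55, 8), tolerance = 1e-12)

  # empty design is the identity
  expect_identical(residualize(beta, data.frame()), beta)

  # orthogonality to removed numeric covariates; idempotence
  set.seed(12)
  Y <- matrix(rnorm(30 * 16), 30, 16)
  des <- data.frame(x = rnorm(16), g = rep(c("u", "v"), 8))
  A1 <- residualize(Y, des)
  for (j in 1:30)
    expect_lt(abs(cor(A1[j, ], des$x)), 1e-10)
  A2 <- residualize(A1, des)
  expect_equal(A2, A1, tolerance = 1e-10)

  # rank deficiency names the aliased term
  bad <- data.frame(x = rnorm(16))
  bad$y <- 2 * bad$x
  expect_error(residualize(Y, bad), "aliased.*y")
})

test_that("residualization agrees with limma's batch-removal on shared cases", {
  skip_if_not_installed("limma")
  set.seed(91)
  Y <- matrix(rnorm(25 * 14, 0.5, 0.1), 25, 14)
  batch <- rep(c("b1", "b2"), each = 7)
  # residualize centers numeric covariates to keep the grand mean;
  # removeBatchEffect subtracts them as-is, so hand it the centered version
  x <- as.numeric(scale(rnorm(14), scale = FALSE))
  ours <- residualize(Y, data.frame(batch = batch, x = x))
  theirs <- limma::removeBatchEffect(Y, batch = batch,
                                     covariates = cbind(x = x))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("combining batches removes a planted mean shift", {
  set.seed(3)
  b1 <- matrix(rnorm(40 * 10, 0.5, 0.05), 40, 10,
               dimnames = list(sprintf("cg%02d", 1:40), sprintf("a%d", 1:10)))
  b2 <- matrix(rnorm(40 * 12, 0.55, 0.05), 40, 12,
               dimnames = list(rownames(b1), sprintf("b%d", 1:12)))
  res <- combine_and_debatch(b1, b2)
  expect_equal(ncol(res$betas), 22)
  d <- rowMeans(res$betas[, 1:10]) - rowMeans(res$betas[, 11:22])
  expect_equal(unname(d), rep(0, 40), tolerance = 1e-10)

  expect_error(combine_and_debatch(b1, b2[, 0]), "at least one sample")
  expect_error(combine_and_debatch(b1[1:10, ], b2), "probe sets differ")
})

test_that("direct PC adjustment orthogonalizes against the removed scores", {
  set.seed(77)
  n <- 24
  ann <- make_annotation(pos = sort(sample.int(3e6, 200)))
  # planted rank-1 confounder
  f <- rnorm(n)
  X <- outer(rnorm(200, 0, 0.3), f) + matrix(rnorm(200 * n, 0, 0.1), 200, n)
  dimnames(X) <- list(ann$cpg_id, sprintf("s%02d", 1:n))

  expect_identical(direct_pc_adjust(X, ann, k = 0), X)
  expect_error(direct_pc_adjust(X, ann, k = -1), ">= 0")
  expect_error(direct_pc_adjust(X, ann, k = n), "n_samples - 1")

  adj <- direct_pc_adjust(X, ann, k = 2, seed = 5)
  sub <- intersect(bin_subsample(ann, 1e5, seed = 5), rownames(X))
  sc <- meth_pca(X, sub)$scores[, 1:2]
  for (i in 1:2) {
    cors <- abs(apply(adj, 1, cor, y = sc[, i]))
    expect_lt(max(cors, na.rm = TRUE), 1e-8)
  }
})
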