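# Shared fixtures and small independent oracles, all built in code.

tiny_config <- function(...) {
  args <- utils::modifyList(list(
    n_pairs = 30L, n_cpgs = 300L, n_snps = 80L,
    chrom_lengths = c(chr1 = 5e6, chr2 = 4e6),
    seed = 11L), list(...))
  do.call(sim_config, args)
}

# a config with every confounder and planted signal switched off
null_config <- function(...) {
  base <- list(
    frac_correlated = 0, frac_mqtl = 0, batch_shift = 0,
    covariate_effect_sds = c(cell = 0, conversion = 0, batch = 0,
                             diagnosis = 0, array = 0, position = 0))
  do.call(tiny_config, utils::modifyList(base, list(...)))
}

make_annotation <- function(pos, chrom = "chr1", region = "Body",
                            flag_xy = FALSE, flag_snp = FALSE,
                            flag_multimap = FALSE) {
  n <- length(pos)
  probe_annotation(data.frame(
    cpg_id = sprintf("cg%05d", seq_len(n)), chrom = rep_len(chrom, n),
    pos = pos, region = rep_len(region, n),
    flag_xy = rep_len(flag_xy, n), flag_snp = rep_len(flag_snp, n),
    flag_multimap = rep_len(flag_multimap, n), stringsAsFactors = FALSE))
}

# all permutations of 1..n (for the exact Spearman null)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    out[rows, -1] <- ifelse(sub >= i, sub + 1L, sub)
  }
  out
}

# naive double-loop Spearman (rank + Pearson), the independent oracle
naive_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# independent hand implementation of the BH step-up
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}
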