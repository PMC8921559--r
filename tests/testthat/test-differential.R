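make_pm <- function(values, n_pairs, libsizes = NULL) {
  samples <- as.vector(t(outer(sprintf("P%02d", seq_len(n_pairs)),
                               c("T", "N"), paste, sep = "_")))
  colnames(values) <- samples
  paired_matrix(values, sub("_[TN]$", "", samples),
                ifelse(grepl("_T$", samples), "tumor", "normal"),
                libsizes)
}

test_that("FPM normalization follows count / library * 1e6", {
  cnt <- matrix(c(0, 10, 50), 3, 2,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  ls <- c(s1 = 1e6, s2 = 2e6)
  f <- fpm(cnt, ls)
  expect_equal(unname(f[, "s1"]), c(0, 10, 50))
  expect_equal(unname(f[, "s2"]), c(0, 5, 25))
  expect_equal(log2p1(f["a", "s1"]), 0)
  expect_error(fpm(cnt, c(s1 = 0, s2 = 2e6)), "library size")
})

test_that("paired_matrix rejects unpaired designs", {
  v <- matrix(1, 1, 4, dimnames = list("f", paste0("s", 1:4)))
  expect_error(paired_matrix(v, c("P1", "P1", "P2", "P2"),
                             c("tumor", "tumor", "tumor", "normal")),
               "unpaired")
  expect_silent(paired_matrix(v, c("P1", "P1", "P2", "P2"),
                              c("tumor", "normal", "tumor", "normal")))
})

test_that("paired t matches the textbook computation on a 5-pair toy", {
  tumor <- c(5.1, 6.3, 4.8, 7.0, 5.9)
  normal <- c(4.0, 5.1, 4.9, 5.5, 5.0)
  v <- matrix(as.vector(rbind(tumor, normal)), 1, 10)
  pm <- make_pm(v, 5)
  res <- paired_diff_test(pm, transform = "identity")
  want <- t.test(tumor, normal, paired = TRUE)
  expect_equal(res$t, unname(want$statistic), tolerance = 1e-10)
  expect_equal(res$p, want$p.value, tolerance = 1e-10)
  expect_equal(res$effect, mean(tumor - normal), tolerance = 1e-12)
})

test_that("degenerate paired differences map to p in {0,1}", {
  v <- rbind(c(1, 1, 2, 2, 3, 3),            # identical tumor/normal
             c(2, 1, 3, 2, 4, 3))            # constant nonzero diff
  pm <- make_pm(v, 3)
  expect_message(res <- paired_diff_test(pm, transform = "identity"),
                 "zero-variance")
  expect_equal(res$effect[1], 0)
  expect_equal(res$p[1], 1)
  expect_equal(res$p[2], 0)
})

test_that("BH adjustment matches the step-up computation by hand", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # monotone non-decreasing in sorted-p order and order-invariant
  set.seed(1)
  p <- runif(30)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  perm <- sample(30)
  expect_equal(bh_fdr(p[perm]), q[perm])
})

test_that("DEE/DEG thresholds are strict and direction-labelled", {
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    effect = c(0.6, 0.5, -0.7, 1.2),
                    p = c(0.001, 0.001, 0.002, 1e-7),
                    fdr = c(0.01, 0.01, 0.04, 1e-6),
                    direction = c("up", "up", "down", "up"))
  dee <- call_dee(res)
  expect_setequal(dee$feature_id, c("a", "c", "d"))
  expect_equal(dee$status[dee$feature_id == "a"], "activated")
  expect_equal(dee$status[dee$feature_id == "c"], "repressed")
  # effect exactly at the threshold is not called
  expect_false("b" %in% dee$feature_id)
  deg <- call_deg(res)
  expect_equal(deg$status[deg$feature_id == "d"], "up")
  # stricter modifier screen at |LFC| > 1
  res2 <- data.frame(feature_id = c("m1", "m2"),
                     effect = c(-1.3, -0.4), p = c(1e-4, 1e-4),
                     fdr = c(0.01, 0.01), direction = "down")
  expect_equal(call_deg(res2, lfc = 1)$feature_id, "m1")
  expect_false("m2" %in% call_deg(res2)$feature_id)
})

test_that("DML runs form DMRs under the gap and count rules", {
  n_pairs <- 8
  mk_beta <- function(pos, delta) {
    nc <- length(pos)
    normal <- matrix(0.5, nc, n_pairs)
    tumor <- normal + delta + matrix(rnorm(nc * n_pairs, 0, 0.01), nc)
    v <- matrix(0, nc, 2 * n_pairs)
    v[, seq(1, 2 * n_pairs, 2)] <- tumor
    v[, seq(2, 2 * n_pairs, 2)] <- normal
    v
  }
  # 8 consecutive hypo DMLs, 100 bp apart -> one hypo DMR of 8 CpGs
  pos <- seq(1000, by = 100, length.out = 8)
  pm <- make_pm(mk_beta(pos, -0.3), n_pairs)
  res <- call_dml_dmr(pm, data.frame(cpg_id = seq_along(pos),
                                     chrom = "chr1", pos = pos))
  expect_equal(nrow(res$dmr), 1L)
  expect_equal(res$dmr$n_cpgs, 8L)
  expect_equal(res$dmr$direction, "hypo")
  expect_equal(res$dmr$start, 1000L)
  expect_equal(res$dmr$end, 1701L)
  expect_lt(res$dmr$mean_delta, -0.25)

  # 4 DMLs only: below min_cpgs, no DMR
  pos4 <- seq(1000, by = 100, length.out = 4)
  pm4 <- make_pm(mk_beta(pos4, 0.3), n_pairs)
  res4 <- call_dml_dmr(pm4, data.frame(cpg_id = 1:4, chrom = "chr1",
                                       pos = pos4))
  expect_equal(nrow(res4$dmr), 0L)

  # a 600 bp gap splits 10 DMLs into 5 + 5 -> two DMRs
  pos10 <- c(seq(1000, by = 100, length.out = 5),
             seq(2000, by = 100, length.out = 5))
  pm10 <- make_pm(mk_beta(pos10, 0.3), n_pairs)
  res10 <- call_dml_dmr(pm10, data.frame(cpg_id = 1:10, chrom = "chr1",
                                         pos = pos10))
  expect_equal(nrow(res10$dmr), 2L)
  expect_equal(res10$dmr$n_cpgs, c(5L, 5L))

  # unsorted positions are rejected
  expect_error(call_dml_dmr(pm4, data.frame(cpg_id = 1:4, chrom = "chr1",
                                            pos = rev(pos4))),
               "sorted")
})

test_that("DMR caller agrees with a brute-force scan on random DML sets", {
  set.seed(11)
  n_pairs <- 10
  for (rep in 1:10) {
    n <- 40
    pos <- sort(sample(0:9000, n))
    delta <- sample(c(-0.3, 0, 0.3), n, replace = TRUE,
                    prob = c(0.4, 0.2, 0.4))
    normal <- matrix(0.5, n, n_pairs)
    tumor <- normal + delta + matrix(rnorm(n * n_pairs, 0, 0.005), n)
    v <- matrix(0, n, 2 * n_pairs)
    v[, seq(1, 2 * n_pairs, 2)] <- tumor
    v[, seq(2, 2 * n_pairs, 2)] <- normal
    pm <- make_pm(v, n_pairs)
    res <- call_dml_dmr(pm, data.frame(cpg_id = 1:n, chrom = "chr1",
                                       pos = pos))
    dml <- res$dml[res$dml$is_dml, ]
    want <- oracle_dmr_scan(dml$pos,
                            ifelse(dml$effect > 0, "hyper", "hypo"))
    expect_equal(res$dmr$start, want$start)
    expect_equal(res$dmr$end, want$end)
    expect_equal(res$dmr$n_cpgs, want$n)
  }
})

test_that("planted effects are recovered with controlled error rates", {
  # sensitivity under the planted-effect regime (n = 30 pairs, |LFC| = 2)
  cfg <- sim_config(seed = 31, n_pairs_rnaseq = 30L)
  sim <- simulate_dataset(cfg)
  fp <- fpm(sim$expression$erna_counts, sim$expression$library_sizes)
  dee <- call_dee(paired_diff_test(
    as_paired_matrix(fp, sim$expression$sample_info)))
  sens <- mean(sim$truth$dee$enh_id %in% dee$feature_id)
  fdr_hat <- mean(!dee$feature_id %in% sim$truth$dee$enh_id)
  expect_gte(sens, 0.90)
  expect_lte(fdr_hat, 0.10)
})

test_that("type-I error is near nominal on null expression data", {
  cfg <- sim_config(seed = 32, n_chroms = 2L, chrom_length = 2e7,
                    n_genes = 600L, n_enhancers = 60L,
                    n_pairs_rnaseq = 30L, planted_deg_frac = 0,
                    planted_dee_frac = 0, planted_dmr_frac = 0)
  sim <- simulate_dataset(cfg)
  gf <- fpm(sim$expression$gene_counts, sim$expression$library_sizes)
  res <- paired_diff_test(as_paired_matrix(gf, sim$expression$sample_info))
  alpha_hat <- mean(res$p < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_gte(alpha_hat, 0.05 - 2 * se)
  expect_lte(alpha_hat, 0.05 + 2 * se)
  # and essentially no DEG calls after BH + effect gates
  expect_lte(nrow(call_deg(res)), 2L)
})

test_that("null methylation yields (almost) no DMR calls", {
  cfg <- sim_config(seed = 33, effect_dmeth = 0)
  sim <- simulate_dataset(cfg)
  pm <- as_paired_matrix(sim$methylation$beta,
                         sim$methylation$sample_info)
  res <- call_dml_dmr(pm, sim$methylation$cpgs[, c("cpg_id", "chrom",
                                                   "pos")])
  expect_lte(nrow(res$dmr), 1L)
})
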