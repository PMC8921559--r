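test_that("spearman_cor matches the rank formula, ties included", {
  x <- 1:8
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  # 6-point toy with one tie, against the averaged-rank formula
  xt <- c(1, 2, 2, 3, 4, 5)
  yt <- c(2.3, 1.1, 4.0, 3.2, 5.5, 4.9)
  got <- spearman_cor(xt, yt)
  want <- oracle_spearman(xt, yt)
  expect_equal(got$rho, want$rho, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  # and against cor.test's rho
  expect_equal(got$rho,
               unname(suppressWarnings(
                 cor.test(xt, yt, method = "spearman")$estimate)),
               tolerance = 1e-12)
  expect_message(cz <- spearman_cor(rep(1, 6), yt), "constant")
  expect_equal(cz, list(rho = 0, p = 1))
})

# shared toy for intergenic linking: 2 DEEs, 3 DEGs on one chromosome
toy_link_setup <- function() {
  enh <- data.frame(enh_id = c("E1", "E2"), chrom = "chr1",
                    start = c(100000L, 5000000L),
                    end = c(101000L, 5001000L))
  genes <- toy_genes(
    list("G1", "chr1", "+", 200000, 210000),     # 99.5 kb from E1 center
    list("G2", "chr1", "+", 1000000, 1010000),   # 899.5 kb from E1 center
    list("G3", "chr1", "+", 1800000, 1810000))   # 1.2995 Mb from E1 center
  set.seed(1)
  n <- 20
  base <- rnorm(n)
  erna <- rbind(E1 = base + rnorm(n, 0, 0.1),
                E2 = rnorm(n))
  gexp <- rbind(G1 = base + rnorm(n, 0, 0.1),   # strongly linked to E1
                G2 = rnorm(n),                  # unlinked
                G3 = base)                      # correlated but too far
  colnames(erna) <- colnames(gexp) <- paste0("s", 1:n)
  dee <- data.frame(feature_id = c("E1", "E2"),
                    status = "activated", effect = 1, fdr = 0.001)
  deg <- data.frame(feature_id = c("G1", "G2", "G3"), status = "up",
                    effect = 1, fdr = 0.001)
  list(enh = enh, genes = genes, erna = erna, gexp = gexp, dee = dee,
       deg = deg)
}

test_that("intergenic links obey the distance, rho and Bonferroni gates", {
  s <- toy_link_setup()
  out <- link_intergenic(s$dee, s$deg, s$erna, s$gexp, s$enh, s$genes)
  # G3 at 1.2995 Mb is never tested
  expect_false("G3" %in% out$tested$gene_id)
  # candidates: E1-G1, E1-G2 (within 1 Mb), E2-G2/G3? E2 center 5000500
  expect_true(all(abs(out$tested$distance) <= 1e6))
  # retained: only the planted E1-G1
  expect_equal(nrow(out$links), 1L)
  expect_equal(out$links$enhancer_id, "E1")
  expect_equal(out$links$gene_id, "G1")
  # Bonferroni with family = all tested candidates, by hand
  m <- out$n_tested
  i <- match(paste("E1", "G1"),
             paste(out$tested$enhancer_id, out$tested$gene_id))
  expect_equal(out$tested$p_adj[i], min(1, m * out$tested$p[i]))
  # rho below 0.7 is rejected regardless of p
  hi <- out$tested
  expect_true(all(out$links$rho >= 0.7))
})

test_that("rho = 0.69 fails and the boundary is strict on p only", {
  # construct vectors with known spearman rho just below / above 0.7
  set.seed(2)
  n <- 40
  x <- 1:n
  make_rho <- function(target) {
    for (f in seq(0.1, 3, 0.01)) {
      y <- x + f * sample(n)
      if (spearman_cor(x, y, quiet = TRUE)$rho < target) return(y)
    }
  }
  y_low <- make_rho(0.695)
  rho_low <- spearman_cor(x, y_low)$rho
  expect_lt(rho_low, 0.7)
  enh <- data.frame(enh_id = "E1", chrom = "chr1", start = 1000L,
                    end = 2000L)
  genes <- toy_genes(list("G1", "chr1", "+", 50000, 60000))
  erna <- matrix(x, 1, dimnames = list("E1", paste0("s", 1:n)))
  gexp <- matrix(y_low, 1, dimnames = list("G1", paste0("s", 1:n)))
  dee <- data.frame(feature_id = "E1", status = "activated")
  deg <- data.frame(feature_id = "G1", status = "up")
  out <- link_intergenic(dee, deg, erna, gexp, enh, genes)
  expect_equal(nrow(out$links), 0L)   # despite p ~ 0
  expect_lt(out$tested$p_adj, 0.01)
})

test_that("no shared samples raises an error", {
  s <- toy_link_setup()
  gexp2 <- s$gexp
  colnames(gexp2) <- paste0("z", seq_len(ncol(gexp2)))
  expect_error(link_intergenic(s$dee, s$deg, s$erna, gexp2, s$enh,
                               s$genes), "shared samples")
})

test_that("genic DME candidate gates follow the overlap criteria", {
  catalog <- data.frame(
    chrom = "chr1", start = c(10000L, 20000L, 30000L, 40000L),
    end = c(10700L, 20500L, 30700L, 40700L),
    enhancer_id = c("enh1", "enh2", "enh3", "enh4"),
    concurrence = c(3L, 3L, 1L, 3L), class = "genic")
  # enh1: overlap 250 bp hyper DMR, >= 5 CpGs -> candidate
  # enh2: overlap 150 bp -> fails min_overlap
  # enh3: concurrence 1 -> fails
  # enh4: overlap 250 bp but only 4 CpGs inside -> fails
  dmrs <- data.frame(chrom = "chr1",
                     start = c(10000L, 20000L, 30000L, 40000L),
                     end = c(10250L, 20150L, 30250L, 40250L),
                     direction = c("hyper", "hypo", "hypo", "hypo"))
  cpgs <- data.frame(chrom = "chr1",
                     pos = c(seq(10010, 10240, 40),
                             seq(20010, 20140, 30),
                             seq(30010, 30240, 40),
                             seq(40010, 40130, 40)))
  genes <- toy_genes(list("G1", "chr1", "+", 60000, 70000))
  n <- 20
  set.seed(3)
  base <- rnorm(n)
  samples <- paste0("s", 1:n)
  beta <- matrix(rep(0.5 + 0.05 * base, each = nrow(cpgs)),
                 nrow(cpgs), n, dimnames = list(NULL, samples))
  gexp <- matrix(base, 1, dimnames = list("G1", samples))
  deg <- data.frame(feature_id = "G1", status = "up")
  out <- link_genic_dme(catalog, dmrs, cpgs, deg, beta, gexp, genes)
  expect_equal(out$dme$enhancer_id, "enh1")
  expect_equal(out$dme$dmr_direction, "hyper")
  expect_gte(out$dme$overlap_bp, 200)
  expect_gte(out$dme$overlap_fraction, 0.3)
  expect_gte(out$dme$n_cpgs_overlap, 5)
  expect_equal(out$links$gene_id, "G1")
})

test_that("genic DME links accept negative correlations (|rho| gate)", {
  catalog <- data.frame(chrom = "chr1", start = 10000L, end = 10700L,
                        enhancer_id = "enh1", concurrence = 2L,
                        class = "genic")
  dmrs <- data.frame(chrom = "chr1", start = 10000L, end = 10700L,
                     direction = "hypo")
  cpgs <- data.frame(chrom = "chr1", pos = seq(10010, 10690, 50))
  genes <- toy_genes(list("G1", "chr1", "+", 60000, 70000))
  n <- 20
  set.seed(4)
  base <- rnorm(n)
  samples <- paste0("s", 1:n)
  beta <- matrix(rep(0.5 + 0.05 * base, each = nrow(cpgs)), nrow(cpgs),
                 n, dimnames = list(NULL, samples))
  gexp <- matrix(-base + rnorm(n, 0, 0.05), 1,
                 dimnames = list("G1", samples))
  deg <- data.frame(feature_id = "G1", status = "down")
  out <- link_genic_dme(catalog, dmrs, cpgs, deg, beta, gexp, genes)
  expect_equal(nrow(out$links), 1L)
  expect_lt(out$links$rho, -0.5)
  expect_equal(classify_dme_deg(out$links$dmr_direction,
                                out$links$deg_direction), "HypoDown")
})

test_that("DME-DEG categories cross methylation and expression direction", {
  expect_equal(classify_dme_deg("hyper", "up"), "HyperUp")
  expect_equal(classify_dme_deg("hyper", "down"), "HyperDown")
  expect_equal(classify_dme_deg("hypo", "up"), "HypoUp")
  expect_equal(classify_dme_deg("hypo", "down"), "HypoDown")
  expect_equal(classify_dme_deg(c("hyper", "hypo"), c("down", "down")),
               c("HyperDown", "HypoDown"))
  expect_error(classify_dme_deg("other", "up"), "hyper")
  expect_error(classify_dme_deg("hyper", "sideways"), "up")
})

test_that("methylation-associated DEEs need a DMR and a correlation", {
  sim <- sim_cache()
  fp <- fpm(sim$expression$erna_counts, sim$expression$library_sizes)
  dee <- call_dee(paired_diff_test(
    as_paired_matrix(fp, sim$expression$sample_info)))
  pmb <- as_paired_matrix(sim$methylation$beta,
                          sim$methylation$sample_info)
  dmr <- call_dml_dmr(pmb, sim$methylation$cpgs[, c("cpg_id", "chrom",
                                                    "pos")])$dmr
  ma <- methylation_associated_dees(dee, sim$genome$template, dmr,
                                    sim$methylation$cpgs,
                                    sim$methylation$beta, log2p1(fp))
  expect_true(all(ma$flagged$feature_id %in% dee$feature_id))
  expect_gte(ma$frac_dees, 0)
  expect_lte(ma$frac_dees, 1)
  # every planted methylation-driven DEE that was called is flagged
  planted <- sim$truth$dmrs$target_enh[sim$truth$dmrs$kind == "dee_meth"]
  called <- intersect(planted, dee$feature_id)
  expect_true(all(called %in% ma$flagged$feature_id))
  # DEEs without any DMR overlap are never flagged
  no_dmr <- methylation_associated_dees(dee, sim$genome$template,
                                        dmr[0, ], sim$methylation$cpgs,
                                        sim$methylation$beta, log2p1(fp))
  expect_equal(nrow(no_dmr$flagged), 0L)
})

test_that("modifier coexpression counts |rho| > 0.5 significant features", {
  set.seed(5)
  n <- 30
  samples <- paste0("s", 1:n)
  mod <- rnorm(n)
  gexp <- rbind(MOD = mod,
                DEG1 = mod,              # identical -> counted
                DEG2 = rnorm(n))         # noise -> not counted
  erna <- rbind(E1 = mod + rnorm(n, 0, 0.05), E2 = rnorm(n),
                E3 = rnorm(n))
  colnames(gexp) <- colnames(erna) <- samples
  out <- modifier_coexpression("MOD", c("E1", "E2", "E3"),
                               c("DEG1", "DEG2"), erna, gexp)
  expect_equal(out$frac_dees, 1 / 3)
  expect_equal(out$frac_deg_links, 1 / 2)
  # order invariance
  out2 <- modifier_coexpression("MOD", c("E3", "E2", "E1"),
                                c("DEG2", "DEG1"), erna, gexp)
  expect_equal(out2$frac_dees, out$frac_dees)
  expect_error(modifier_coexpression("ABSENT", "E1", "DEG1", erna, gexp),
               "ABSENT")
})

test_that("a pure-noise modifier associates with ~no features", {
  sim <- sim_cache()
  fp <- log2p1(fpm(sim$expression$erna_counts,
                   sim$expression$library_sizes))
  gf <- log2p1(fpm(sim$expression$gene_counts,
                   sim$expression$library_sizes))
  set.seed(6)
  noise <- matrix(rnorm(ncol(gf)), 1, dimnames = list("NOISE",
                                                      colnames(gf)))
  gf2 <- rbind(gf, noise)
  out <- modifier_coexpression("NOISE", rownames(fp)[1:100],
                               rownames(gf)[1:50], fp, gf2)
  expect_lte(out$frac_dees, 0.02)
})

test_that("super-enhancer chains respect gap, sharing and thresholds", {
  # 7 repressed DEEs, 10 kb apart, all linked to 6 genes -> one cluster
  enh <- data.frame(enh_id = sprintf("E%02d", 1:7), chrom = "chr16",
                    start = seq(56520000, by = 10000, length.out = 7),
                    end = seq(56521000, by = 10000, length.out = 7))
  dee <- data.frame(feature_id = enh$enh_id, status = "repressed")
  links <- expand.grid(enhancer_id = enh$enh_id,
                       gene_id = sprintf("MT%d", 1:6),
                       stringsAsFactors = FALSE)
  out <- detect_super_enhancer_clusters(links, enh, dee)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_dees, 7L)
  expect_equal(out$n_degs, 6L)
  # 4 chained DEEs stay unreported
  out4 <- detect_super_enhancer_clusters(
    links[links$enhancer_id %in% enh$enh_id[1:4], ], enh, dee)
  expect_equal(nrow(out4), 0L)
  # a 200 kb gap splits the chain into two separately evaluated parts
  enh2 <- enh
  enh2$start[5:7] <- enh2$start[5:7] + 200000L
  enh2$end[5:7] <- enh2$end[5:7] + 200000L
  out_split <- detect_super_enhancer_clusters(links, enh2, dee)
  expect_equal(nrow(out_split), 0L)  # 4 + 3 members, both below 5
  # an opposite-direction member is excluded from the chain
  dee_mix <- dee
  dee_mix$status[4] <- "activated"
  out_mix <- detect_super_enhancer_clusters(links, enh, dee_mix)
  expect_equal(out_mix$n_dees, 6L)
  expect_false(grepl("E04", out_mix$dee_ids))
  # strict mode: genes linked to every member only
  links_strict <- links[!(links$enhancer_id == "E03" &
                            links$gene_id == "MT1"), ]
  s_loose <- detect_super_enhancer_clusters(links_strict, enh, dee)
  s_strict <- detect_super_enhancer_clusters(links_strict, enh, dee,
                                             strict = TRUE)
  expect_equal(s_loose$n_degs, 6L)
  expect_equal(s_strict$n_degs, 5L)
})

test_that("synthetic linking keeps >= 95% precision for planted links", {
  sim <- sim_cache()
  fp <- fpm(sim$expression$erna_counts, sim$expression$library_sizes)
  gf <- fpm(sim$expression$gene_counts, sim$expression$library_sizes)
  dee <- call_dee(paired_diff_test(
    as_paired_matrix(fp, sim$expression$sample_info)))
  deg <- call_deg(paired_diff_test(
    as_paired_matrix(gf, sim$expression$sample_info)))
  out <- link_intergenic(dee, deg, log2p1(fp), log2p1(gf),
                         sim$genome$template, sim$genome$genes)
  got <- paste(out$links$enhancer_id, out$links$gene_id)
  planted <- paste(sim$truth$links$enh_id, sim$truth$links$gene_id)
  expect_gt(nrow(out$links), 5)
  expect_gte(mean(got %in% planted), 0.95)
  # all links respect the same-chromosome consequence of the gate
  ei <- match(out$links$enhancer_id, sim$genome$template$enh_id)
  gi <- match(out$links$gene_id, sim$genome$genes$gene_id)
  expect_true(all(sim$genome$template$chrom[ei] ==
                    sim$genome$genes$chrom[gi]))
  # median realized correlation of tested planted links is high
  tst <- paste(out$tested$enhancer_id, out$tested$gene_id)
  expect_gte(median(out$tested$rho[tst %in% planted]), 0.7)
})
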