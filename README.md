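# enhancerAE

Integrative identification of **aberrant enhancers** and their target
genes in paired tumor/normal cohorts, with a six-gene prognostic risk
score. The package is aimed at computational biologists working with
matched histone ChIP-seq, RNA-seq and whole-genome bisulfite data who
want a self-contained, fully testable implementation of the analysis
chain from per-sample peak files to survival stratification.

## What it computes

1. **Enhancer catalog** — per-sample H3K4me1 peaks are classified
   *active* (overlapping H3K27ac) or *primed*, chromatin-state calls
   are ingested alongside, and everything is union-merged into a
   catalog of non-overlapping enhancers. Each merged enhancer carries
   its *concurrence* (number of supporting samples) and is partitioned
   into genic/intergenic; intervals < 50 bp or overlapping a promoter
   (TSS −1,500 bp / +500 bp, strand-aware) are removed.
2. **Differential calling** — paired t-tests on log2(FPM + 1) for eRNA
   and genes (DEE/DEG at |log2FC| > 0.5, BH-FDR < 0.05) and on
   methylation betas for CpGs; DMRs are runs of ≥ 5 same-direction
   differential CpGs with gaps ≤ 500 bp.
3. **Enhancer–gene linking** — intergenic DEE→DEG links by Spearman
   correlation (ρ ≥ 0.7, Bonferroni p < 0.01) within ±1 Mb of the
   enhancer center; genic differentially methylated enhancers (DMEs:
   concurrence ≥ 2, DMR overlap ≥ 200 bp, ≥ 30 % of the enhancer,
   ≥ 5 CpGs) linked to DEGs by methylation–expression correlation
   (|ρ| ≥ 0.5, FDR ≤ 0.01); methylation-associated DEEs, histone-modifier
   coexpression fractions, and super-enhancer clusters (≥ 5 chained
   same-direction DEEs sharing ≥ 5 target genes).
4. **Replication** — cross-cohort concurrence (1 + number of cohorts
   replicating a DEE or link with matching direction) and
   platform-aware replication of DME–DEG pairs with raw
   (`100·success/total`) and platform-adjusted
   (`100·success/(success + typeII)`) rates.
5. **Downstream** — TAD/loop confirmation of links, hypergeometric
   gene-set enrichment (GMT), and the six-gene risk score
   `0.424·PLOD2 + 0.109·HOXD9 + 0.184·BOP1 − 0.134·RAB26 −
   0.185·KLRK1 − 0.0547·RGL4` with a log-rank-minimizing cutoff.

A synthetic-data generator (`sim_config()` / `simulate_dataset()`)
plants ground-truth DEEs, DEGs, enhancer–gene links, DMRs, TAD
memberships and survival structure, so every stage can be validated
offline. See the vignette (`vignettes/aberrant-enhancers.Rmd`) for the
modelling details and design decisions.

## Worked example

```r
library(enhancerAE)

sim <- simulate_dataset(sim_config(seed = 1))

# 1. catalog from the 11 simulated ChIP-seq samples
se <- lapply(seq_along(sim$chip), function(s)
  classify_sample_enhancers(sim$chip[[s]]$h3k4me1,
                            sim$chip[[s]]$h3k27ac, names(sim$chip)[s]))
names(se) <- names(sim$chip)
catalog <- merge_catalog(se, sim$genome$genes)
head(catalog[, 1:6], 3)
#>   chrom  start    end enhancer_id concurrence      class
#> 1  chr1 254990 255710   enh_00001          10      genic
#> 2  chr1 335663 338046   enh_00002           8 intergenic
#> 3  chr1 404561 405232   enh_00003           5 intergenic
concurrence_histogram(catalog, 11)$frac_concurrent
#> [1] 0.574

# 2. differential eRNA / genes on the 33 tumor/normal pairs
fp  <- fpm(sim$expression$erna_counts, sim$expression$library_sizes)
gf  <- fpm(sim$expression$gene_counts, sim$expression$library_sizes)
dee <- call_dee(paired_diff_test(as_paired_matrix(fp, sim$expression$sample_info)))
deg <- call_deg(paired_diff_test(as_paired_matrix(gf, sim$expression$sample_info)))
nrow(dee); nrow(deg)
#> [1] 39      # 22 activated, 17 repressed
#> [1] 33

# 3. intergenic DEE-DEG links (distance + rho + Bonferroni gates)
links <- link_intergenic(dee, deg, log2p1(fp), log2p1(gf),
                         sim$genome$template, sim$genome$genes)
head(links$links[, c("enhancer_id", "gene_id", "rho", "p_adj", "distance")], 3)
#>   enhancer_id gene_id       rho        p_adj distance
#> 1       E0011   G0006 0.9007165 9.632622e-23  -164251
#> 2       E0014   G0003 0.9232291 3.658202e-26  -583622
#> 3       E0058   G0037 0.8713233 2.426286e-19   435076

# 4. Hi-C confirmation of the retained links
hc <- hic_confirm(links$links, sim$genome$template, sim$genome$genes,
                  sim$hic$tads, sim$hic$loops)
attr(hc, "summary")
#>    tad   loop either
#> 0.8125 0.1250 0.8125

# 5. risk stratification of the simulated 200-patient cohort
scores <- risk_score(sim$hic$risk_expr)        # six-gene model
oc <- optimal_cutoff(scores, sim$hic$survival$time, sim$hic$survival$status)
c(cutoff = round(oc$cutoff, 3), chisq = round(oc$statistic, 1))
#>  cutoff   chisq
#>   1.957    14.7   # log-rank p = 1.3e-4
```

16 of 131 tested enhancer–gene candidates survive the gates (all of
them planted links), 81 % sit in one TAD with their target, and the
score cutoff separates the cohort into groups with clearly different
survival — which is exactly what the planted simulation encodes.

A thin CLI over the same functions lives in `inst/cli/enhancerAE.R`
(`simulate`, `catalog`, `dee`, `dmr`, `risk`, `enrich` subcommands).

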