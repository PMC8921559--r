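#' Configuration for the synthetic aberrant-enhancer dataset generator
#'
#' Bundles every knob of the generator. Defaults emulate the discovery
#' design the pipeline targets: 33 paired tumor/normal RNA-seq + WGBS
#' samples, 11 histone ChIP-seq samples (one lacking H3K27ac), roughly a
#' third of enhancers active, just over half of enhancers concurrent in
#' at least two ChIP-seq samples, 1 Mb TADs.
#'
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of genes (0 allowed: all enhancers intergenic).
#' @param n_enhancers number of template enhancers.
#' @param n_samples_chip number of ChIP-seq samples.
#' @param n_pairs_rnaseq number of tumor/normal patient pairs (RNA + WGBS).
#' @param frac_active fraction of present enhancer calls that are active
#'   (H3K4me1 + H3K27ac) rather than primed.
#' @param planted_dee_frac fraction of intergenic enhancers planted as
#'   differentially expressed (eRNA).
#' @param planted_deg_frac fraction of genes planted as differentially
#'   expressed.
#' @param planted_dmr_frac fraction of genic enhancers receiving a planted
#'   differentially methylated region.
#' @param effect_lfc planted expression effect, log2 units.
#' @param effect_dmeth planted methylation effect, delta-beta units.
#' @param link_rho_target target Spearman correlation of planted
#'   enhancer-gene links (targeted, not exact).
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param tad_size TAD tile width in bp.
#' @param frac_enh_promoter fraction of template enhancers deliberately
#'   placed inside promoters (planted filter violations).
#' @param frac_enh_short fraction of templates deliberately shorter than
#'   50 bp (planted filter violations; emitted without positional jitter).
#' @param frac_enh_genic fraction of templates placed inside gene bodies.
#' @param frac_enh_long fraction of intergenic templates longer than 3 kb.
#' @param frac_concurrent fraction of templates present in >= 2 ChIP-seq
#'   samples.
#' @param no_h3k27ac_sample index of the ChIP-seq sample emitted without an
#'   H3K27ac file (NA for none); defaults to the last sample.
#' @param frac_links_in_tad fraction of planted enhancer-gene links whose
#'   enhancer center and target TSS fall inside the same TAD tile.
#' @param loop_frac fraction of planted links additionally connected by a
#'   chromatin loop.
#' @param expr_noise_sd per-feature, per-sample log2 expression noise sd.
#'   Deliberately large so that co-differential but unlinked features stay
#'   uncorrelated across samples; planted links overcome it via a shared
#'   latent factor.
#' @param pair_sd sd of the per-patient latent factor shared by the tumor
#'   and normal library of a patient (cancels in paired tests).
#' @param beta_noise_sd per-CpG, per-sample methylation noise sd.
#' @param n_surv number of patients in the simulated survival cohort.
#' @param jitter_bp maximum per-edge positional jitter of ChIP peaks.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 1e7,
                       n_genes = 160L,
                       n_enhancers = 300L,
                       n_samples_chip = 11L,
                       n_pairs_rnaseq = 33L,
                       frac_active = 0.32,
                       planted_dee_frac = 0.2,
                       planted_deg_frac = 0.2,
                       planted_dmr_frac = 0.3,
                       effect_lfc = 2,
                       effect_dmeth = 0.3,
                       link_rho_target = 0.95,
                       nb_dispersion = 0.05,
                       tad_size = 1e6,
                       frac_enh_promoter = 0.05,
                       frac_enh_short = 0.05,
                       frac_enh_genic = 0.30,
                       frac_enh_long = 0.05,
                       frac_concurrent = 0.55,
                       no_h3k27ac_sample = NULL,
                       frac_links_in_tad = 0.7,
                       loop_frac = 0.2,
                       expr_noise_sd = 1.5,
                       pair_sd = 0.2,
                       beta_noise_sd = 0.05,
                       n_surv = 200L,
                       jitter_bp = 25L) {
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.numeric(chrom_length), n_genes = as.integer(n_genes),
    n_enhancers = as.integer(n_enhancers),
    n_samples_chip = as.integer(n_samples_chip),
    n_pairs_rnaseq = as.integer(n_pairs_rnaseq),
    frac_active = frac_active, planted_dee_frac = planted_dee_frac,
    planted_deg_frac = planted_deg_frac,
    planted_dmr_frac = planted_dmr_frac,
    effect_lfc = effect_lfc, effect_dmeth = effect_dmeth,
    link_rho_target = link_rho_target, nb_dispersion = nb_dispersion,
    tad_size = as.numeric(tad_size),
    frac_enh_promoter = frac_enh_promoter,
    frac_enh_short = frac_enh_short, frac_enh_genic = frac_enh_genic,
    frac_enh_long = frac_enh_long, frac_concurrent = frac_concurrent,
    no_h3k27ac_sample =
      if (is.null(no_h3k27ac_sample)) as.integer(n_samples_chip)
      else as.integer(no_h3k27ac_sample),
    frac_links_in_tad = frac_links_in_tad, loop_frac = loop_frac,
    expr_noise_sd = expr_noise_sd, pair_sd = pair_sd,
    beta_noise_sd = beta_noise_sd, n_surv = as.integer(n_surv),
    jitter_bp = as.integer(jitter_bp)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fracs <- c("frac_active", "planted_dee_frac", "planted_deg_frac",
             "planted_dmr_frac", "link_rho_target", "frac_enh_promoter",
             "frac_enh_short", "frac_enh_genic", "frac_enh_long",
             "frac_concurrent", "frac_links_in_tad", "loop_frac")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("sim_config: ", f, " must be a fraction in [0, 1]", call. = FALSE)
    }
  }
  pos <- c("n_chroms", "chrom_length", "n_enhancers", "n_samples_chip",
           "n_pairs_rnaseq", "nb_dispersion", "tad_size", "expr_noise_sd",
           "beta_noise_sd", "n_surv")
  for (f in pos) {
    if (cfg[[f]] <= 0) stop("sim_config: ", f, " must be positive",
                            call. = FALSE)
  }
  if (cfg$n_genes < 0) stop("sim_config: n_genes must be >= 0", call. = FALSE)
  if (cfg$n_pairs_rnaseq < 3) {
    stop("sim_config: need at least 3 tumor/normal pairs", call. = FALSE)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chroms, "chrom x", format(x$chrom_length, big.mark = ","),
      "bp;", x$n_genes, "genes;", x$n_enhancers, "enhancers;",
      x$n_samples_chip, "ChIP samples;", x$n_pairs_rnaseq,
      "tumor/normal pairs\n")
  invisible(x)
}
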