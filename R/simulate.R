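# Synthetic-data generator. Every stage of the pipeline can be exercised
# against the planted ground truth this module records, without any
# external download. Coordinates are 0-based half-open throughout.

# Layout constants: genes sit on a regular grid; intergenic enhancer slots
# tile the gaps. Margins keep non-promoter placements clear of any
# promoter window (1,500 bp up / 500 bp down) on either strand.
.GAP_MARGIN <- 2000L
.SLOT_PITCH <- 7000L
.GENIC_MARGIN <- 600L
.GENIC_PITCH <- 1500L

#' Simulate gene annotation and template enhancer intervals
#'
#' Genes are placed on a regular per-chromosome grid (so transcripts never
#' overlap) with random strand. Template enhancers are placed in four
#' classes: intergenic, genic (inside a gene body, clear of the promoter),
#' promoter-overlapping (planted catalog-filter violations), and <50 bp
#' (planted length-filter violations). With `n_genes = 0` all enhancers
#' are intergenic.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (gene_id, chrom, strand, tx_start, tx_end),
#'   `template` (enh_id, chrom, start, end, placement) and `chroms`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))

  n_genes <- config$n_genes
  genes <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tx_start = integer(),
                      tx_end = integer(), stringsAsFactors = FALSE)
  if (n_genes > 0) {
    gpc <- ceiling(n_genes / config$n_chroms)
    spacing <- floor(config$chrom_length / (gpc + 1))
    if (spacing < 12000) {
      stop("simulate_genome: chromosome too short to host ", n_genes,
           " genes (need >= 12 kb spacing, got ", spacing, ")",
           call. = FALSE)
    }
    rows <- vector("list", n_genes)
    i <- 0L
    for (ch in chroms) {
      for (j in seq_len(gpc)) {
        if (i >= n_genes) break
        i <- i + 1L
        anchor <- j * spacing
        len <- sample(5000:min(20000L, spacing - 6000L), 1)
        rows[[i]] <- data.frame(
          gene_id = sprintf("G%04d", i), chrom = ch,
          strand = sample(c("+", "-"), 1),
          tx_start = anchor, tx_end = anchor + len,
          stringsAsFactors = FALSE
        )
      }
    }
    genes <- do.call(rbind, rows)
  }

  slots <- .intergenic_slots(config, genes, chroms)
  n_enh <- config$n_enhancers
  n_prom <- if (n_genes > 0) round(config$frac_enh_promoter * n_enh) else 0L
  n_short <- round(config$frac_enh_short * n_enh)
  n_genic <- if (n_genes > 0) round(config$frac_enh_genic * n_enh) else 0L
  n_inter <- n_enh - n_prom - n_short - n_genic
  if (n_inter < 0) {
    stop("simulate_genome: enhancer class fractions exceed 1", call. = FALSE)
  }
  if (nrow(slots) < n_inter + n_short) {
    stop("simulate_genome: chromosome too short to host ", n_inter + n_short,
         " intergenic enhancers (", nrow(slots), " slots available)",
         call. = FALSE)
  }

  take <- slots[sample.int(nrow(slots), n_inter + n_short), , drop = FALSE]
  tmpl <- list()
  if (n_inter > 0) {
    it <- take[seq_len(n_inter), , drop = FALSE]
    long <- runif(n_inter) < config$frac_enh_long
    w <- ifelse(long, sample(3500:6000, n_inter, replace = TRUE),
                sample(300:2500, n_inter, replace = TRUE))
    tmpl$inter <- data.frame(chrom = it$chrom, start = it$pos,
                             end = it$pos + w, placement = "intergenic",
                             stringsAsFactors = FALSE)
  }
  if (n_short > 0) {
    st <- take[n_inter + seq_len(n_short), , drop = FALSE]
    w <- sample(20:49, n_short, replace = TRUE)
    tmpl$short <- data.frame(chrom = st$chrom, start = st$pos,
                             end = st$pos + w, placement = "short",
                             stringsAsFactors = FALSE)
  }
  if (n_genic > 0) {
    gslots <- .genic_slots(genes)
    if (nrow(gslots) < n_genic) {
      stop("simulate_genome: genes too short/few to host ", n_genic,
           " genic enhancers", call. = FALSE)
    }
    gs <- gslots[sample.int(nrow(gslots), n_genic), , drop = FALSE]
    w <- sample(300:700, n_genic, replace = TRUE)
    tmpl$genic <- data.frame(chrom = gs$chrom, start = gs$pos,
                             end = gs$pos + w, placement = "genic",
                             host_gene = gs$gene_id,
                             stringsAsFactors = FALSE)
  }
  if (n_prom > 0) {
    pick <- genes[sample.int(nrow(genes), n_prom), , drop = FALSE]
    tss <- gene_tss(pick)
    tmpl$prom <- data.frame(chrom = pick$chrom, start = tss - 150L,
                            end = tss + 150L, placement = "promoter",
                            stringsAsFactors = FALSE)
  }
  tmpl <- lapply(tmpl, function(d) {
    if (!"host_gene" %in% names(d)) d$host_gene <- NA_character_
    d
  })
  template <- do.call(rbind, tmpl)
  template <- template[order(template$chrom, template$start), ]
  template <- data.frame(enh_id = sprintf("E%04d", seq_len(nrow(template))),
                         template, row.names = NULL,
                         stringsAsFactors = FALSE)
  list(genes = genes, template = template, chroms = chroms)
}

.intergenic_slots <- function(config, genes, chroms) {
  out <- list()
  for (ch in chroms) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$tx_start), , drop = FALSE]
    bounds <- c(0L, rbind(g$tx_start, g$tx_end), config$chrom_length)
    gap_start <- bounds[seq(1, length(bounds), 2)]
    gap_end <- bounds[seq(2, length(bounds), 2)]
    for (k in seq_along(gap_start)) {
      lo <- gap_start[k] + .GAP_MARGIN
      hi <- gap_end[k] - .GAP_MARGIN - .SLOT_PITCH
      if (hi > lo) {
        pos <- seq(lo, hi, by = .SLOT_PITCH)
        out[[length(out) + 1L]] <- data.frame(chrom = ch, pos = pos,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = integer()))
  }
  do.call(rbind, out)
}

.genic_slots <- function(genes) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    lo <- genes$tx_start[i] + .GENIC_MARGIN
    hi <- genes$tx_end[i] - .GENIC_MARGIN - 800L
    if (hi > lo) {
      pos <- seq(lo, hi, by = .GENIC_PITCH)
      out[[length(out) + 1L]] <- data.frame(chrom = genes$chrom[i],
                                            gene_id = genes$gene_id[i],
                                            pos = pos,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), gene_id = character(),
                      pos = integer()))
  }
  do.call(rbind, out)
}

#' Plant the ground truth for a simulated genome
#'
#' Decides, before any data matrix is drawn: which ChIP-seq samples carry
#' each template enhancer (and whether the call is active or primed);
#' which enhancers/genes are differentially expressed and in which
#' direction; which enhancer-gene pairs are linked (with the per-sample
#' latent factors that induce the correlation); where DMRs sit and which
#' of them drive genic DME links or methylation-associated DEEs; CpG
#' positions; and which planted links fall inside one TAD tile.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @return list of class `ae_truth`; sufficient to score every pipeline
#'   stage without re-reading the config.
#' @export
plant_truth <- function(config, genome) {
  set.seed(config$seed + 10L)
  tmpl <- genome$template
  genes <- genome$genes
  n_t <- nrow(tmpl)
  ns <- config$n_samples_chip
  n_pairs <- config$n_pairs_rnaseq
  samples <- as.vector(t(outer(sprintf("P%02d", seq_len(n_pairs)),
                               c("T", "N"), paste, sep = "_")))

  # ChIP presence/activity plan
  presence <- matrix(FALSE, n_t, ns,
                     dimnames = list(tmpl$enh_id,
                                     sprintf("S%02d", seq_len(ns))))
  conc <- ifelse(runif(n_t) < config$frac_concurrent,
                 sample(2:max(2, ns), n_t, replace = TRUE), 1L)
  conc <- pmin(conc, ns)
  for (i in seq_len(n_t)) {
    presence[i, sample.int(ns, conc[i])] <- TRUE
  }
  active <- presence & matrix(runif(n_t * ns) < config$frac_active, n_t, ns)

  # planted DEEs (intergenic eRNA features) and DEGs
  erna_ids <- tmpl$enh_id[tmpl$placement == "intergenic"]
  n_dee <- round(config$planted_dee_frac * length(erna_ids))
  dee_ids <- sample(erna_ids, n_dee)
  dee <- data.frame(enh_id = dee_ids,
                    direction = sample(c("up", "down"), n_dee,
                                       replace = TRUE),
                    stringsAsFactors = FALSE)
  n_deg <- round(config$planted_deg_frac * nrow(genes))
  deg_ids <- if (n_deg > 0) sample(genes$gene_id, n_deg) else character()
  deg <- data.frame(gene_id = deg_ids,
                    direction = sample(c("up", "down"), n_deg,
                                       replace = TRUE),
                    stringsAsFactors = FALSE)

  # planted intergenic links: same chromosome, same direction, TSS within
  # 0.9 Mb of the enhancer center; TAD co-membership controlled
  # latent factors are per-patient (identical in the tumor and normal
  # columns of a patient): they cancel in paired tests but still induce
  # cross-sample correlation between the two features sharing them
  patient_of <- match(sub("_[TN]$", "", samples),
                      sprintf("P%02d", seq_len(n_pairs)))
  expand <- function(m_pat) {
    out <- m_pat[, patient_of, drop = FALSE]
    colnames(out) <- samples
    out
  }
  links <- .plant_links(config, tmpl, genes, dee, deg)
  n_links <- nrow(links)
  link_latent <- if (n_links > 0) {
    expand(matrix(rnorm(n_links * n_pairs), n_links, n_pairs))
  } else matrix(0, 0, length(samples))

  # planted DMRs: on genic enhancers (DME candidates), on a subset of
  # planted DEEs (methylation-associated DEEs), and plain regions
  dmrs <- .plant_dmrs(config, tmpl, genes, dee, deg, conc, links)
  dme_rows <- which(dmrs$kind == "dme")
  deem_rows <- which(dmrs$kind == "dee_meth")
  dmr_latent <- if (nrow(dmrs) > 0) {
    expand(matrix(rnorm(nrow(dmrs) * n_pairs), nrow(dmrs), n_pairs))
  } else matrix(0, 0, length(samples))

  cpgs <- .place_cpgs(config, genome, dmrs)

  truth <- list(
    samples = samples,
    presence = presence, active = active,
    expected_concurrence = rowSums(presence),
    dee = dee, deg = deg,
    links = links, link_latent = link_latent,
    dmrs = dmrs, dmr_latent = dmr_latent,
    cpgs = cpgs,
    erna_ids = erna_ids
  )
  class(truth) <- "ae_truth"
  truth
}

.plant_links <- function(config, tmpl, genes, dee, deg) {
  empty <- data.frame(enh_id = character(), gene_id = character(),
                      direction = character(), same_tad = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(dee) == 0 || nrow(deg) == 0) return(empty)
  ei <- match(dee$enh_id, tmpl$enh_id)
  centers <- interval_center(tmpl[ei, ])
  gi <- match(deg$gene_id, genes$gene_id)
  tss <- gene_tss(genes[gi, ])
  cand <- list()
  for (a in seq_len(nrow(dee))) {
    same <- which(genes$chrom[gi] == tmpl$chrom[ei[a]] &
                    abs(tss - centers[a]) <= 9e5 &
                    deg$direction == dee$direction[a])
    if (length(same)) {
      cand[[length(cand) + 1L]] <- data.frame(
        enh_id = dee$enh_id[a], gene_id = deg$gene_id[same],
        direction = dee$direction[a],
        same_tad = floor(centers[a] / config$tad_size) ==
          floor(tss[same] / config$tad_size),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  n_target <- max(1L, round(0.6 * nrow(dee)))
  n_in <- round(config$frac_links_in_tad * n_target)
  # one link per enhancer AND per gene: each planted pair must own its
  # shared latent factor exclusively, or realized correlations dilute
  used_e <- character()
  used_g <- character()
  pick <- function(pool, k) {
    pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
    keep <- integer()
    for (r in seq_len(nrow(pool))) {
      if (length(keep) >= k) break
      if (!pool$enh_id[r] %in% used_e && !pool$gene_id[r] %in% used_g) {
        keep <- c(keep, r)
        used_e <<- c(used_e, pool$enh_id[r])
        used_g <<- c(used_g, pool$gene_id[r])
      }
    }
    pool[keep, , drop = FALSE]
  }
  sel_in <- pick(cand[cand$same_tad, , drop = FALSE], n_in)
  rest <- cand[!cand$same_tad, , drop = FALSE]
  sel_out <- pick(rest, n_target - nrow(sel_in))
  out <- rbind(sel_in, sel_out)
  rownames(out) <- NULL
  out
}

.plant_dmrs <- function(config, tmpl, genes, dee, deg, conc, links) {
  rows <- list()
  genic <- tmpl[tmpl$placement == "genic", , drop = FALSE]
  genic_conc <- conc[match(genic$enh_id, tmpl$enh_id)]
  # prefer concurrence >= 2 hosts so planted DMEs survive the catalog gate
  ord <- order(-genic_conc)
  n_dme <- round(config$planted_dmr_frac * nrow(genic))
  hosts <- genic[ord[seq_len(min(n_dme, nrow(genic)))], , drop = FALSE]
  deg_free <- setdiff(deg$gene_id, links$gene_id)
  if (nrow(hosts) > 0) {
    gi <- match(deg_free, genes$gene_id)
    tssf <- gene_tss(genes[gi, , drop = FALSE])
    for (i in seq_len(nrow(hosts))) {
      ok <- which(genes$chrom[gi] == hosts$chrom[i] &
                    pmin(abs(tssf - hosts$start[i]),
                         abs(tssf - hosts$end[i])) <= 9e5 &
                    !is.na(gi))
      # each DME owns its target gene (and latent) exclusively
      target <- if (length(ok)) {
        deg_free[ok[sample.int(length(ok), 1)]]
      } else NA_character_
      if (!is.na(target)) {
        drop_i <- match(target, deg_free)
        deg_free <- deg_free[-drop_i]
        gi <- gi[-drop_i]
        tssf <- tssf[-drop_i]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = hosts$chrom[i], start = hosts$start[i], end = hosts$end[i],
        direction = sample(c("hyper", "hypo"), 1), kind = "dme",
        target_enh = hosts$enh_id[i], target_gene = target,
        stringsAsFactors = FALSE
      )
    }
  }
  # methylation-associated DEEs: hypo when activated, hyper when repressed
  n_dm <- round(0.3 * nrow(dee))
  if (n_dm > 0) {
    picked <- dee[sample.int(nrow(dee), n_dm), , drop = FALSE]
    ti <- match(picked$enh_id, tmpl$enh_id)
    for (i in seq_len(nrow(picked))) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tmpl$chrom[ti[i]], start = tmpl$start[ti[i]],
        end = tmpl$end[ti[i]],
        direction = if (picked$direction[i] == "up") "hypo" else "hyper",
        kind = "dee_meth", target_enh = picked$enh_id[i],
        target_gene = NA_character_, stringsAsFactors = FALSE
      )
    }
  }
  # plain DMRs in otherwise-empty intergenic space, for DMR-caller checks
  slots <- .intergenic_slots(config, genes, unique(tmpl$chrom))
  used <- paste(tmpl$chrom, tmpl$start)
  free <- slots[!paste(slots$chrom, slots$pos) %in% used, , drop = FALSE]
  n_plain <- min(10L, nrow(free))
  if (n_plain > 0) {
    fs <- free[sample.int(nrow(free), n_plain), , drop = FALSE]
    for (i in seq_len(n_plain)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fs$chrom[i], start = fs$pos[i], end = fs$pos[i] + 360L,
        direction = sample(c("hyper", "hypo"), 1), kind = "plain",
        target_enh = NA_character_, target_gene = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      kind = character(), target_enh = character(),
                      target_gene = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$dmr_id <- sprintf("DMR%03d", seq_len(nrow(out)))
  out
}

.place_cpgs <- function(config, genome, dmrs) {
  tmpl <- genome$template
  host <- rbind(
    data.frame(chrom = tmpl$chrom, start = tmpl$start, end = tmpl$end,
               stringsAsFactors = FALSE)[tmpl$placement != "short", ],
    data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
               stringsAsFactors = FALSE)
  )
  pos_list <- lapply(seq_len(nrow(host)), function(i) {
    if (host$end[i] - host$start[i] < 120) return(NULL)
    data.frame(chrom = host$chrom[i],
               pos = seq(host$start[i] + 10L, host$end[i] - 11L, by = 50L),
               stringsAsFactors = FALSE)
  })
  # background CpG clusters for null behavior
  slots <- .intergenic_slots(config, genome$genes, genome$chroms)
  used <- paste(host$chrom, host$start)
  free <- slots[!paste(slots$chrom, slots$pos) %in% used, , drop = FALSE]
  n_bg <- min(40L, nrow(free))
  if (n_bg > 0) {
    bg <- free[sample.int(nrow(free), n_bg), , drop = FALSE]
    pos_list <- c(pos_list, lapply(seq_len(n_bg), function(i) {
      data.frame(chrom = bg$chrom[i],
                 pos = bg$pos[i] + seq(0L, 550L, by = 50L),
                 stringsAsFactors = FALSE)
    }))
  }
  cpgs <- do.call(rbind, pos_list)
  cpgs <- unique(cpgs)
  cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), ]
  cpgs$cpg_id <- paste0(cpgs$chrom, "_", cpgs$pos)
  rownames(cpgs) <- NULL
  cpgs
}

#' Simulate per-sample ChIP-seq peak and chromatin-state files
#'
#' Each ChIP-seq sample receives a jittered copy of every template
#' enhancer assigned to it by the planted presence matrix. Active calls
#' get an overlapping H3K27ac peak; the configured no-H3K27ac sample emits
#' only H3K4me1 (so all its calls are state-unknown downstream) and no
#' state file. Sub-50 bp templates are emitted without jitter so the
#' planted length-filter violations stay below threshold after merging.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @param truth output of [plant_truth()]; regenerated if missing.
#' @param presence optional logical override matrix (template x sample);
#'   `presence = TRUE` everywhere makes every sample carry every template.
#' @return named list (one element per sample) of lists with `h3k4me1`,
#'   `h3k27ac` (NULL for the no-H3K27ac sample) and `states` interval
#'   tables.
#' @export
simulate_chip_samples <- function(config, genome,
                                  truth = plant_truth(config, genome),
                                  presence = NULL) {
  set.seed(config$seed + 20L)
  tmpl <- genome$template
  pres <- presence %||% truth$presence
  if (is.logical(pres) && length(pres) == 1) {
    pres <- matrix(pres, nrow(tmpl), config$n_samples_chip)
  }
  act <- truth$active & pres
  ns <- config$n_samples_chip
  jit <- config$jitter_bp
  out <- vector("list", ns)
  names(out) <- sprintf("S%02d", seq_len(ns))
  for (s in seq_len(ns)) {
    idx <- which(pres[, s])
    t_s <- tmpl[idx, , drop = FALSE]
    fixed <- t_s$placement == "short"
    d1 <- ifelse(fixed, 0L, sample(-jit:jit, nrow(t_s), replace = TRUE))
    d2 <- ifelse(fixed, 0L, sample(-jit:jit, nrow(t_s), replace = TRUE))
    k4 <- data.frame(chrom = t_s$chrom, start = pmax(0L, t_s$start + d1),
                     end = t_s$end + d2, stringsAsFactors = FALSE)
    k4 <- k4[order(k4$chrom, k4$start), ]
    is_active <- act[idx, s]
    k27 <- NULL
    states <- NULL
    if (s != config$no_h3k27ac_sample) {
      a <- which(is_active)
      e1 <- ifelse(fixed[a], 0L, sample(-jit:jit, length(a), replace = TRUE))
      e2 <- ifelse(fixed[a], 0L, sample(-jit:jit, length(a), replace = TRUE))
      k27 <- data.frame(chrom = t_s$chrom[a],
                        start = pmax(0L, t_s$start[a] + e1),
                        end = t_s$end[a] + e2,
                        stringsAsFactors = FALSE)
      k27 <- k27[order(k27$chrom, k27$start), ]
      states <- data.frame(
        chrom = k4$chrom, start = k4$start, end = k4$end,
        name = ifelse(is_active, "active_enhancer", "poised_enhancer"),
        stringsAsFactors = FALSE
      )
      # decoy promoter-state rows that ingest_state_bed must drop
      if (nrow(genome$genes) > 0) {
        pr <- gene_promoters(genome$genes)
        pick <- seq_len(min(5L, nrow(pr)))
        states <- rbind(states,
                        data.frame(chrom = pr$chrom[pick],
                                   start = pr$start[pick],
                                   end = pr$end[pick], name = "promoter",
                                   stringsAsFactors = FALSE))
      }
      states <- states[order(states$chrom, states$start), ]
    }
    out[[s]] <- list(h3k4me1 = k4, h3k27ac = k27, states = states)
  }
  out
}

#' Simulate paired tumor/normal gene and eRNA count matrices
#'
#' Counts are negative binomial around a log2-scale mean built from: a
#' per-feature baseline, a per-patient latent factor shared by the tumor
#' and normal libraries (cancels in paired tests), heavy independent
#' per-sample noise (`expr_noise_sd`), the planted tumor shift
#' (`effect_lfc`) for planted DEEs/DEGs, and -- for planted links -- a
#' per-sample latent factor shared between the enhancer's eRNA and its
#' target gene, scaled to aim at `link_rho_target`.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @param truth output of [plant_truth()].
#' @return list with `gene_counts`, `erna_counts` (feature x sample
#'   integer matrices), `library_sizes` (named), and `sample_info`
#'   (sample_id, patient, condition).
#' @export
simulate_expression <- function(config, genome,
                                truth = plant_truth(config, genome)) {
  set.seed(config$seed + 30L)
  samples <- truth$samples
  n_s <- length(samples)
  patient <- sub("_[TN]$", "", samples)
  condition <- ifelse(grepl("_T$", samples), "tumor", "normal")
  lib <- stats::setNames(runif(n_s, 1.6e6, 2.4e6), samples)

  pairfac <- stats::setNames(rnorm(config$n_pairs_rnaseq, 0, config$pair_sd),
                             unique(patient))[patient]
  tumor <- condition == "tumor"

  # shared-latent scale aimed at the configured rho; capped so the log2
  # dynamic range stays within what NB counts can express without
  # saturating at zero (rho is targeted, not exact)
  rho <- min(config$link_rho_target, 0.92)
  lambda <- config$expr_noise_sd * sqrt(rho / (1 - rho))

  draw <- function(ids, base_lo, base_hi, planted, latent_of) {
    n_f <- length(ids)
    if (n_f == 0) {
      return(matrix(0L, 0, n_s, dimnames = list(NULL, samples)))
    }
    logmu <- matrix(runif(n_f, base_lo, base_hi), n_f, n_s) +
      matrix(pairfac, n_f, n_s, byrow = TRUE) +
      matrix(rnorm(n_f * n_s, 0, config$expr_noise_sd), n_f, n_s)
    pi <- match(ids, planted[[1]])
    shift <- ifelse(is.na(pi), 0,
                    ifelse(planted$direction[pi] == "up", 1, -1) *
                      config$effect_lfc)
    logmu <- logmu + outer(shift, as.numeric(tumor))
    lat <- latent_of(ids)
    if (!is.null(lat)) logmu <- logmu + lambda * lat
    mu <- sweep(2^pmin(logmu, 26), 2, lib / 2e6, "*")
    cnt <- matrix(rnbinom(n_f * n_s, mu = mu, size = 1 / config$nb_dispersion),
                  n_f, n_s, dimnames = list(ids, samples))
    storage.mode(cnt) <- "double"
    cnt
  }

  links <- truth$links
  gene_latent <- function(ids) {
    if (nrow(links) == 0) return(NULL)
    lat <- matrix(0, length(ids), n_s)
    li <- match(ids, links$gene_id)
    hit <- which(!is.na(li))
    if (length(hit)) lat[hit, ] <- truth$link_latent[li[hit], , drop = FALSE]
    # genic DME target genes share a latent with enhancer methylation;
    # sign chosen so tumor shifts and the latent reinforce each other
    dme <- truth$dmrs[truth$dmrs$kind == "dme" &
                        !is.na(truth$dmrs$target_gene), , drop = FALSE]
    if (nrow(dme)) {
      di <- match(ids, dme$target_gene)
      hit2 <- which(!is.na(di))
      for (h in hit2) {
        row <- which(truth$dmrs$dmr_id == dme$dmr_id[di[h]])
        sgn <- .dme_corr_sign(dme$direction[di[h]],
                              truth$deg$direction[
                                match(dme$target_gene[di[h]],
                                      truth$deg$gene_id)])
        lat[h, ] <- lat[h, ] + 0.7 * sgn * truth$dmr_latent[row, ]
      }
    }
    lat
  }
  erna_latent <- function(ids) {
    lat <- matrix(0, length(ids), n_s)
    if (nrow(links)) {
      li <- match(ids, links$enh_id)
      hit <- which(!is.na(li))
      if (length(hit)) {
        lat[hit, ] <- truth$link_latent[li[hit], , drop = FALSE]
      }
    }
    dm <- truth$dmrs[truth$dmrs$kind == "dee_meth", , drop = FALSE]
    if (nrow(dm)) {
      di <- match(ids, dm$target_enh)
      hit <- which(!is.na(di))
      for (h in hit) {
        row <- which(truth$dmrs$dmr_id == dm$dmr_id[di[h]])
        dee_dir <- truth$dee$direction[match(dm$target_enh[di[h]],
                                             truth$dee$enh_id)]
        sgn <- .dme_corr_sign(dm$direction[di[h]], dee_dir)
        lat[h, ] <- lat[h, ] + 0.7 * sgn * truth$dmr_latent[row, ]
      }
    }
    lat
  }

  gene_counts <- draw(genome$genes$gene_id, 5, 9,
                      truth$deg, gene_latent)
  erna_counts <- draw(truth$erna_ids, 5, 8,
                      stats::setNames(truth$dee, c("enh_id", "direction")),
                      erna_latent)

  list(gene_counts = gene_counts, erna_counts = erna_counts,
       library_sizes = lib,
       sample_info = data.frame(sample_id = samples, patient = patient,
                                condition = condition,
                                stringsAsFactors = FALSE))
}

# sign of the planted methylation-expression correlation implied by the
# DMR direction and the expression direction (they must reinforce the
# cross-sample pattern the tumor shifts already create)
.dme_corr_sign <- function(dmr_dir, expr_dir) {
  ifelse((dmr_dir == "hyper") == (expr_dir == "up"), 1, -1)
}

#' Simulate a per-CpG methylation (beta) matrix across paired samples
#'
#' Beta values are clipped normals around a per-CpG baseline. CpGs inside
#' planted DMRs get a tumor shift of `effect_dmeth` (sign per DMR
#' direction); DMRs that drive genic DME links or methylation-associated
#' DEEs additionally carry the per-sample latent factor shared with the
#' target expression feature.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @param truth output of [plant_truth()].
#' @return list with `beta` (CpG x sample matrix in [0,1]), `cpgs`
#'   (cpg_id, chrom, pos), and `sample_info`.
#' @export
simulate_methylation <- function(config, genome,
                                 truth = plant_truth(config, genome)) {
  set.seed(config$seed + 40L)
  cpgs <- truth$cpgs
  samples <- truth$samples
  n_c <- nrow(cpgs)
  n_s <- length(samples)
  tumor <- grepl("_T$", samples)
  base <- runif(n_c, 0.3, 0.7)
  beta <- matrix(base, n_c, n_s) +
    matrix(rnorm(n_c * n_s, 0, config$beta_noise_sd), n_c, n_s)
  dmrs <- truth$dmrs
  if (nrow(dmrs)) {
    cpg_gr <- GenomicRanges::GRanges(cpgs$chrom,
                                     IRanges::IRanges(cpgs$pos + 1L,
                                                      width = 1L))
    dmr_gr <- bed_to_gr(dmrs[, c("chrom", "start", "end")])
    ov <- GenomicRanges::findOverlaps(cpg_gr, dmr_gr)
    shift_dir <- ifelse(dmrs$direction == "hyper", 1, -1)
    for (h in seq_along(S4Vectors::queryHits(ov))) {
      ci <- S4Vectors::queryHits(ov)[h]
      di <- S4Vectors::subjectHits(ov)[h]
      beta[ci, tumor] <- beta[ci, tumor] +
        shift_dir[di] * config$effect_dmeth
      if (dmrs$kind[di] %in% c("dme", "dee_meth")) {
        beta[ci, ] <- beta[ci, ] + 0.08 * truth$dmr_latent[di, ]
      }
    }
  }
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(cpgs$cpg_id, samples)
  list(beta = beta, cpgs = cpgs,
       sample_info = data.frame(
         sample_id = samples, patient = sub("_[TN]$", "", samples),
         condition = ifelse(tumor, "tumor", "normal"),
         stringsAsFactors = FALSE))
}

#' Simulate TADs, chromatin loops, and a survival cohort
#'
#' TADs tile each chromosome at `tad_size`; whether a planted link falls
#' inside one tile was fixed at planting time. Loops connect a
#' `loop_frac` subset of planted links (enhancer interval to TSS +/- 2 kb).
#' Survival times are exponential with hazard proportional to
#' `exp(risk score)` over six designated genes (default: the packaged
#' six-gene risk model), or with a hazard jump at a planted score
#' threshold when `hazard_model = "threshold"`.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @param truth output of [plant_truth()].
#' @param hazard_model `"proportional"` (default) or `"threshold"`.
#' @param threshold planted score threshold for the jump model; defaults
#'   to the median simulated score.
#' @param hazard_ratio hazard ratio above the threshold (jump model).
#' @return list with `tads`, `loops`, `survival` (patient, time, status),
#'   `risk_expr` (6-gene x patient matrix), `scores`, and `threshold`.
#' @export
simulate_hic_survival <- function(config, genome,
                                  truth = plant_truth(config, genome),
                                  hazard_model = c("proportional",
                                                   "threshold"),
                                  threshold = NULL, hazard_ratio = 6) {
  hazard_model <- match.arg(hazard_model)
  set.seed(config$seed + 50L)
  tads <- do.call(rbind, lapply(genome$chroms, function(ch) {
    s <- seq(0, config$chrom_length - 1, by = config$tad_size)
    data.frame(chrom = ch, start = as.integer(s),
               end = as.integer(pmin(s + config$tad_size,
                                     config$chrom_length)),
               stringsAsFactors = FALSE)
  }))

  links <- truth$links
  loops <- data.frame(chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer())
  if (nrow(links)) {
    n_loop <- round(config$loop_frac * nrow(links))
    if (n_loop > 0) {
      pick <- links[sample.int(nrow(links), n_loop), , drop = FALSE]
      ti <- match(pick$enh_id, genome$template$enh_id)
      gi <- match(pick$gene_id, genome$genes$gene_id)
      tss <- gene_tss(genome$genes[gi, , drop = FALSE])
      loops <- data.frame(
        chrom1 = genome$template$chrom[ti],
        start1 = genome$template$start[ti],
        end1 = genome$template$end[ti],
        chrom2 = genome$genes$chrom[gi],
        start2 = pmax(0L, tss - 2000L), end2 = tss + 2000L,
        stringsAsFactors = FALSE
      )
    }
  }

  n <- config$n_surv
  model <- risk_model()
  gene_names <- names(model$coefficients)
  expr <- matrix(rnorm(6 * n, mean = 5, sd = 1), 6, n,
                 dimnames = list(gene_names,
                                 sprintf("PT%03d", seq_len(n))))
  scores <- risk_score(expr, model)
  if (hazard_model == "proportional") {
    rate <- (log(2) / 1000) * exp(scores - mean(scores))
  } else {
    threshold <- threshold %||% stats::median(scores)
    rate <- (log(2) / 1000) * ifelse(scores > threshold, hazard_ratio, 1)
  }
  t_event <- rexp(n, rate = rate)
  t_cens <- runif(n, 200, 4000)
  surv <- data.frame(
    patient = colnames(expr),
    time = round(pmin(t_event, t_cens), 2),
    status = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE
  )
  surv$time[surv$time <= 0] <- 0.01
  list(tads = tads, loops = loops, survival = surv, risk_expr = expr,
       scores = scores,
       threshold = if (hazard_model == "threshold") threshold else NULL)
}

#' Simulate a complete dataset with planted ground truth
#'
#' Orchestrates [simulate_genome()], [plant_truth()],
#' [simulate_chip_samples()], [simulate_expression()],
#' [simulate_methylation()], and [simulate_hic_survival()]. Deterministic
#' for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `ae_simulation` with components `config`,
#'   `genome`, `truth`, `chip`, `expression`, `methylation`, `hic`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  truth <- plant_truth(config, genome)
  sim <- list(
    config = config,
    genome = genome,
    truth = truth,
    chip = simulate_chip_samples(config, genome, truth),
    expression = simulate_expression(config, genome, truth),
    methylation = simulate_methylation(config, genome, truth),
    hic = simulate_hic_survival(config, genome, truth)
  )
  class(sim) <- "ae_simulation"
  sim
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Emits `genes.tsv`, per-sample `sample_<k>.H3K4me1.bed` /
#' `.H3K27ac.bed` / `.states.bed`, `gene_counts.tsv`, `erna_counts.tsv`,
#' `libsizes.tsv`, `cpg_beta.tsv`, `tads.bed`, `loops.bedpe`,
#' `survival.tsv`, `risk_expr.tsv`, `enhancer_template.tsv` and
#' `truth.json`.
#'
#' @param sim output of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "ae_simulation"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  data.table::fwrite(sim$genome$genes, p("genes.tsv"), sep = "\t")
  data.table::fwrite(sim$genome$template, p("enhancer_template.tsv"),
                     sep = "\t")
  for (s in seq_along(sim$chip)) {
    smp <- sim$chip[[s]]
    write_bed(smp$h3k4me1, p(sprintf("sample_%02d.H3K4me1.bed", s)))
    if (!is.null(smp$h3k27ac)) {
      write_bed(smp$h3k27ac, p(sprintf("sample_%02d.H3K27ac.bed", s)))
    }
    if (!is.null(smp$states)) {
      write_bed(smp$states, p(sprintf("sample_%02d.states.bed", s)))
    }
  }
  write_matrix_tsv(sim$expression$gene_counts, p("gene_counts.tsv"),
                   "gene_id")
  write_matrix_tsv(sim$expression$erna_counts, p("erna_counts.tsv"),
                   "enh_id")
  data.table::fwrite(
    data.frame(sample_id = names(sim$expression$library_sizes),
               library_size = unname(sim$expression$library_sizes)),
    p("libsizes.tsv"), sep = "\t")
  beta_df <- data.frame(cpg_id = rownames(sim$methylation$beta),
                        sim$methylation$cpgs[, c("chrom", "pos")],
                        sim$methylation$beta, check.names = FALSE)
  data.table::fwrite(beta_df, p("cpg_beta.tsv"), sep = "\t")
  write_bed(sim$hic$tads, p("tads.bed"))
  write_bedpe(sim$hic$loops, p("loops.bedpe"))
  data.table::fwrite(sim$hic$survival, p("survival.tsv"), sep = "\t")
  write_matrix_tsv(sim$hic$risk_expr, p("risk_expr.tsv"), "gene_id")
  truth_out <- list(
    dee = sim$truth$dee, deg = sim$truth$deg, links = sim$truth$links,
    dmrs = sim$truth$dmrs,
    expected_concurrence = as.list(sim$truth$expected_concurrence)
  )
  jsonlite::write_json(truth_out, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}
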