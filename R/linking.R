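# Enhancer-gene linking: intergenic DEE-DEGs by distance-constrained
# Spearman correlation, genic DMEs by DMR overlap + methylation-expression
# correlation, methylation/modifier associations, and super-enhancer
# cluster detection.

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; p from the t approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) with n-2 df. A constant input vector
#' makes rho undefined; it is returned as 0 with p = 1 (with a message).
#'
#' @param x,y equal-length numeric vectors, n >= 4.
#' @param quiet suppress the constant-vector message.
#' @return list with `rho` and `p`.
#' @export
spearman_cor <- function(x, y, quiet = FALSE) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("spearman_cor: need n >= 4", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    if (!quiet) message("spearman_cor: constant vector; rho set to 0")
    return(list(rho = 0, p = 1))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

# Spearman of each row pair (xm[i, ], ym[i, ]); returns rho and p vectors.
.spearman_rows <- function(xm, ym) {
  n <- ncol(xm)
  rx <- t(apply(xm, 1, rank))
  ry <- t(apply(ym, 1, rank))
  rx <- rx - rowMeans(rx)
  ry <- ry - rowMeans(ry)
  den <- sqrt(rowSums(rx^2) * rowSums(ry^2))
  rho <- ifelse(den > 0, rowSums(rx * ry) / den, 0)
  p <- rep(1, length(rho))
  ok <- den > 0 & abs(rho) < 1
  tstat <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[den > 0 & abs(rho) >= 1] <- 0
  list(rho = rho, p = p)
}

#' Link intergenic DEEs to nearby DEGs by eRNA-mRNA correlation
#'
#' For every (DEE, DEG) pair on the same chromosome with the gene TSS
#' within `max_dist` of the enhancer center, computes the Spearman
#' correlation between eRNA and gene expression across the shared
#' samples. Links are retained when rho >= `min_rho` and the
#' Bonferroni-corrected p (family = all tested candidate pairs) is below
#' `max_p`.
#'
#' @param dee DEE calls ([call_dee()] output; `feature_id` = enhancer id).
#' @param deg DEG calls ([call_deg()] output).
#' @param erna_expr eRNA expression matrix (enhancer x sample); any
#'   monotone scale (e.g. log2 FPM).
#' @param gene_expr gene expression matrix (gene x sample).
#' @param enhancers enhancer coordinate table with `enhancer_id` (or
#'   `enh_id`), chrom, start, end.
#' @param genes gene annotation table.
#' @param max_dist center-to-TSS distance gate in bp (default 1e6).
#' @param min_rho minimum Spearman rho, positive only (default 0.7).
#' @param max_p Bonferroni-corrected p threshold (default 0.01).
#' @return list with `links` (retained LinkRecords: enhancer_id, gene_id,
#'   rho, p, p_adj, distance, category), `tested` (all candidates),
#'   `n_tested`, `per_dee` target counts and `per_deg` regulator counts.
#' @export
link_intergenic <- function(dee, deg, erna_expr, gene_expr, enhancers,
                            genes, max_dist = 1e6, min_rho = 0.7,
                            max_p = 0.01) {
  id_col <- if ("enhancer_id" %in% names(enhancers)) "enhancer_id"
            else "enh_id"
  shared <- intersect(colnames(erna_expr), colnames(gene_expr))
  if (length(shared) == 0) stop("no shared samples between matrices",
                                call. = FALSE)
  e_ids <- intersect(dee$feature_id, rownames(erna_expr))
  g_ids <- intersect(deg$feature_id, rownames(gene_expr))
  empty <- data.frame(enhancer_id = character(), gene_id = character(),
                      rho = numeric(), p = numeric(), p_adj = numeric(),
                      distance = numeric(), category = character(),
                      stringsAsFactors = FALSE)
  if (!length(e_ids) || !length(g_ids)) {
    return(list(links = empty, tested = empty, n_tested = 0L,
                per_dee = integer(), per_deg = integer()))
  }
  ei <- match(e_ids, enhancers[[id_col]])
  if (anyNA(ei)) stop("DEE ids missing from enhancer table", call. = FALSE)
  centers <- interval_center(enhancers[ei, ])
  gi <- match(g_ids, genes$gene_id)
  if (anyNA(gi)) stop("DEG ids missing from gene table", call. = FALSE)
  tss <- gene_tss(genes[gi, , drop = FALSE])
  g_chrom <- genes$chrom[gi]

  cand <- list()
  for (a in seq_along(e_ids)) {
    hit <- which(g_chrom == enhancers$chrom[ei[a]] &
                   abs(tss - centers[a]) <= max_dist)
    if (length(hit)) {
      cand[[length(cand) + 1L]] <- data.frame(
        enhancer_id = e_ids[a], gene_id = g_ids[hit],
        distance = tss[hit] - centers[a], stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) {
    return(list(links = empty, tested = empty, n_tested = 0L,
                per_dee = integer(), per_deg = integer()))
  }
  cand <- do.call(rbind, cand)
  sp <- .spearman_rows(erna_expr[cand$enhancer_id, shared, drop = FALSE],
                       gene_expr[cand$gene_id, shared, drop = FALSE])
  cand$rho <- sp$rho
  cand$p <- sp$p
  cand$p_adj <- bonferroni_p(cand$p, m = nrow(cand))
  cand$category <- "intergenic_DEE_DEG"
  links <- cand[cand$rho >= min_rho & cand$p_adj < max_p, , drop = FALSE]
  rownames(links) <- NULL
  cols <- c("enhancer_id", "gene_id", "rho", "p", "p_adj", "distance",
            "category")
  list(links = links[, cols], tested = cand[, cols],
       n_tested = nrow(cand),
       per_dee = table(links$enhancer_id),
       per_deg = table(links$gene_id))
}

# distance from an interval edge to a point (0 when the point is inside)
.edge_distance <- function(start, end, point) {
  ifelse(point < start, start - point,
         ifelse(point >= end, point - end + 1L, 0L))
}

#' Identify genic differentially methylated enhancers and their DEG links
#'
#' A genic catalog enhancer with concurrence >= `min_concurrence` is a
#' DME candidate when some DMR overlaps it by >= `min_overlap` bp, the
#' overlap covers >= `min_overlap_frac` of the enhancer, and >=
#' `min_cpgs` CpGs fall inside the overlap. For each candidate, DEGs
#' with edge-to-TSS distance <= `max_dist` are tested by Spearman
#' correlation between gene expression and the enhancer's mean
#' methylation; links need |rho| >= `min_rho` and BH-FDR <= `max_fdr`
#' (family = all tested candidate pairs). Candidates with no link are
#' dropped.
#'
#' @param catalog merged catalog ([merge_catalog()] output).
#' @param dmrs DMR table (chrom, start, end, direction).
#' @param cpgs CpG position table (chrom, pos).
#' @param deg DEG calls.
#' @param beta CpG x sample beta matrix (rownames matching `cpgs` order).
#' @param gene_expr gene x sample expression matrix.
#' @param genes gene annotation.
#' @param min_concurrence,min_overlap,min_overlap_frac,min_cpgs DME
#'   candidate gates (defaults 2, 200 bp, 0.3, 5).
#' @param max_dist,min_rho,max_fdr link gates (defaults 1 Mb, 0.5, 0.01).
#' @return list with `dme` (candidate table with best-overlap stats,
#'   direction, n_links) and `links` (enhancer_id, gene_id, rho, fdr,
#'   distance, category, dmr_direction, deg_direction).
#' @export
link_genic_dme <- function(catalog, dmrs, cpgs, deg, beta, gene_expr,
                           genes, min_concurrence = 2L,
                           min_overlap = 200L, min_overlap_frac = 0.3,
                           min_cpgs = 5L, max_dist = 1e6, min_rho = 0.5,
                           max_fdr = 0.01) {
  gen <- catalog[catalog$class == "genic" &
                   catalog$concurrence >= min_concurrence, , drop = FALSE]
  empty <- list(
    dme = data.frame(enhancer_id = character(), overlap_bp = integer(),
                     overlap_fraction = numeric(),
                     n_cpgs_overlap = integer(),
                     dmr_direction = character(), n_links = integer(),
                     stringsAsFactors = FALSE),
    links = data.frame(enhancer_id = character(), gene_id = character(),
                       rho = numeric(), p = numeric(), fdr = numeric(),
                       distance = numeric(), category = character(),
                       dmr_direction = character(),
                       deg_direction = character(),
                       stringsAsFactors = FALSE))
  if (nrow(gen) == 0 || nrow(dmrs) == 0 || nrow(deg) == 0) return(empty)

  enh_gr <- bed_to_gr(gen[, c("chrom", "start", "end")])
  dmr_gr <- bed_to_gr(dmrs[, c("chrom", "start", "end")])
  cpg_gr <- GenomicRanges::GRanges(cpgs$chrom,
                                   IRanges::IRanges(cpgs$pos + 1L,
                                                    width = 1L))
  ov <- GenomicRanges::findOverlaps(enh_gr, dmr_gr)
  if (length(ov) == 0) return(empty)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  inter <- GenomicRanges::pintersect(enh_gr[qi], dmr_gr[si])
  ov_bp <- GenomicRanges::width(inter)
  ov_frac <- ov_bp / (gen$end[qi] - gen$start[qi])
  n_cpg_ov <- GenomicRanges::countOverlaps(inter, cpg_gr)
  pass <- ov_bp >= min_overlap & ov_frac >= min_overlap_frac &
    n_cpg_ov >= min_cpgs
  if (!any(pass)) return(empty)
  hits <- data.frame(enh = qi[pass], dmr = si[pass],
                     overlap_bp = ov_bp[pass],
                     overlap_fraction = ov_frac[pass],
                     n_cpgs_overlap = n_cpg_ov[pass])
  # best overlap per candidate enhancer
  best <- do.call(rbind, lapply(split(hits, hits$enh), function(h) {
    h[which.max(h$overlap_bp), , drop = FALSE]
  }))
  cand <- data.frame(
    enhancer_id = gen$enhancer_id[best$enh],
    chrom = gen$chrom[best$enh], start = gen$start[best$enh],
    end = gen$end[best$enh], overlap_bp = best$overlap_bp,
    overlap_fraction = best$overlap_fraction,
    n_cpgs_overlap = best$n_cpgs_overlap,
    dmr_direction = dmrs$direction[best$dmr], stringsAsFactors = FALSE)

  # mean methylation over each candidate enhancer, per sample
  meth <- t(vapply(seq_len(nrow(cand)), function(i) {
    in_enh <- cpgs$chrom == cand$chrom[i] & cpgs$pos >= cand$start[i] &
      cpgs$pos < cand$end[i]
    colMeans(beta[in_enh, , drop = FALSE])
  }, numeric(ncol(beta))))
  rownames(meth) <- cand$enhancer_id

  shared <- intersect(colnames(meth), colnames(gene_expr))
  if (!length(shared)) stop("no shared samples between methylation and ",
                            "expression", call. = FALSE)
  g_ids <- intersect(deg$feature_id, rownames(gene_expr))
  gi <- match(g_ids, genes$gene_id)
  tss <- gene_tss(genes[gi, , drop = FALSE])
  g_chrom <- genes$chrom[gi]
  pairs <- list()
  for (i in seq_len(nrow(cand))) {
    hit <- which(g_chrom == cand$chrom[i] &
                   .edge_distance(cand$start[i], cand$end[i], tss) <=
                     max_dist)
    if (length(hit)) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        enhancer_id = cand$enhancer_id[i], gene_id = g_ids[hit],
        distance = .edge_distance(cand$start[i], cand$end[i], tss[hit]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs)) return(empty)
  pairs <- do.call(rbind, pairs)
  sp <- .spearman_rows(meth[pairs$enhancer_id, shared, drop = FALSE],
                       gene_expr[pairs$gene_id, shared, drop = FALSE])
  pairs$rho <- sp$rho
  pairs$p <- sp$p
  pairs$fdr <- bh_fdr(pairs$p)
  keep <- abs(pairs$rho) >= min_rho & pairs$fdr <= max_fdr
  links <- pairs[keep, , drop = FALSE]
  links$category <- "genic_DME_DEG"
  links$dmr_direction <- cand$dmr_direction[match(links$enhancer_id,
                                                  cand$enhancer_id)]
  di <- match(links$gene_id, deg$feature_id)
  links$deg_direction <- deg$status[di]
  rownames(links) <- NULL

  n_links <- table(links$enhancer_id)
  cand$n_links <- as.integer(n_links[cand$enhancer_id])
  cand$n_links[is.na(cand$n_links)] <- 0L
  dme <- cand[cand$n_links > 0,
              c("enhancer_id", "overlap_bp", "overlap_fraction",
                "n_cpgs_overlap", "dmr_direction", "n_links")]
  rownames(dme) <- NULL
  list(dme = dme,
       links = links[, c("enhancer_id", "gene_id", "rho", "p", "fdr",
                         "distance", "category", "dmr_direction",
                         "deg_direction")])
}

#' Cross DMR direction with DEG direction into the four DME-DEG classes
#'
#' @param dmr_direction `"hyper"` or `"hypo"` (vectorized).
#' @param deg_direction `"up"` or `"down"` (vectorized).
#' @return `"HyperUp"`, `"HyperDown"`, `"HypoUp"` or `"HypoDown"`.
#' @export
classify_dme_deg <- function(dmr_direction, deg_direction) {
  if (!all(dmr_direction %in% c("hyper", "hypo"))) {
    stop("dmr_direction must be 'hyper' or 'hypo'", call. = FALSE)
  }
  if (!all(deg_direction %in% c("up", "down"))) {
    stop("deg_direction must be 'up' or 'down'", call. = FALSE)
  }
  paste0(ifelse(dmr_direction == "hyper", "Hyper", "Hypo"),
         ifelse(deg_direction == "up", "Up", "Down"))
}

#' Flag methylation-associated DEEs
#'
#' A DEE is methylation-associated when it overlaps at least one DMR and
#' the Spearman correlation between its mean enhancer methylation and
#' its eRNA expression is significant at BH-FDR < `max_fdr` (family =
#' all DMR-overlapping DEEs tested).
#'
#' @param dee DEE calls.
#' @param enhancers enhancer coordinate table.
#' @param dmrs DMR table.
#' @param cpgs CpG positions; @param beta CpG x sample matrix.
#' @param erna_expr enhancer x sample eRNA expression.
#' @param links optional intergenic link table to report the flagged
#'   fraction of DEE-DEGs.
#' @param max_fdr significance threshold (default 0.05).
#' @return list with `flagged` (table of flagged DEEs with rho/fdr),
#'   `frac_dees`, and `frac_links` (NA when `links` not given).
#' @export
methylation_associated_dees <- function(dee, enhancers, dmrs, cpgs, beta,
                                        erna_expr, links = NULL,
                                        max_fdr = 0.05) {
  id_col <- if ("enhancer_id" %in% names(enhancers)) "enhancer_id"
            else "enh_id"
  ei <- match(dee$feature_id, enhancers[[id_col]])
  coords <- enhancers[ei, , drop = FALSE]
  n_dmr <- if (nrow(dmrs)) {
    GenomicRanges::countOverlaps(
      bed_to_gr(coords[, c("chrom", "start", "end")]),
      bed_to_gr(dmrs[, c("chrom", "start", "end")]))
  } else rep(0L, nrow(coords))
  tested_i <- which(n_dmr > 0)
  flagged <- data.frame(feature_id = character(), rho = numeric(),
                        fdr = numeric(), stringsAsFactors = FALSE)
  if (length(tested_i)) {
    meth <- t(vapply(tested_i, function(i) {
      in_enh <- cpgs$chrom == coords$chrom[i] &
        cpgs$pos >= coords$start[i] & cpgs$pos < coords$end[i]
      colMeans(beta[in_enh, , drop = FALSE])
    }, numeric(ncol(beta))))
    shared <- intersect(colnames(beta), colnames(erna_expr))
    ids <- dee$feature_id[tested_i]
    sp <- .spearman_rows(meth[, shared, drop = FALSE],
                         erna_expr[ids, shared, drop = FALSE])
    fdr <- bh_fdr(sp$p)
    keep <- which(fdr < max_fdr)
    flagged <- data.frame(feature_id = ids[keep], rho = sp$rho[keep],
                          fdr = fdr[keep], stringsAsFactors = FALSE)
  }
  frac_links <- NA_real_
  if (!is.null(links) && nrow(links) > 0) {
    frac_links <- mean(links$enhancer_id %in% flagged$feature_id)
  }
  list(flagged = flagged,
       frac_dees = if (nrow(dee)) nrow(flagged) / nrow(dee) else NA_real_,
       frac_links = frac_links)
}

#' Histone-modifier coexpression fractions
#'
#' For each differentially expressed histone-modification regulator,
#' reports the fraction of DEEs (by eRNA) and of DEE-DEG genes (by mRNA)
#' whose expression is significantly correlated with the modifier's mRNA
#' (|rho| > `min_rho`, BH-FDR < `max_fdr`; BH family = the respective
#' feature set per modifier).
#'
#' @param modifier_ids gene ids of the pre-filtered modifiers (screened
#'   at |LFC| > 1, FDR < 5\%).
#' @param dee_ids DEE enhancer ids (rows of `erna_expr`).
#' @param link_gene_ids DEE-DEG gene ids (rows of `gene_expr`).
#' @param erna_expr,gene_expr expression matrices.
#' @param min_rho,max_fdr thresholds (defaults 0.5 and 0.05).
#' @return data.frame modifier / frac_dees / frac_deg_links.
#' @export
modifier_coexpression <- function(modifier_ids, dee_ids, link_gene_ids,
                                  erna_expr, gene_expr, min_rho = 0.5,
                                  max_fdr = 0.05) {
  missing_mod <- setdiff(modifier_ids, rownames(gene_expr))
  if (length(missing_mod)) {
    stop("modifier gene(s) absent from expression matrix: ",
         paste(missing_mod, collapse = ", "), call. = FALSE)
  }
  shared <- intersect(colnames(gene_expr), colnames(erna_expr))
  frac_vs <- function(mod, ids, mat) {
    if (!length(ids)) return(NA_real_)
    mv <- matrix(gene_expr[mod, shared], length(ids), length(shared),
                 byrow = TRUE)
    sp <- .spearman_rows(mat[ids, shared, drop = FALSE], mv)
    mean(abs(sp$rho) > min_rho & bh_fdr(sp$p) < max_fdr)
  }
  out <- data.frame(
    modifier = modifier_ids,
    frac_dees = vapply(modifier_ids, frac_vs, numeric(1), dee_ids,
                       erna_expr),
    frac_deg_links = vapply(modifier_ids, frac_vs, numeric(1),
                            unique(link_gene_ids), gene_expr),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Detect super-enhancer clusters among linked DEEs
#'
#' Same-direction DEEs on one chromosome are chained in positional order
#' while the gap to the previous member is <= `max_gap` and the new
#' member shares at least one linked DEG with the chain. Chains with >=
#' `min_dees` members and >= `min_degs` distinct DEGs are reported. In
#' strict mode the DEG set is the intersection over members (every
#' member linked to every reported gene).
#'
#' @param links intergenic LinkRecords (enhancer_id, gene_id).
#' @param enhancers enhancer coordinates.
#' @param dee DEE calls with `status` (activated/repressed).
#' @param max_gap maximum gap between consecutive member enhancers (bp,
#'   default 50000).
#' @param min_dees,min_degs reporting thresholds (default 5 and 5).
#' @param strict require every member to be linked to every reported DEG.
#' @return data.frame: cluster_id, chrom, start, end, direction,
#'   n_dees, n_degs, dee_ids, deg_ids (comma-separated).
#' @export
detect_super_enhancer_clusters <- function(links, enhancers, dee,
                                           max_gap = 50000L,
                                           min_dees = 5L, min_degs = 5L,
                                           strict = FALSE) {
  empty <- data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      direction = character(), n_dees = integer(),
                      n_degs = integer(), dee_ids = character(),
                      deg_ids = character(), stringsAsFactors = FALSE)
  if (nrow(links) == 0) return(empty)
  id_col <- if ("enhancer_id" %in% names(enhancers)) "enhancer_id"
            else "enh_id"
  members <- unique(links$enhancer_id)
  ei <- match(members, enhancers[[id_col]])
  info <- data.frame(
    enhancer_id = members, chrom = enhancers$chrom[ei],
    start = enhancers$start[ei], end = enhancers$end[ei],
    direction = dee$status[match(members, dee$feature_id)],
    stringsAsFactors = FALSE)
  deg_sets <- split(links$gene_id, links$enhancer_id)
  out <- list()
  for (key in split(seq_len(nrow(info)),
                    paste(info$chrom, info$direction))) {
    grp <- info[key, , drop = FALSE]
    grp <- grp[order(grp$start), , drop = FALSE]
    chain <- integer()
    chain_degs <- character()
    flush <- function(chain, chain_degs) {
      if (length(chain) < min_dees) return(NULL)
      degs <- if (strict) {
        Reduce(intersect, deg_sets[grp$enhancer_id[chain]])
      } else {
        unique(unlist(deg_sets[grp$enhancer_id[chain]]))
      }
      if (length(degs) < min_degs) return(NULL)
      data.frame(chrom = grp$chrom[1], start = min(grp$start[chain]),
                 end = max(grp$end[chain]), direction = grp$direction[1],
                 n_dees = length(chain), n_degs = length(degs),
                 dee_ids = paste(grp$enhancer_id[chain], collapse = ","),
                 deg_ids = paste(sort(degs), collapse = ","),
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(grp))) {
      my_degs <- deg_sets[[grp$enhancer_id[i]]]
      extend <- length(chain) > 0 &&
        (grp$start[i] - max(grp$end[chain])) <= max_gap &&
        length(intersect(my_degs, chain_degs)) > 0
      if (extend) {
        chain <- c(chain, i)
        chain_degs <- union(chain_degs, my_degs)
      } else {
        out[[length(out) + 1L]] <- flush(chain, chain_degs)
        chain <- i
        chain_degs <- my_degs
      }
    }
    out[[length(out) + 1L]] <- flush(chain, chain_degs)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res <- data.frame(cluster_id = sprintf("SE%03d", seq_len(nrow(res))),
                    res, row.names = NULL, stringsAsFactors = FALSE)
  res
}
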