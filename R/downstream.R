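# Downstream confirmation and clinical scoring: TAD/loop confirmation of
# enhancer-gene pairs, hypergeometric gene-set enrichment, and the
# six-gene aberrant-enhancer risk score with a log-rank-minimizing
# cutoff.

#' Confirm enhancer-gene links against TADs and chromatin loops
#'
#' A link is TAD-confirmed when the enhancer center and the gene TSS
#' fall inside the same TAD (any one TAD suffices when TADs overlap);
#' loop-confirmed when the enhancer interval overlaps one loop anchor
#' and the TSS falls in the other (either orientation).
#'
#' @param links link table (enhancer_id, gene_id).
#' @param enhancers enhancer coordinates; @param genes gene annotation.
#' @param tads TAD interval table; @param loops BEDPE-style loop table
#'   (may have zero rows).
#' @return data.frame per link with tad_confirmed, loop_confirmed,
#'   confirmed; attribute `summary` holds the confirmation fractions.
#' @export
hic_confirm <- function(links, enhancers, genes, tads,
                        loops = NULL) {
  id_col <- if ("enhancer_id" %in% names(enhancers)) "enhancer_id"
            else "enh_id"
  ei <- match(links$enhancer_id, enhancers[[id_col]])
  gi <- match(links$gene_id, genes$gene_id)
  if (anyNA(ei) || anyNA(gi)) {
    stop("links reference unknown enhancers or genes", call. = FALSE)
  }
  centers <- interval_center(enhancers[ei, , drop = FALSE])
  tss <- gene_tss(genes[gi, , drop = FALSE])
  e_chrom <- enhancers$chrom[ei]
  g_chrom <- genes$chrom[gi]

  tad_gr <- bed_to_gr(tads[, c("chrom", "start", "end")])
  point_hits <- function(chrom, pos) {
    GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L)),
      tad_gr)
  }
  he <- point_hits(e_chrom, centers)
  hg <- point_hits(g_chrom, tss)
  e_tads <- split(S4Vectors::subjectHits(he), S4Vectors::queryHits(he))
  g_tads <- split(S4Vectors::subjectHits(hg), S4Vectors::queryHits(hg))
  tad_conf <- vapply(seq_len(nrow(links)), function(i) {
    length(intersect(e_tads[[as.character(i)]],
                     g_tads[[as.character(i)]])) > 0
  }, logical(1))

  loop_conf <- rep(FALSE, nrow(links))
  if (!is.null(loops) && nrow(loops) > 0) {
    enh_gr <- bed_to_gr(data.frame(chrom = e_chrom,
                                   start = enhancers$start[ei],
                                   end = enhancers$end[ei]))
    tss_gr <- GenomicRanges::GRanges(g_chrom,
                                     IRanges::IRanges(tss + 1L, width = 1L))
    a1 <- bed_to_gr(data.frame(chrom = loops$chrom1, start = loops$start1,
                               end = loops$end1))
    a2 <- bed_to_gr(data.frame(chrom = loops$chrom2, start = loops$start2,
                               end = loops$end2))
    ov <- function(q, s) {
      m <- matrix(FALSE, length(q), length(s))
      h <- GenomicRanges::findOverlaps(q, s)
      m[cbind(S4Vectors::queryHits(h), S4Vectors::subjectHits(h))] <- TRUE
      m
    }
    loop_conf <- rowSums((ov(enh_gr, a1) & ov(tss_gr, a2)) |
                           (ov(enh_gr, a2) & ov(tss_gr, a1))) > 0
  }

  out <- data.frame(enhancer_id = links$enhancer_id,
                    gene_id = links$gene_id,
                    tad_confirmed = tad_conf, loop_confirmed = loop_conf,
                    confirmed = tad_conf | loop_conf,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- c(tad = mean(tad_conf), loop = mean(loop_conf),
                            either = mean(tad_conf | loop_conf))
  out
}

#' Confirm links against several Hi-C topology samples
#'
#' @param links,enhancers,genes as in [hic_confirm()].
#' @param topologies named list; each element a list with `tads` and
#'   optional `loops`.
#' @return list with `per_sample` confirmation tables and `summary`
#'   (per-sample fractions plus `both`/`either` across samples).
#' @export
hic_confirm_multi <- function(links, enhancers, genes, topologies) {
  per <- lapply(topologies, function(tp) {
    hic_confirm(links, enhancers, genes, tp$tads, tp$loops %||% NULL)
  })
  conf <- vapply(per, function(d) d$confirmed,
                 logical(nrow(links)))
  conf <- matrix(conf, nrow = nrow(links))
  summary <- c(vapply(per, function(d) mean(d$confirmed), numeric(1)),
               both = mean(rowSums(conf) == ncol(conf)),
               either = mean(rowSums(conf) > 0))
  list(per_sample = per, summary = summary)
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' Upper-tail test P(X >= k) of drawing `k` set members in a query of
#' size `n` from a background of `N` genes containing `K` set members.
#'
#' @param query_genes character vector (subset of `background`).
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param background character vector of background gene ids.
#' @return data.frame: gene_set, N, K, n, k, p, fdr.
#' @export
hypergeom_enrich <- function(query_genes, gene_sets, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background", call. = FALSE)
  query <- unique(intersect(query_genes, background))
  res <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], background)
    k <- length(intersect(query, set))
    data.frame(gene_set = nm, N = length(background), K = length(set),
               n = length(query), k = k,
               p = stats::phyper(k - 1, length(set),
                                 length(background) - length(set),
                                 length(query), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$fdr <- bh_fdr(res$p)
  rownames(res) <- NULL
  res
}

#' The six-gene aberrant-enhancer risk model
#'
#' Fixed multivariate-Cox-derived coefficients for PLOD2, HOXD9, BOP1,
#' RAB26, KLRK1 and RGL4; overridable for other signatures. The score
#' scale follows whatever normalized-expression scale is supplied, so
#' any absolute cutoff is scale-dependent.
#'
#' @param coefficients named numeric vector of per-gene coefficients.
#' @param cutoff optional fixed risk-score cutoff.
#' @return object of class `risk_model`.
#' @export
risk_model <- function(coefficients = c(PLOD2 = 0.424, HOXD9 = 0.109,
                                        BOP1 = 0.184, RAB26 = -0.134,
                                        KLRK1 = -0.185, RGL4 = -0.0547),
                       cutoff = NULL) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  structure(list(coefficients = coefficients, cutoff = cutoff),
            class = "risk_model")
}

#' Compute per-patient risk scores
#'
#' score = sum over model genes of coefficient x normalized expression.
#'
#' @param expression gene x patient matrix of normalized expression with
#'   gene rownames; must contain every model gene.
#' @param model a [risk_model()].
#' @return named numeric vector of scores (one per patient).
#' @export
risk_score <- function(expression, model = risk_model()) {
  genes <- names(model$coefficients)
  missing_g <- setdiff(genes, rownames(expression))
  if (length(missing_g)) {
    stop("expression matrix is missing model gene(s): ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  }
  colSums(expression[genes, , drop = FALSE] * model$coefficients)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic (observed minus expected events over the
#' pooled event times, hypergeometric variance), referred to a 1-df
#' chi-square.
#'
#' @param time survival/censoring times (> 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @param group two-level grouping vector.
#' @return list with `statistic` (chi-square) and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop("logrank_test: need exactly two non-empty groups", call. = FALSE)
  }
  if (sum(event) < 1) stop("logrank_test: need at least one event",
                           call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd$chisq
  list(statistic = stat, p = stats::pchisq(stat, df = 1,
                                           lower.tail = FALSE))
}

#' Optimal risk-score cutoff by log-rank p minimization
#'
#' Scans candidate cutoffs (the observed scores between the `lower` and
#' `upper` score quantiles), splits patients into high (score > cutoff)
#' and low groups, and picks the cutoff minimizing the log-rank
#' p-value. Candidates leaving either group without an event are
#' skipped; ties are broken toward the cutoff nearest the median score.
#'
#' @param score per-patient risk scores.
#' @param time,event survival data aligned with `score`.
#' @param lower,upper candidate quantile bounds (defaults 0.1 / 0.9).
#' @return list with `cutoff`, `p`, `statistic`, and `group` (factor
#'   high/low per patient).
#' @export
optimal_cutoff <- function(score, time, event, lower = 0.1,
                           upper = 0.9) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  qs <- stats::quantile(score, c(lower, upper), names = FALSE)
  cands <- sort(unique(score[score >= qs[1] & score <= qs[2]]))
  cands <- cands[cands < max(score)]
  if (!length(cands)) {
    stop("optimal_cutoff: no valid candidate cutoffs (degenerate scores)",
         call. = FALSE)
  }
  med <- stats::median(score)
  best <- NULL
  for (cut in cands) {
    grp <- factor(ifelse(score > cut, "high", "low"),
                  levels = c("low", "high"))
    if (sum(event[grp == "high"]) < 1 || sum(event[grp == "low"]) < 1) {
      next
    }
    lr <- logrank_test(time, event, grp)
    if (is.null(best) || lr$p < best$p - 1e-12 ||
        (abs(lr$p - best$p) <= 1e-12 &&
         abs(cut - med) < abs(best$cutoff - med))) {
      best <- list(cutoff = cut, p = lr$p, statistic = lr$statistic,
                   group = grp)
    }
  }
  if (is.null(best)) {
    stop("optimal_cutoff: no candidate leaves events in both groups",
         call. = FALSE)
  }
  best
}
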