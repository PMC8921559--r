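# Paired differential testing: gene expression, eRNA expression, and
# CpG methylation, plus threshold-based calling of DEGs/DEEs/DML/DMRs.

#' Construct a paired tumor/normal feature matrix
#'
#' @param values numeric matrix, features x samples, with rownames and
#'   colnames.
#' @param patient character vector (one per column) of patient ids.
#' @param condition character vector (one per column), `"tumor"` or
#'   `"normal"`; every patient must contribute exactly one of each.
#' @param library_sizes optional named per-sample totals (> 0), required
#'   for [fpm()].
#' @return object of class `paired_matrix`.
#' @export
paired_matrix <- function(values, patient, condition,
                          library_sizes = NULL) {
  stopifnot(is.matrix(values), ncol(values) == length(patient),
            length(patient) == length(condition))
  if (!all(condition %in% c("tumor", "normal"))) {
    stop("condition must be 'tumor' or 'normal'", call. = FALSE)
  }
  tab <- table(patient, condition)
  bad <- rownames(tab)[tab[, "tumor"] != 1 | tab[, "normal"] != 1]
  if (length(bad)) {
    stop("unpaired columns: patient(s) ", paste(bad, collapse = ", "),
         " lack exactly one tumor and one normal sample", call. = FALSE)
  }
  if (!is.null(library_sizes)) {
    if (any(library_sizes <= 0)) {
      stop("library sizes must be positive", call. = FALSE)
    }
    library_sizes <- library_sizes[colnames(values)]
  }
  structure(list(values = values, patient = patient,
                 condition = condition, library_sizes = library_sizes),
            class = "paired_matrix")
}

#' Build a paired_matrix from a count matrix and a sample-info table
#' @param values feature x sample matrix.
#' @param sample_info data.frame with sample_id, patient, condition.
#' @param library_sizes optional named vector.
#' @return a `paired_matrix`.
#' @export
as_paired_matrix <- function(values, sample_info, library_sizes = NULL) {
  idx <- match(colnames(values), sample_info$sample_id)
  if (anyNA(idx)) stop("sample_info is missing some columns", call. = FALSE)
  paired_matrix(values, sample_info$patient[idx],
                sample_info$condition[idx], library_sizes)
}

#' Fragments-per-million normalization
#'
#' FPM = count / library_size * 1e6. Downstream differential tests run on
#' log2(FPM + 1).
#'
#' @param counts feature x sample count matrix.
#' @param library_sizes named per-sample totals (all > 0).
#' @return FPM matrix of the same shape.
#' @export
fpm <- function(counts, library_sizes) {
  ls <- library_sizes[colnames(counts)]
  if (anyNA(ls)) stop("library_sizes missing for some samples",
                      call. = FALSE)
  if (any(ls <= 0)) stop("zero or negative library size", call. = FALSE)
  sweep(counts, 2, ls, "/") * 1e6
}

#' Paired t-test per feature on a tumor/normal matrix
#'
#' For each feature, computes per-patient differences
#' (tumor - normal) on the transformed scale, a paired t-test, and
#' BH-FDR across features. Degenerate features are mapped to p = 1 when
#' every difference is zero and p = 0 when the differences are constant
#' and nonzero (both reported via a message).
#'
#' @param pm a [paired_matrix()]. For count data pass FPM/CPM values and
#'   keep the default log2(x+1) transform; for methylation betas use
#'   `transform = "identity"`.
#' @param transform `"log2p1"` or `"identity"`.
#' @return data.frame: feature_id, effect (mean paired difference, log2
#'   scale for expression / delta-beta for methylation), t, p, fdr,
#'   direction (`up`/`down`/`none` by sign of effect).
#' @export
paired_diff_test <- function(pm, transform = c("log2p1", "identity")) {
  stopifnot(inherits(pm, "paired_matrix"))
  transform <- match.arg(transform)
  n <- length(unique(pm$patient))
  if (n < 3) stop("need >= 3 patient pairs", call. = FALSE)
  x <- pm$values
  if (transform == "log2p1") x <- log2p1(x)
  pats <- unique(pm$patient)
  t_idx <- match(paste0(pats, ".tumor"),
                 paste0(pm$patient, ".", pm$condition))
  n_idx <- match(paste0(pats, ".normal"),
                 paste0(pm$patient, ".", pm$condition))
  d <- x[, t_idx, drop = FALSE] - x[, n_idx, drop = FALSE]
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  tstat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  zero_var <- s == 0
  if (any(zero_var)) {
    p[zero_var & m == 0] <- 1
    p[zero_var & m != 0] <- 0
    message("paired_diff_test: ", sum(zero_var),
            " zero-variance feature(s) mapped to p in {0,1}")
  }
  data.frame(
    feature_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    effect = m, t = tstat, p = p, fdr = bh_fdr(p),
    direction = ifelse(m > 0, "up", ifelse(m < 0, "down", "none")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

.call_differential <- function(results, lfc, fdr, labels) {
  sig <- abs(results$effect) > lfc & results$fdr < fdr
  out <- results[sig, , drop = FALSE]
  out$status <- ifelse(out$effect > 0, labels[1], labels[2])
  rownames(out) <- NULL
  out
}

#' Call differentially expressed enhancers (DEEs) from eRNA results
#'
#' DEE iff |log2 fold change of FPM| > `lfc` (strict) and BH-FDR <
#' `fdr` (strict); activated when the effect is positive, repressed when
#' negative.
#'
#' @param results output of [paired_diff_test()] on the eRNA matrix.
#' @param lfc,fdr thresholds (defaults 0.5 and 0.05).
#' @return subset of `results` with a `status` column
#'   (`activated`/`repressed`).
#' @export
call_dee <- function(results, lfc = 0.5, fdr = 0.05) {
  .call_differential(results, lfc, fdr, c("activated", "repressed"))
}

#' Call differentially expressed genes (DEGs)
#'
#' Same thresholds as [call_dee()] applied to the gene matrix; the
#' stricter histone-modifier screen is obtained with `lfc = 1`.
#'
#' @inheritParams call_dee
#' @return subset of `results` with a `status` column (`up`/`down`).
#' @export
call_deg <- function(results, lfc = 0.5, fdr = 0.05) {
  .call_differential(results, lfc, fdr, c("up", "down"))
}

#' Call differentially methylated loci and regions
#'
#' A DML is a CpG with paired-test BH-FDR < `fdr` and |mean delta-beta|
#' >= `min_delta`. A DMR is a maximal run of >= `min_cpgs`
#' same-direction DMLs whose consecutive genomic gaps are <= `max_gap`
#' bp.
#'
#' @param beta_pm a [paired_matrix()] of beta values (rows = CpGs).
#' @param positions data.frame cpg_id/chrom/pos matching the rows of
#'   `beta_pm`; must be sorted by position within each chromosome.
#' @param min_cpgs minimum DMLs per DMR (default 5).
#' @param max_gap maximum gap between consecutive member DMLs (bp,
#'   default 500).
#' @param min_delta minimum |mean delta-beta| for a DML (default 0.1).
#' @param fdr DML significance threshold (default 0.05).
#' @return list with `dml` (per-CpG results with `is_dml`) and `dmr`
#'   (chrom, start, end, n_cpgs, mean_delta, direction).
#' @export
call_dml_dmr <- function(beta_pm, positions, min_cpgs = 5L,
                         max_gap = 500L, min_delta = 0.1, fdr = 0.05) {
  stopifnot(nrow(positions) == nrow(beta_pm$values))
  for (ch in unique(positions$chrom)) {
    ppos <- positions$pos[positions$chrom == ch]
    if (is.unsorted(ppos)) {
      stop("CpG positions must be sorted within chromosome ", ch,
           call. = FALSE)
    }
  }
  res <- paired_diff_test(beta_pm, transform = "identity")
  res$chrom <- positions$chrom
  res$pos <- positions$pos
  res$is_dml <- res$fdr < fdr & abs(res$effect) >= min_delta
  dml <- res[res$is_dml, , drop = FALSE]
  dmr_rows <- list()
  for (ch in unique(dml$chrom)) {
    d <- dml[dml$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    if (nrow(d) == 0) next
    dir <- ifelse(d$effect > 0, "hyper", "hypo")
    new_run <- c(TRUE, diff(d$pos) > max_gap | dir[-1] != dir[-nrow(d)])
    run_id <- cumsum(new_run)
    for (r in unique(run_id)) {
      idx <- which(run_id == r)
      if (length(idx) >= min_cpgs) {
        dmr_rows[[length(dmr_rows) + 1L]] <- data.frame(
          chrom = ch, start = d$pos[idx[1]],
          end = d$pos[idx[length(idx)]] + 1L,
          n_cpgs = length(idx), mean_delta = mean(d$effect[idx]),
          direction = dir[idx[1]], stringsAsFactors = FALSE
        )
      }
    }
  }
  dmr <- if (length(dmr_rows)) {
    out <- do.call(rbind, dmr_rows)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_cpgs = integer(), mean_delta = numeric(),
               direction = character(), stringsAsFactors = FALSE)
  }
  list(dml = res, dmr = dmr)
}
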