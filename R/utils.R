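#' @keywords internal
"_PACKAGE"

#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
#' @importFrom data.table fread fwrite data.table as.data.table :=
#' @importFrom stats p.adjust pt pchisq phyper rexp rnbinom rnorm runif
#'   quantile median cor setNames complete.cases
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a 0-based half-open interval table to GRanges
#'
#' All on-disk coordinates in this package are BED-style 0-based half-open;
#' GRanges is 1-based closed, so start shifts by +1.
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @return a `GRanges` object carrying any extra columns as metadata.
#' @keywords internal
bed_to_gr <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(extra)) S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  gr
}

#' Convert GRanges back to a 0-based half-open interval table
#' @keywords internal
gr_to_bed <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  rownames(df) <- NULL
  df
}

#' log2(x + 1) transform used for FPM/CPM values
#' @param x numeric vector or matrix.
#' @return transformed values.
#' @export
log2p1 <- function(x) log2(x + 1)

assert_interval_df <- function(df, what = "interval table") {
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    stop(what, " must have columns chrom, start, end", call. = FALSE)
  }
  bad <- which(!(df$start < df$end))
  if (length(bad)) {
    stop(what, ": start must be < end (row ", bad[1], ")", call. = FALSE)
  }
  invisible(df)
}

#' Strand-aware TSS (0-based position) for a gene table
#'
#' @param genes data.frame with `chrom`, `strand`, `tx_start`, `tx_end`
#'   (0-based half-open transcript span).
#' @return integer vector of 0-based TSS positions.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
}

#' Strand-aware promoter windows for a gene table
#'
#' The promoter spans from `upstream` bp upstream to `downstream` bp
#' downstream of the TSS (TSS included in the downstream run), matching
#' `GenomicRanges::promoters()` semantics.
#'
#' @param genes gene table (`gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`), 0-based half-open.
#' @param upstream,downstream window sizes in bp; defaults 1500/500.
#' @return data.frame of promoter intervals (0-based half-open) with
#'   `gene_id`.
#' @export
gene_promoters <- function(genes, upstream = 1500L, downstream = 500L) {
  if (nrow(genes) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), gene_id = character()))
  }
  gr <- bed_to_gr(data.frame(chrom = genes$chrom, start = genes$tx_start,
                             end = genes$tx_end, strand = genes$strand))
  prom <- GenomicRanges::promoters(gr, upstream = upstream,
                                   downstream = downstream)
  out <- gr_to_bed(prom)
  out$gene_id <- genes$gene_id
  out$strand <- NULL
  out
}

#' Midpoint (0-based) of intervals
#' @keywords internal
interval_center <- function(df) {
  as.integer(floor((df$start + df$end) / 2))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Thin wrapper over [stats::p.adjust()] kept as a named step because every
#' calling stage of the pipeline corrects across its own family.
#'
#' @param p numeric vector of raw p-values.
#' @return BH-adjusted values, same order as input.
#' @export
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Bonferroni-corrected p-values with an explicit family size
#'
#' @param p raw p-values.
#' @param m family size; defaults to `length(p)`.
#' @return `pmin(1, m * p)`.
#' @export
bonferroni_p <- function(p, m = length(p)) pmin(1, m * p)
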