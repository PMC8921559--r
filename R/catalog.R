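# Enhancer catalog: per-sample enhancer calls from histone marks or
# chromatin-state annotations, merged across samples with concurrence,
# length/promoter filtering, and genic/intergenic partition.

#' Classify a sample's H3K4me1 peaks as active or primed enhancers
#'
#' An H3K4me1 peak overlapping (>= 1 bp) any H3K27ac peak is an active
#' enhancer; otherwise it is primed. When the sample has no H3K27ac data
#' the state cannot be resolved and every peak is labeled `unknown`
#' (it still counts as an enhancer downstream).
#'
#' @param h3k4me1 interval table (chrom, start, end), 0-based half-open.
#' @param h3k27ac interval table, or NULL when the mark was not profiled.
#' @param sample_id optional label attached to the output.
#' @return data.frame chrom/start/end/state/sample_id.
#' @export
classify_sample_enhancers <- function(h3k4me1, h3k27ac = NULL,
                                      sample_id = NA_character_) {
  assert_interval_df(h3k4me1, "H3K4me1 peaks")
  out <- h3k4me1[, c("chrom", "start", "end")]
  if (is.null(h3k27ac)) {
    out$state <- if (nrow(out)) "unknown" else character()
  } else {
    assert_interval_df(h3k27ac, "H3K27ac peaks")
    if (nrow(out) == 0 || nrow(h3k27ac) == 0) {
      out$state <- rep("primed", nrow(out))
    } else {
      hits <- GenomicRanges::countOverlaps(bed_to_gr(out),
                                           bed_to_gr(h3k27ac))
      out$state <- ifelse(hits > 0, "active", "primed")
    }
  }
  out$sample_id <- rep(sample_id, nrow(out))
  rownames(out) <- NULL
  out
}

#' Ingest a ChromHMM-style state BED as enhancer calls
#'
#' Rows labeled as active enhancers map to state `active`; poised/primed
#' enhancer labels map to `primed`; every other state is dropped (with a
#' message listing the unrecognized labels).
#'
#' @param states interval table with a `name` column holding state labels.
#' @param label_map named character vector mapping state labels to
#'   `active`/`primed`.
#' @param sample_id optional label.
#' @return data.frame chrom/start/end/state/sample_id.
#' @export
ingest_state_bed <- function(states,
                             label_map = c(active_enhancer = "active",
                                           poised_enhancer = "primed",
                                           primed = "primed"),
                             sample_id = NA_character_) {
  if (nrow(states) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), state = character(),
                      sample_id = character()))
  }
  assert_interval_df(states, "state BED")
  if (!"name" %in% names(states)) {
    stop("state BED needs a 4th column with state labels", call. = FALSE)
  }
  mapped <- unname(label_map[states$name])
  dropped <- unique(states$name[is.na(mapped)])
  if (length(dropped)) {
    message("ingest_state_bed: dropping states outside the enhancer ",
            "vocabulary: ", paste(dropped, collapse = ", "))
  }
  keep <- !is.na(mapped)
  out <- states[keep, c("chrom", "start", "end")]
  out$state <- mapped[keep]
  out$sample_id <- rep(sample_id, nrow(out))
  rownames(out) <- NULL
  out
}

#' Merge per-sample enhancer calls into a unified catalog
#'
#' Union-merges all sample enhancers (overlapping or book-ended intervals
#' coalesce), then drops merged intervals shorter than `min_length` bp or
#' overlapping (>= 1 bp) any promoter. Concurrence is the number of
#' distinct samples contributing at least one overlapping source
#' interval. Class is `intergenic` when the merged interval overlaps no
#' gene body, else `genic`.
#'
#' @param sample_enhancers named list of per-sample call tables (as
#'   returned by [classify_sample_enhancers()] / [ingest_state_bed()]).
#' @param genes gene table (may have zero rows).
#' @param min_length minimum merged length in bp (kept when length >=
#'   `min_length`); default 50.
#' @param promoter_upstream,promoter_downstream promoter window around the
#'   TSS, strand-aware.
#' @return data.frame: chrom, start, end, enhancer_id, concurrence, class,
#'   contributing_samples (comma-separated).
#' @export
merge_catalog <- function(sample_enhancers, genes,
                          min_length = 50L,
                          promoter_upstream = 1500L,
                          promoter_downstream = 500L) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), enhancer_id = character(),
                      concurrence = integer(), class = character(),
                      contributing_samples = character(),
                      stringsAsFactors = FALSE)
  if (length(sample_enhancers) == 0) return(empty)
  if (is.null(names(sample_enhancers)) ||
      anyDuplicated(names(sample_enhancers))) {
    names(sample_enhancers) <- sprintf("S%02d",
                                       seq_along(sample_enhancers))
  }
  nonempty <- vapply(sample_enhancers, nrow, integer(1)) > 0
  if (!any(nonempty)) return(empty)
  all_df <- do.call(rbind, lapply(names(sample_enhancers)[nonempty],
                                  function(nm) {
    d <- sample_enhancers[[nm]][, c("chrom", "start", "end")]
    d$src <- nm
    d
  }))
  gr <- bed_to_gr(all_df)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L,
                                  ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(merged, gr)
  src <- split(all_df$src[S4Vectors::subjectHits(ov)],
               S4Vectors::queryHits(ov))
  contributing <- vapply(seq_along(merged), function(i) {
    s <- src[[as.character(i)]]
    paste(sort(unique(s)), collapse = ",")
  }, character(1))
  concurrence <- vapply(strsplit(contributing, ","), length, integer(1))

  cat_df <- gr_to_bed(merged)
  cat_df$concurrence <- concurrence
  cat_df$contributing_samples <- contributing

  keep <- (cat_df$end - cat_df$start) >= min_length
  if (nrow(genes) > 0) {
    prom <- gene_promoters(genes, promoter_upstream, promoter_downstream)
    in_prom <- GenomicRanges::countOverlaps(bed_to_gr(cat_df),
                                            bed_to_gr(prom)) > 0
    keep <- keep & !in_prom
  }
  cat_df <- cat_df[keep, , drop = FALSE]
  if (nrow(cat_df) == 0) return(empty)

  if (nrow(genes) > 0) {
    bodies <- data.frame(chrom = genes$chrom, start = genes$tx_start,
                         end = genes$tx_end)
    genic <- GenomicRanges::countOverlaps(bed_to_gr(cat_df),
                                          bed_to_gr(bodies)) > 0
  } else {
    genic <- rep(FALSE, nrow(cat_df))
  }
  cat_df$class <- ifelse(genic, "genic", "intergenic")
  cat_df <- cat_df[order(cat_df$chrom, cat_df$start), , drop = FALSE]
  cat_df$enhancer_id <- sprintf("enh_%05d", seq_len(nrow(cat_df)))
  rownames(cat_df) <- NULL
  cat_df[, c("chrom", "start", "end", "enhancer_id", "concurrence",
             "class", "contributing_samples")]
}

#' Concurrence histogram of a merged catalog
#'
#' @param catalog output of [merge_catalog()].
#' @param n_samples number of input samples (histogram support 1..n).
#' @return list with `counts` (named vector over 1..n_samples),
#'   `fractions`, and `frac_concurrent` (share with concurrence >= 2).
#' @export
concurrence_histogram <- function(catalog,
                                  n_samples = max(catalog$concurrence)) {
  counts <- vapply(seq_len(n_samples), function(k) {
    sum(catalog$concurrence == k)
  }, integer(1))
  names(counts) <- seq_len(n_samples)
  total <- nrow(catalog)
  fractions <- if (total > 0) counts / total else counts * NA_real_
  list(counts = counts, fractions = fractions,
       frac_concurrent = if (total > 0) {
         sum(catalog$concurrence >= 2) / total
       } else NA_real_)
}

#' Per-sample fraction of long enhancers
#'
#' @param sample_enhancers named list of per-sample call tables.
#' @param threshold length threshold in bp; an enhancer is long when its
#'   length is strictly greater (default 3000).
#' @return data.frame sample_id / n / n_long / fraction, plus attribute
#'   `mean_fraction`.
#' @export
long_enhancer_fraction <- function(sample_enhancers, threshold = 3000L) {
  if (is.null(names(sample_enhancers))) {
    names(sample_enhancers) <- sprintf("S%02d", seq_along(sample_enhancers))
  }
  res <- do.call(rbind, lapply(names(sample_enhancers), function(nm) {
    d <- sample_enhancers[[nm]]
    n <- nrow(d)
    n_long <- sum(d$end - d$start > threshold)
    data.frame(sample_id = nm, n = n, n_long = n_long,
               fraction = if (n > 0) n_long / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  attr(res, "mean_fraction") <- mean(res$fraction, na.rm = TRUE)
  res
}
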