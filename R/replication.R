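# Cross-cohort concurrence of DEEs/DEE-DEG links and platform-aware
# replication of genic DME-DEG pairs, with raw and platform-adjusted
# replication rates.

#' Bundle one cohort's significance calls for concurrence scoring
#'
#' @param dee DEE calls for the cohort (`feature_id`, `status`), e.g.
#'   [call_dee()] output; only significant features are listed.
#' @param deg DEG calls for the cohort.
#' @param links retained intergenic links for the cohort
#'   (`enhancer_id`, `gene_id`), i.e. pairs passing the rho and
#'   Bonferroni gates in that cohort.
#' @return list of class `cohort_result`.
#' @export
cohort_result <- function(dee, deg, links) {
  structure(list(dee = dee, deg = deg, links = links),
            class = "cohort_result")
}

#' Concurrence of discovery DEEs across replication cohorts
#'
#' Concurrence = 1 + the number of cohorts in which the DEE is called
#' significant with the same direction as in discovery (direction-blind
#' counting would inflate concurrence).
#'
#' @param discovery_dee discovery DEE calls (`feature_id`, `status`).
#' @param cohorts list of [cohort_result()] objects, all produced with
#'   the identical calling protocol on the shared enhancer catalog.
#' @return data.frame feature_id / concurrence.
#' @export
dee_concurrence <- function(discovery_dee, cohorts) {
  for (co in cohorts) {
    if (!all(c("feature_id", "status") %in% names(co$dee))) {
      stop("cohort DEE table must carry the shared catalog feature_id ",
           "and status columns", call. = FALSE)
    }
  }
  conc <- vapply(seq_len(nrow(discovery_dee)), function(i) {
    id <- discovery_dee$feature_id[i]
    dir <- discovery_dee$status[i]
    1L + sum(vapply(cohorts, function(co) {
      j <- match(id, co$dee$feature_id)
      !is.na(j) && co$dee$status[j] == dir
    }, logical(1)))
  }, integer(1))
  data.frame(feature_id = discovery_dee$feature_id, concurrence = conc,
             stringsAsFactors = FALSE)
}

#' Concurrence of discovery DEE-DEG links across replication cohorts
#'
#' A cohort counts toward a pair's concurrence when the DEE is
#' significant (same direction), the DEG is significant (same
#' direction), and the pair passes the link criteria in that cohort
#' (i.e. appears among the cohort's retained links).
#'
#' @param discovery list with `dee`, `deg` (calls with `status`) and
#'   `links` (enhancer_id, gene_id) from the discovery cohort.
#' @param cohorts list of [cohort_result()] objects.
#' @return data.frame enhancer_id / gene_id / concurrence.
#' @export
link_concurrence <- function(discovery, cohorts) {
  links <- discovery$links
  key <- function(df) paste(df$enhancer_id, df$gene_id)
  conc <- vapply(seq_len(nrow(links)), function(i) {
    e <- links$enhancer_id[i]
    g <- links$gene_id[i]
    e_dir <- discovery$dee$status[match(e, discovery$dee$feature_id)]
    g_dir <- discovery$deg$status[match(g, discovery$deg$feature_id)]
    1L + sum(vapply(cohorts, function(co) {
      ei <- match(e, co$dee$feature_id)
      gi <- match(g, co$deg$feature_id)
      !is.na(ei) && co$dee$status[ei] == e_dir &&
        !is.na(gi) && co$deg$status[gi] == g_dir &&
        paste(e, g) %in% key(co$links)
    }, logical(1)))
  }, integer(1))
  data.frame(enhancer_id = links$enhancer_id, gene_id = links$gene_id,
             concurrence = conc, stringsAsFactors = FALSE)
}

#' Classify replication outcomes of genic DME-DEG pairs
#'
#' Type I failure: the DME interval contains no CpG covered by the
#' replication platform (e.g. 450k-array sparsity), so the pair could
#' not be tested. Otherwise the pair is a success when differential
#' methylation, differential expression, and the methylation-expression
#' correlation are all significant in the replication cohort; any other
#' covered pair is a type II failure.
#'
#' @param pairs data.frame with enhancer_id, gene_id, chrom, start, end
#'   (DME interval) and `category` (HyperUp/HyperDown/HypoUp/HypoDown).
#' @param platform_cpgs covered CpG positions (chrom, pos).
#' @param replication_stats data.frame aligned with `pairs` (or keyed by
#'   enhancer_id+gene_id) with logical `meth_sig`, `expr_sig`,
#'   `corr_sig`.
#' @return data.frame of ReplicationRecords: enhancer_id, gene_id,
#'   category, covered_cpgs, status (success/type1/type2).
#' @export
classify_replication <- function(pairs, platform_cpgs,
                                 replication_stats) {
  if (!nrow(pairs)) {
    return(data.frame(enhancer_id = character(), gene_id = character(),
                      category = character(), covered_cpgs = integer(),
                      status = character(), stringsAsFactors = FALSE))
  }
  if (!all(c("meth_sig", "expr_sig", "corr_sig") %in%
           names(replication_stats))) {
    stop("replication_stats needs meth_sig, expr_sig, corr_sig",
         call. = FALSE)
  }
  st <- replication_stats
  if (all(c("enhancer_id", "gene_id") %in% names(st))) {
    idx <- match(paste(pairs$enhancer_id, pairs$gene_id),
                 paste(st$enhancer_id, st$gene_id))
    st <- st[idx, , drop = FALSE]
  }
  covered <- if (nrow(platform_cpgs)) {
    GenomicRanges::countOverlaps(
      bed_to_gr(pairs[, c("chrom", "start", "end")]),
      GenomicRanges::GRanges(platform_cpgs$chrom,
                             IRanges::IRanges(platform_cpgs$pos + 1L,
                                              width = 1L)))
  } else rep(0L, nrow(pairs))
  status <- ifelse(covered == 0, "type1",
                   ifelse(st$meth_sig & st$expr_sig & st$corr_sig,
                          "success", "type2"))
  data.frame(enhancer_id = pairs$enhancer_id, gene_id = pairs$gene_id,
             category = pairs$category, covered_cpgs = covered,
             status = status, stringsAsFactors = FALSE)
}

#' Raw and platform-adjusted replication rates per category
#'
#' raw_rate = 100 * successes / total;
#' adjusted_rate = 100 * successes / (successes + type II failures),
#' discounting pairs the platform could not cover at all. Rates are kept
#' in full precision; reports round to 2 decimals. Empty categories get
#' NA rates (with a message), never 0.
#'
#' @param records ReplicationRecords ([classify_replication()] output).
#' @param categories categories to summarize; defaults to those present
#'   plus `"all"`.
#' @return data.frame: category, n_total, n_success, n_type1, n_type2,
#'   raw_rate, adjusted_rate.
#' @export
replication_rates <- function(records,
                              categories = c(sort(unique(
                                records$category)), "all")) {
  one <- function(cat) {
    r <- if (cat == "all") records else
      records[records$category == cat, , drop = FALSE]
    n <- nrow(r)
    ns <- sum(r$status == "success")
    n1 <- sum(r$status == "type1")
    n2 <- sum(r$status == "type2")
    if (n == 0) {
      message("replication_rates: category '", cat,
              "' is empty; rates undefined")
      raw <- adj <- NA_real_
    } else {
      raw <- 100 * ns / n
      adj <- if (ns + n2 > 0) 100 * ns / (ns + n2) else NA_real_
    }
    data.frame(category = cat, n_total = n, n_success = ns,
               n_type1 = n1, n_type2 = n2, raw_rate = raw,
               adjusted_rate = adj, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(categories, one))
  rownames(out) <- NULL
  out
}
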