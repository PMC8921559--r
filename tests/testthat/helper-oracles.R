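# Independent brute-force oracles used to validate the package's
# interval, rank, counting, and survival arithmetic on small instances.

# Per-base union merge of several samples' intervals on one chromosome:
# coverage vector -> maximal covered runs; concurrence = number of
# samples overlapping each run by >= 1 bp. Intervals 0-based half-open.
oracle_merge <- function(sample_intervals, chrom_len = 10000L) {
  cov <- logical(chrom_len)
  for (iv in sample_intervals) {
    for (r in seq_len(nrow(iv))) {
      cov[(iv$start[r] + 1):iv$end[r]] <- TRUE
    }
  }
  runs <- rle(cov)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  out <- data.frame(start = starts[keep] - 1L, end = ends[keep])
  out$concurrence <- vapply(seq_len(nrow(out)), function(i) {
    sum(vapply(sample_intervals, function(iv) {
      any(iv$start < out$end[i] & iv$end > out$start[i])
    }, logical(1)))
  }, integer(1))
  out
}

# Textbook Spearman: average ranks, rho from the rank formula, p from
# the t approximation.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2))
}

# Exhaustive hypergeometric upper tail by enumerating all draws (N <= 12).
oracle_hyper <- function(N, K, n, k) {
  draws <- combn(N, n)
  in_set <- seq_len(K)  # first K elements are set members
  hits <- apply(draws, 2, function(d) sum(d %in% in_set))
  mean(hits >= k)
}

# Textbook two-group log-rank: observed minus expected over event times,
# hypergeometric variance, 1-df chi-square.
oracle_logrank <- function(time, event, group) {
  group <- as.character(group)
  gl <- sort(unique(group))
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == gl[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == gl[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) {
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# Brute-force DMR scan: given DML table (pos sorted, direction), find
# maximal same-direction runs with gaps <= max_gap and >= min_cpgs.
oracle_dmr_scan <- function(pos, direction, max_gap = 500, min_cpgs = 5) {
  if (!length(pos)) return(data.frame(start = integer(), end = integer(),
                                      n = integer()))
  runs <- list()
  cur <- 1L
  for (i in seq_along(pos)[-1]) {
    if (pos[i] - pos[i - 1] > max_gap || direction[i] != direction[i - 1]) {
      runs[[length(runs) + 1L]] <- cur:(i - 1)
      cur <- i
    }
  }
  runs[[length(runs) + 1L]] <- cur:length(pos)
  runs <- runs[vapply(runs, length, integer(1)) >= min_cpgs]
  do.call(rbind, c(list(data.frame(start = integer(), end = integer(),
                                   n = integer())),
                   lapply(runs, function(r) {
                     data.frame(start = pos[r[1]],
                                end = pos[r[length(r)]] + 1L,
                                n = length(r))
                   })))
}

# A small cached default simulation shared by several test files.
sim_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- enhancerAE::simulate_dataset(enhancerAE::sim_config(seed = 101))
    }
    cache
  }
})

# Toy gene table helper
toy_genes <- function(...) {
  rows <- list(...)
  if (!length(rows)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tx_start = integer(),
                      tx_end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], chrom = r[[2]], strand = r[[3]],
               tx_start = as.integer(r[[4]]), tx_end = as.integer(r[[5]]),
               stringsAsFactors = FALSE)
  }))
}

iv <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}
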