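# Readers/writers for the plain-text formats the pipeline exchanges.
# All genomic coordinates on disk are BED-style 0-based half-open.

#' Read a BED3+ peak/interval file
#'
#' Accepts headerless tab-separated BED with at least chrom/start/end;
#' extra columns are kept as `name`, `score`, `strand` when present.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end` (+ optional columns).
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          fill = TRUE, data.table = FALSE)
  if (ncol(dt) < 3) {
    stop("malformed BED file '", path, "': fewer than 3 columns",
         call. = FALSE)
  }
  names(dt)[1:3] <- c("chrom", "start", "end")
  extras <- c("name", "score", "strand")
  if (ncol(dt) > 3) {
    names(dt)[4:min(6, ncol(dt))] <- extras[seq_len(min(3, ncol(dt) - 3))]
  }
  start <- suppressWarnings(as.integer(dt$start))
  end <- suppressWarnings(as.integer(dt$end))
  bad <- which(is.na(start) | is.na(end) | !(start < end))
  if (length(bad)) {
    stop("malformed BED line ", bad[1], " in '", path,
         "': need integer start < end", call. = FALSE)
  }
  dt$start <- start
  dt$end <- end
  dt
}

#' Write an interval table as BED
#' @param df data.frame with chrom/start/end first (extra columns appended).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  keep <- c(c("chrom", "start", "end"),
            setdiff(names(df), c("chrom", "start", "end")))
  data.table::fwrite(df[, keep, drop = FALSE], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 6-column BEDPE loop file
#' @param path file path.
#' @return data.frame chrom1/start1/end1/chrom2/start2/end2.
#' @export
read_bedpe <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer()))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (ncol(dt) < 6) stop("BEDPE '", path, "' needs 6 columns", call. = FALSE)
  dt <- dt[, 1:6]
  names(dt) <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (any(dt$chrom1 != dt$chrom2)) {
    stop("BEDPE '", path, "': loop anchors must share a chromosome",
         call. = FALSE)
  }
  dt
}

#' Write a 6-column BEDPE loop file
#' @param loops data.frame as returned by [read_bedpe()].
#' @param path output path.
#' @export
write_bedpe <- function(loops, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  data.table::fwrite(loops[, cols, drop = FALSE], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with header: gene_id, chrom, strand, tx_start, tx_end
#' (0-based half-open).
#'
#' @param path file path.
#' @return gene data.frame.
#' @export
read_genes <- function(path) {
  g <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  if (!all(need %in% names(g))) {
    stop("gene table '", path, "' must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(g$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  g
}

#' Read a feature-by-sample numeric matrix from TSV
#'
#' First column = feature id; remaining columns = samples.
#'
#' @param path file path.
#' @return numeric matrix with feature rownames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a feature-by-sample matrix to TSV
#' @param m matrix with rownames; @param path output; @param id_col name of
#'   the feature-id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: set name, description, then member genes per line.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed GMT line: ", substr(l, 1, 40), call. = FALSE)
    }
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}

#' Read a survival table (patient, time, status)
#' @param path TSV with header columns patient, time, status (1=event).
#' @return data.frame.
#' @export
read_survival <- function(path) {
  s <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("patient", "time", "status")
  if (!all(need %in% names(s))) {
    stop("survival table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(s$time <= 0)) stop("survival times must be positive", call. = FALSE)
  s
}
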