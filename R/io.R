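# Readers and writers for the plain-text interchange formats: expression /
# time-course TSV (rows = genes, header = sample ids), clinical TSV, CNV TSV,
# bedGraph coverage (0-based half-open), gene-annotation TSV (1-based TSS),
# cell-metadata TSV, and JSON truth/config documents. All parsers reject
# rather than silently coerce malformed input.

#' Read an expression matrix from TSV
#'
#' Expected layout: a header line `gene_id<TAB>sample1<TAB>...`, then one row
#' per gene with numeric log2 values. Round-trips byte-identically with
#' [write_expression_tsv()] for canonical formatting.
#'
#' @param path File path.
#' @return Numeric matrix genes x samples with dimnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop_bad("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop_bad("expression TSV needs >= 2 columns: %s", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop_bad("duplicate gene id '%s' in %s", ids[duplicated(ids)][1], path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_bad("non-numeric value at row %d (gene %s), column %d in %s",
             bad[1], ids[bad[1]], bad[2] + 1L, path)
  }
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' Write an expression matrix to TSV
#'
#' @param expr Genes x samples matrix with dimnames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Required columns: `sample_id`, `time` (>= 0), `event` (0/1); `er_status`
#' optional.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_clinical_tsv <- function(path) {
  if (!file.exists(path)) stop_bad("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop_bad("clinical TSV needs columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop_bad("duplicate sample ids in %s", path)
  if (!is.numeric(df$time) || any(!is.finite(df$time)) || any(df$time < 0))
    stop_bad("clinical 'time' must be finite and >= 0")
  if (!all(df$event %in% c(0, 1)))
    stop_bad("clinical 'event' must be 0 or 1")
  df
}

#' Write a clinical table to TSV
#' @param clinical Data frame with `sample_id`, `time`, `event`, ...
#' @param path Output path.
#' @export
write_clinical_tsv <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a copy-number table from TSV
#'
#' Layout: header `sample_id<TAB>gene...`, one row per sample, integer copy
#' states in \{-2, -1, 0, +1\}.
#'
#' @param path File path.
#' @return Integer matrix samples x genes.
#' @export
read_cnv_tsv <- function(path) {
  if (!file.exists(path)) stop_bad("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop_bad("duplicate sample ids in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (anyNA(m)) stop_bad("non-numeric copy state in %s", path)
  if (!all(m %in% c(-2, -1, 0, 1)))
    stop_bad("copy states must be in {-2,-1,0,+1}: %s", path)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a copy-number table to TSV
#' @param cnv Samples x genes integer matrix.
#' @param path Output path.
#' @export
write_cnv_tsv <- function(cnv, path) {
  df <- data.frame(sample_id = rownames(cnv), cnv, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage file
#'
#' Four tab-separated columns `chrom start end value`, 0-based half-open
#' intervals, no header (a `track` line is tolerated and skipped). Intervals
#' must be non-overlapping within each contig and have `end > start`.
#'
#' @param path File path.
#' @return Data frame `chrom`, `start`, `end`, `value`, sorted by contig and
#'   start.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop_bad("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) stop_bad("empty bedGraph: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop_bad("bedGraph line without 4 tab-separated fields in %s", path)
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L))),
    end = suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L))),
    value = suppressWarnings(as.numeric(vapply(parts, `[`, "", 4L))),
    stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$value))
    stop_bad("non-numeric coordinate or value in %s", path)
  if (any(df$end <= df$start))
    stop_bad("bedGraph interval with end <= start in %s", path)
  if (any(df$value < 0)) stop_bad("negative coverage in %s", path)
  df <- df[order(df$chrom, df$start), ]
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) > 1L && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop_bad("overlapping bedGraph intervals on %s in %s", ch, path)
  }
  rownames(df) <- NULL
  df
}

#' Write a coverage table as bedGraph
#' @param cov Data frame `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(cov, path) {
  utils::write.table(cov[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene-annotation TSV
#'
#' Columns `gene_id`, `chrom`, `tss` (1-based), `strand` (`+`/`-`).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) stop_bad("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(df)))
    stop_bad("annotation needs columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop_bad("duplicate gene ids in %s", path)
  if (!is.numeric(df$tss) || any(df$tss < 1))
    stop_bad("tss must be 1-based positive integers")
  if (!all(df$strand %in% c("+", "-")))
    stop_bad("strand must be '+' or '-'")
  df
}

#' Read single-cell metadata TSV
#'
#' Columns `cell_id`, `dye` (`DiI`/`DiO`), `set_domain_detected`
#' (TRUE/FALSE or 0/1).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_cell_metadata_tsv <- function(path) {
  if (!file.exists(path)) stop_bad("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("cell_id", "dye", "set_domain_detected")
  if (!all(need %in% names(df)))
    stop_bad("cell metadata needs columns %s", paste(need, collapse = ", "))
  if (!all(df$dye %in% c("DiI", "DiO")))
    stop_bad("dye must be 'DiI' or 'DiO'")
  df$set_domain_detected <- as.logical(df$set_domain_detected)
  if (anyNA(df$set_domain_detected))
    stop_bad("set_domain_detected must be logical")
  df
}
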