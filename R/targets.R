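# Classification of PRC2 target genes: promoter mark enrichment, the
# responsive / indirect / nonresponsive partition, early vs late timing,
# rescue status, and TSS density profiles.

#' Promoter signal set
#'
#' Bundles per-condition binned coverage (bedGraph-backed), per-condition
#' scaling factors, and the gene annotation used to locate promoters.
#'
#' @param conditions Named list of coverage data frames (`chrom`, `start`,
#'   `end`, `value`; 0-based half-open intervals) as returned by
#'   [read_bedgraph()].
#' @param annotation Data frame `gene_id`, `chrom`, `tss` (1-based), `strand`
#'   (`"+"`/`"-"`).
#' @param scaling Named numeric scaling factors (> 0) per condition; missing
#'   conditions default to 1 (conventionally e.g. 0.05 for a knockout ChIP
#'   whose immunoprecipitated DNA yield was far lower).
#' @return List of class `promoter_signal_set`.
#' @export
promoter_signal_set <- function(conditions, annotation, scaling = NULL) {
  if (!is.list(conditions) || is.null(names(conditions)))
    stop_bad("'conditions' must be a named list of coverage tables")
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(annotation)))
    stop_bad("annotation needs columns %s", paste(need, collapse = ", "))
  if (!all(annotation$strand %in% c("+", "-")))
    stop_bad("strand must be '+' or '-'")
  sc <- stats::setNames(rep(1, length(conditions)), names(conditions))
  if (!is.null(scaling)) {
    if (any(scaling <= 0)) stop_bad("scaling factors must be > 0")
    sc[names(scaling)] <- scaling
  }
  structure(list(conditions = conditions, annotation = annotation,
                 scaling = sc),
            class = "promoter_signal_set")
}

# Per-contig sorted index over a coverage table for fast window queries.
coverage_index <- function(cov) {
  lapply(split(cov[c("start", "end", "value")], cov$chrom), function(d) {
    d <- d[order(d$start), ]
    list(start = d$start, end = d$end, value = d$value)
  })
}

# Mean coverage of [start, end) (0-based half-open) from an index; uncovered
# bases count as zero.
window_mean_idx <- function(idx, chrom, start, end) {
  stopifnot(end > start)
  d <- idx[[chrom]]
  if (is.null(d)) return(0)
  # intervals are sorted, non-overlapping: candidates have start < end
  j2 <- findInterval(end - 0.5, d$start)
  if (j2 < 1L) return(0)
  j1 <- findInterval(start, d$start)
  j1 <- max(1L, j1)
  sel <- j1:j2
  len <- pmax(0, pmin(d$end[sel], end) - pmax(d$start[sel], start))
  sum(len * d$value[sel]) / (end - start)
}

# Mean coverage of [start, end) (0-based half-open) on one contig; uncovered
# bases count as zero.
coverage_window_mean <- function(cov, chrom, start, end) {
  window_mean_idx(coverage_index(cov), chrom, start, end)
}

# Contig lengths implied by a coverage table (domain assumed to start at 0).
contig_lengths <- function(cov) {
  tapply(cov$end, cov$chrom, max)
}

#' Promoter mark enrichment per gene
#'
#' Computes the mean scaled coverage in the promoter window
#' `[tss - window_bp, tss + window_bp)` for the wild-type and knockout
#' conditions and calls a gene mark-positive iff the wild-type promoter mean
#' is at least `threshold_fold` times the genome-wide background AND at least
#' `threshold_fold` times the knockout promoter mean. Windows exceeding
#' contig bounds are clipped and flagged.
#'
#' @param signals A `promoter_signal_set` containing conditions `wt` and `ko`.
#' @param window_bp Promoter half-window in bp (default 2000).
#' @param threshold_fold Fold-enrichment threshold (default 2).
#' @return Data frame: `gene_id`, `wt_mean`, `ko_mean`, `background`,
#'   `enrichment` (wt over background), `positive`, `clipped`.
#' @export
promoter_enrichment <- function(signals, window_bp = 2000,
                                threshold_fold = 2) {
  stopifnot(inherits(signals, "promoter_signal_set"))
  check_number(window_bp, "window_bp", lower = 0, strict_lower = TRUE)
  if (!all(c("wt", "ko") %in% names(signals$conditions)))
    stop_bad("signals must contain conditions 'wt' and 'ko'")
  ann <- signals$annotation
  wt <- signals$conditions$wt; ko <- signals$conditions$ko
  s_wt <- signals$scaling[["wt"]]; s_ko <- signals$scaling[["ko"]]
  lens <- contig_lengths(wt)
  background <- s_wt * sum((wt$end - wt$start) * wt$value) / sum(lens)
  wt_idx <- coverage_index(wt)
  ko_idx <- coverage_index(ko)
  n <- nrow(ann)
  wm <- km <- numeric(n)
  clipped <- logical(n)
  for (i in seq_len(n)) {
    chrom <- ann$chrom[i]
    tss0 <- ann$tss[i] - 1L  # 1-based TSS -> 0-based coordinate
    w_start <- tss0 - window_bp
    w_end <- tss0 + window_bp
    lim <- if (chrom %in% names(lens)) lens[[chrom]] else w_end
    if (w_start < 0) { w_start <- 0; clipped[i] <- TRUE }
    if (w_end > lim) { w_end <- lim; clipped[i] <- TRUE }
    if (w_end <= w_start) stop_bad("empty promoter window for gene %s",
                                   ann$gene_id[i])
    wm[i] <- s_wt * window_mean_idx(wt_idx, chrom, w_start, w_end)
    km[i] <- s_ko * window_mean_idx(ko_idx, chrom, w_start, w_end)
  }
  data.frame(gene_id = ann$gene_id, wt_mean = wm, ko_mean = km,
             background = background,
             enrichment = if (background > 0) wm / background else Inf,
             positive = wm >= threshold_fold * background &
               wm >= threshold_fold * km,
             clipped = clipped, stringsAsFactors = FALSE)
}

#' Classify genes into responsive / indirect / nonresponsive targets
#'
#' Responsive = up-regulated AND promoter mark-positive; indirect =
#' up-regulated without the mark; nonresponsive = mark-positive but not
#' up-regulated; everything else is null. The four classes partition the
#' gene universe.
#'
#' @param up_set Character vector of up-regulated gene ids.
#' @param promoter_positive_set Character vector of mark-positive gene ids.
#' @param all_genes The gene universe; both sets must be subsets of it.
#' @return List of class `target_classes`: `labels` (named factor over
#'   `all_genes` with levels responsive/indirect/nonresponsive/null) and
#'   `counts` (named integer vector, the Venn counts).
#' @export
classify_targets <- function(up_set, promoter_positive_set, all_genes) {
  if (!all(up_set %in% all_genes) ||
      !all(promoter_positive_set %in% all_genes))
    stop_bad("up/positive sets must be subsets of all_genes")
  up <- all_genes %in% up_set
  pos <- all_genes %in% promoter_positive_set
  lab <- ifelse(up & pos, "responsive",
                ifelse(up & !pos, "indirect",
                       ifelse(pos, "nonresponsive", "null")))
  labels <- factor(lab, levels = c("responsive", "indirect",
                                   "nonresponsive", "null"))
  names(labels) <- all_genes
  counts <- table(labels)
  structure(list(labels = labels,
                 counts = stats::setNames(as.integer(counts),
                                          names(counts))),
            class = "target_classes")
}

#' Construct a time-course expression matrix
#'
#' @param values Genes x columns matrix of log2 expression.
#' @param times Timepoint of each column (time 0 must be present).
#' @param replicates Replicate label of each column.
#' @return Matrix with attributes `times` and `replicates`, class
#'   `timecourse_matrix`.
#' @export
timecourse_matrix <- function(values, times, replicates) {
  values <- as.matrix(values)
  if (length(times) != ncol(values) || length(replicates) != ncol(values))
    stop_bad("times/replicates must match the number of columns")
  if (!0 %in% times) stop_bad("timepoint 0 must be present")
  colnames(values) <- paste0("t", times, "_r", replicates)
  structure(values, times = as.numeric(times),
            replicates = as.character(replicates),
            class = c("timecourse_matrix", "matrix", "array"))
}

#' Normalize a time course to its initial values
#'
#' Per gene and replicate, expression is expressed relative to time 0:
#' a ratio on the linear scale, equivalently a difference on the log2 scale.
#'
#' @param tc A `timecourse_matrix`.
#' @param scale `"log2"` (input is log2; output is log2 ratios, default) or
#'   `"linear"` (input is linear; output is ratios; zero time-0 values are an
#'   error naming the gene).
#' @return Matrix of the same shape, normalized so every time-0 column is 0
#'   (log2) or 1 (linear).
#' @export
normalize_timecourse <- function(tc, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  times <- attr(tc, "times"); reps <- attr(tc, "replicates")
  if (is.null(times)) stop_bad("input must be a timecourse_matrix")
  out <- unclass(tc)
  for (r in unique(reps)) {
    t0_col <- which(times == 0 & reps == r)
    if (length(t0_col) != 1L)
      stop_bad("replicate %s must have exactly one time-0 column", r)
    base <- out[, t0_col]
    if (scale == "linear") {
      zero <- base == 0
      if (any(zero))
        stop_bad("zero time-0 value for gene %s",
                 rownames(tc)[which(zero)[1]])
      out[, reps == r] <- out[, reps == r] / base
    } else {
      out[, reps == r] <- out[, reps == r] - base
    }
  }
  structure(out, times = times, replicates = reps,
            class = class(tc))
}

# Per-replicate log2 fold-change matrix of timepoint `t` vs time 0.
timecourse_fold_changes <- function(tc, t) {
  times <- attr(tc, "times"); reps <- attr(tc, "replicates")
  if (!t %in% times) stop_bad("timepoint %g not present in time course", t)
  fc <- sapply(unique(reps), function(r) {
    tc[, which(times == t & reps == r)[1]] -
      tc[, which(times == 0 & reps == r)[1]]
  })
  rownames(fc) <- rownames(tc)
  fc
}

#' Classify responsive genes as early or late
#'
#' A responsive gene is "early" iff it already passes the differential call
#' (rank-product pfp and fold-change gates) at `early_timepoint` versus time
#' 0; otherwise it is "late". Genes outside the responsive set get NA.
#'
#' @param tc A `timecourse_matrix` of log2 expression.
#' @param responsive_set Character vector of responsive gene ids.
#' @param early_timepoint The early timepoint (must be in the time course).
#' @param de_rule List with `pfp_max`, `fc_min`, `B`, `seed` controlling the
#'   differential call (defaults 0.15, 2, 200, 1).
#' @return Named factor over the genes of `tc` with levels
#'   `c("early", "late")`; NA off the responsive set.
#' @export
classify_early_late <- function(tc, responsive_set, early_timepoint,
                                de_rule = list()) {
  rule <- utils::modifyList(list(pfp_max = 0.15, fc_min = 2, B = 200L,
                                 seed = 1L), de_rule)
  fc <- timecourse_fold_changes(tc, early_timepoint)
  rp <- rank_product(fc, B = rule$B, seed = rule$seed, direction = "up")
  up_early <- call_differential(rp, fc, pfp_max = rule$pfp_max,
                                fc_min = rule$fc_min)
  genes <- rownames(tc)
  timing <- rep(NA_character_, length(genes))
  resp <- genes %in% responsive_set
  timing[resp] <- ifelse(genes[resp] %in% up_early, "early", "late")
  out <- factor(timing, levels = c("early", "late"))
  names(out) <- genes
  out
}

#' Classify responsive genes as rescued or not
#'
#' A responsive gene is "non_rescued" iff it is still called up-regulated in
#' the rescue condition versus wild type under the differential rule;
#' otherwise it is "rescued".
#'
#' @param expr_wt,expr_rescue Genes x replicates log2 expression matrices for
#'   the wild-type and rescue conditions (matched genes and replicates).
#' @param responsive_set Character vector of responsive gene ids.
#' @param de_rule As in [classify_early_late()].
#' @return Named factor with levels `c("rescued", "non_rescued")`; NA off the
#'   responsive set.
#' @export
classify_rescue <- function(expr_wt, expr_rescue, responsive_set,
                            de_rule = list()) {
  rule <- utils::modifyList(list(pfp_max = 0.15, fc_min = 2, B = 200L,
                                 seed = 1L), de_rule)
  if (!identical(dim(expr_wt), dim(expr_rescue)))
    stop_bad("wild-type and rescue matrices must have matching dimensions")
  fc <- as.matrix(expr_rescue) - as.matrix(expr_wt)
  rownames(fc) <- rownames(expr_wt)
  rp <- rank_product(fc, B = rule$B, seed = rule$seed, direction = "up")
  still_up <- call_differential(rp, fc, pfp_max = rule$pfp_max,
                                fc_min = rule$fc_min)
  genes <- rownames(expr_wt)
  lab <- rep(NA_character_, length(genes))
  resp <- genes %in% responsive_set
  lab[resp] <- ifelse(genes[resp] %in% still_up, "non_rescued", "rescued")
  out <- factor(lab, levels = c("rescued", "non_rescued"))
  names(out) <- genes
  out
}

#' Mean mark density profile around transcription start sites
#'
#' Strand-oriented binned coverage around the TSS, averaged across a gene
#' set; upstream is on the left. Minus-strand windows are mirrored so the
#' profile is oriented in the direction of transcription.
#'
#' @param signals A `promoter_signal_set`.
#' @param gene_set Non-empty character vector of gene ids.
#' @param window_bp Half-window in bp (default 5000).
#' @param bin_bp Bin width in bp (default 100); must divide `2 * window_bp`.
#' @param condition Which condition's coverage to profile (default `"wt"`).
#' @return Data frame: `offset` (bin center relative to the TSS, negative =
#'   upstream) and `density` (mean scaled coverage across genes).
#' @export
tss_density_profile <- function(signals, gene_set, window_bp = 5000,
                                bin_bp = 100, condition = "wt") {
  stopifnot(inherits(signals, "promoter_signal_set"))
  if (length(gene_set) == 0L) stop_bad("empty gene set")
  if ((2 * window_bp) %% bin_bp != 0)
    stop_bad("bin_bp must divide 2*window_bp")
  ann <- signals$annotation
  miss <- setdiff(gene_set, ann$gene_id)
  if (length(miss)) stop_bad("genes missing from annotation: %s",
                             paste(utils::head(miss, 5), collapse = ", "))
  cov <- signals$conditions[[condition]]
  if (is.null(cov)) stop_bad("condition '%s' not in signal set", condition)
  sc <- signals$scaling[[condition]]
  n_bins <- as.integer(2 * window_bp / bin_bp)
  idx <- coverage_index(cov)
  prof <- matrix(NA_real_, nrow = length(gene_set), ncol = n_bins)
  for (i in seq_along(gene_set)) {
    a <- ann[ann$gene_id == gene_set[i], ]
    tss0 <- a$tss - 1L
    starts <- tss0 - window_bp + (seq_len(n_bins) - 1L) * bin_bp
    vals <- vapply(starts, function(s)
      sc * window_mean_idx(idx, a$chrom, s, s + bin_bp), numeric(1))
    if (a$strand == "-") vals <- rev(vals)
    prof[i, ] <- vals
  }
  offsets <- -window_bp + (seq_len(n_bins) - 0.5) * bin_bp
  data.frame(offset = offsets, density = colMeans(prof))
}
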