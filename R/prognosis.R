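# Proliferation-metagene adjustment of a marker transcript and the
# stratification helpers used by the cohort survival analyses.

#' Proliferation metagene
#'
#' Per-sample median of a set of proliferation-associated transcripts, used as
#' a molecular readout of proliferation. The canonical set in the literature
#' contains 54 transcripts; the gene list is a user input.
#'
#' @param expr Expression matrix, genes x samples (rownames = gene ids,
#'   colnames = sample ids), log2 values.
#' @param prolif_genes Character vector of proliferation gene ids; all must be
#'   present in `expr`.
#' @return Named numeric vector (names = sample ids) of per-sample medians.
#' @export
compute_metagene <- function(expr, prolif_genes) {
  if (is.null(rownames(expr))) stop_bad("'expr' must have gene rownames")
  missing_g <- setdiff(prolif_genes, rownames(expr))
  if (length(missing_g))
    stop_bad("proliferation genes missing from expression matrix: %s",
             paste(missing_g, collapse = ", "))
  sub <- expr[prolif_genes, , drop = FALSE]
  apply(sub, 2, stats::median)
}

#' Adjust a marker transcript to the proliferation metagene
#'
#' Ordinary least-squares residualization: fits
#' `marker ~ beta0 + beta1 * metagene` and returns the residuals, the
#' proliferation-independent component of the marker.
#'
#' @param marker Named per-sample marker values (log2).
#' @param metagene Named per-sample metagene values, same samples.
#' @return List of class `adjusted_expression`: `residuals` (named),
#'   `intercept`, `slope`, `fitted`.
#' @export
adjust_to_metagene <- function(marker, metagene) {
  if (length(marker) != length(metagene))
    stop_bad("'marker' and 'metagene' must have equal length")
  if (!is.null(names(marker)) && !is.null(names(metagene))) {
    if (!all(names(marker) == names(metagene))) {
      if (!setequal(names(marker), names(metagene)))
        stop_bad("sample ids of marker and metagene do not match")
      metagene <- metagene[names(marker)]
    }
  }
  p <- as.numeric(metagene); y <- as.numeric(marker)
  vp <- stats::var(p)
  if (!is.finite(vp) || vp == 0)
    stop_bad("metagene has zero variance: degenerate fit")
  b1 <- stats::cov(y, p) / vp
  b0 <- mean(y) - b1 * mean(p)
  fit <- b0 + b1 * p
  r <- y - fit
  names(r) <- names(marker)
  structure(list(residuals = r, intercept = b0, slope = b1, fitted = fit),
            class = "adjusted_expression")
}

#' Median split into low/high groups
#'
#' `high` = strictly above the median; ties at the median are assigned to
#' `low` (a deterministic, documented convention).
#'
#' @param values Per-sample scalars, length >= 2, not all identical.
#' @return Factor with levels `c("low", "high")`, names preserved.
#' @export
median_stratify <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 2L) stop_bad("need >= 2 samples to stratify")
  if (length(unique(v)) == 1L)
    stop_bad("all values identical: no stratification possible")
  med <- stats::median(v)
  f <- factor(ifelse(v > med, "high", "low"), levels = c("low", "high"))
  names(f) <- names(values)
  f
}

#' Stratify samples by per-gene copy-number state
#'
#' Maps integer copy states to groups: -2 and -1 (homozygous/hemizygous
#' loss) to `loss`, 0 to `neutral`, +1 to `gain`.
#'
#' @param cnv_gene Per-sample integer states in \{-2, -1, 0, +1\}.
#' @return Factor with levels `c("loss", "neutral", "gain")` (unused levels
#'   dropped), names preserved.
#' @export
stratify_by_cnv <- function(cnv_gene) {
  s <- as.numeric(cnv_gene)
  if (!all(s %in% c(-2, -1, 0, 1)))
    stop_bad("unknown copy-number code: states must be in {-2,-1,0,+1}")
  f <- factor(ifelse(s <= -1, "loss", ifelse(s == 0, "neutral", "gain")),
              levels = c("loss", "neutral", "gain"))
  f <- droplevels(f)
  names(f) <- names(cnv_gene)
  f
}

#' Marker prognosis before and after proliferation adjustment
#'
#' Convenience wrapper running the full marker workflow on a cohort:
#' metagene, OLS adjustment, median splits of the raw and adjusted marker,
#' log-rank tests and HR(high vs low) for both, plus ROC AUC against the
#' event indicator.
#'
#' @param expr Expression matrix (genes x samples).
#' @param clinical Data frame with `sample_id`, `time`, `event` (samples must
#'   be a subset of the expression columns; extra columns like `er_status`
#'   may be used to pre-filter before calling).
#' @param marker_gene Marker gene id (row of `expr`).
#' @param prolif_genes Proliferation gene-set ids.
#' @return List with `metagene`, `adjusted`, and for each of
#'   `raw`/`adjusted`: group factor, `logrank_result`, `hr_high_vs_low`, and
#'   `auc`.
#' @export
marker_prognosis <- function(expr, clinical, marker_gene, prolif_genes) {
  if (!marker_gene %in% rownames(expr))
    stop_bad("marker gene '%s' not in expression matrix", marker_gene)
  idx <- match(clinical$sample_id, colnames(expr))
  if (anyNA(idx)) stop_bad("clinical samples missing from expression matrix")
  marker <- expr[marker_gene, idx]
  mg <- compute_metagene(expr[, idx, drop = FALSE], prolif_genes)
  adj <- adjust_to_metagene(marker, mg)
  one <- function(v) {
    grp <- median_stratify(v)
    # report HR as (O_high/E_high)/(O_low/E_low): order levels high first
    lr <- logrank_test(clinical$time, clinical$event,
                       factor(grp, levels = c("high", "low")))
    list(groups = grp, logrank = lr, hr_high_vs_low = unname(lr$hr),
         auc = roc_auc(v, clinical$event))
  }
  list(metagene = mg, adjusted = adj,
       raw = one(marker), adjusted_marker = one(adj$residuals))
}
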