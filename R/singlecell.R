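# Single-cell derepression analysis: genotype/color consistency filtering,
# per-genotype detection frequencies, and the concordance statistic
# separating deterministic (all-or-none) from stochastic (combinatorial)
# activation of a gene set.

#' Assign genotypes from dye label and enzyme-assay channel
#'
#' Wild-type cells were labeled with DiI and carry an intact catalytic
#' (SET-domain) transcript; knockout cells were labeled with DiO and lack it.
#' A cell is kept as `wt` iff DiI AND SET-domain detected, as `ko` iff DiO
#' AND SET-domain undetected; every other combination is dropped with a
#' logged reason (only cells with matching genotype/color assignments enter
#' the analysis).
#'
#' @param cell_meta Data frame with columns `cell_id`, `dye` (`"DiI"` /
#'   `"DiO"`) and `set_domain_detected` (logical).
#' @return Data frame: `cell_id`, `dye`, `set_domain_detected`, `genotype`
#'   (`"wt"`/`"ko"`/NA), `kept`, `drop_reason`.
#' @export
assign_genotype <- function(cell_meta) {
  need <- c("cell_id", "dye", "set_domain_detected")
  if (!all(need %in% names(cell_meta)))
    stop_bad("cell metadata needs columns %s", paste(need, collapse = ", "))
  if (!all(cell_meta$dye %in% c("DiI", "DiO")))
    stop_bad("dye must be 'DiI' or 'DiO'")
  det <- as.logical(cell_meta$set_domain_detected)
  wt <- cell_meta$dye == "DiI" & det
  ko <- cell_meta$dye == "DiO" & !det
  genotype <- ifelse(wt, "wt", ifelse(ko, "ko", NA_character_))
  reason <- ifelse(wt | ko, NA_character_,
                   ifelse(cell_meta$dye == "DiI",
                          "DiI dye but no SET-domain transcript",
                          "DiO dye but SET-domain transcript detected"))
  data.frame(cell_id = cell_meta$cell_id, dye = cell_meta$dye,
             set_domain_detected = det, genotype = genotype,
             kept = wt | ko, drop_reason = reason,
             stringsAsFactors = FALSE)
}

#' Binary detection matrix
#'
#' @param scm Genes x cells matrix of log2 expression with 0 meaning
#'   undetected.
#' @param threshold Detection threshold on log2 expression (default 0, the
#'   qPCR limit-of-detection convention): detected iff value > threshold.
#' @return Logical genes x cells matrix.
#' @export
detection_matrix <- function(scm, threshold = 0) {
  check_number(threshold, "threshold", lower = 0)
  m <- as.matrix(scm)
  if (any(m < 0)) stop_bad("expression values must be >= 0")
  m > threshold
}

#' Per-gene detection frequency by genotype
#'
#' Fraction of cells in which each gene is detected, per genotype, with the
#' wt-vs-ko difference and an exact (Clopper-Pearson) binomial confidence
#' interval on each frequency.
#'
#' @param binary Logical genes x cells detection matrix.
#' @param genotypes Per-cell genotype labels (`"wt"`/`"ko"`); each genotype
#'   must have >= 1 cell.
#' @param conf_level Confidence level for the per-frequency intervals
#'   (default 0.95).
#' @return Data frame per gene: `gene`, `freq_wt`, `freq_ko`, `diff`
#'   (ko - wt), and CI bounds `wt_lo`, `wt_hi`, `ko_lo`, `ko_hi`.
#' @export
expression_frequency <- function(binary, genotypes, conf_level = 0.95) {
  g <- as.character(genotypes)
  if (length(g) != ncol(binary))
    stop_bad("'genotypes' must match the number of cells")
  for (lev in c("wt", "ko"))
    if (sum(g == lev) == 0L) stop_bad("empty genotype: %s", lev)
  a <- (1 - conf_level) / 2
  ci <- function(x, n) {
    lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
    c(lo, hi)
  }
  n_wt <- sum(g == "wt"); n_ko <- sum(g == "ko")
  res <- lapply(seq_len(nrow(binary)), function(i) {
    x_wt <- sum(binary[i, g == "wt"]); x_ko <- sum(binary[i, g == "ko"])
    ci_w <- ci(x_wt, n_wt); ci_k <- ci(x_ko, n_ko)
    data.frame(gene = rownames(binary)[i] %||% as.character(i),
               freq_wt = x_wt / n_wt, freq_ko = x_ko / n_ko,
               diff = x_ko / n_ko - x_wt / n_wt,
               wt_lo = ci_w[1], wt_hi = ci_w[2],
               ko_lo = ci_k[1], ko_hi = ci_k[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Concordance statistic for all-or-none vs combinatorial expression
#'
#' For a gene set G and per-cell expressed fraction
#' \eqn{f_c = |\{g \in G: detected\}| / |G|}, the statistic is
#' \deqn{S = 1 - \frac{mean_c[f_c (1 - f_c)]}{\bar f (1 - \bar f)(1 - 1/|G|)}}
#' with \eqn{\bar f} the pooled detection rate. S = 1 exactly when every cell
#' expresses all or none of the genes (deterministic, concerted activation);
#' S is near 0 when genes turn on independently across cells (combinatorial,
#' probabilistic activation). Significance is assessed against a null that
#' permutes each gene's detection pattern independently across cells,
#' preserving per-gene rates while breaking between-gene coupling.
#'
#' @param binary Logical genes x cells detection matrix.
#' @param gene_set Gene ids (>= 2) to score; must be rows of `binary`.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed for the permutation null (required).
#' @return List of class `concordance_result`: `statistic`, `p_value`
#'   (one-sided, \eqn{(1 + \#\{S_{perm} \ge S\})/(B+1)}), `cell_fractions`,
#'   `pooled_rate`, `n_genes`, `n_cells`, `B`.
#' @export
concordance_score <- function(binary, gene_set = rownames(binary),
                              B = 1000L, seed) {
  seed <- check_seed(seed)
  if (length(gene_set) < 2L) stop_bad("need a gene set of >= 2 genes")
  if (is.null(rownames(binary)) && is.character(gene_set))
    stop_bad("binary matrix must have gene rownames")
  sub <- binary[gene_set, , drop = FALSE]
  G <- nrow(sub); n <- ncol(sub)
  stat <- function(m) {
    f_c <- colMeans(m)
    fbar <- mean(f_c)
    denom <- fbar * (1 - fbar) * (1 - 1 / G)
    if (denom == 0) return(NA_real_)
    1 - mean(f_c * (1 - f_c)) / denom
  }
  S <- stat(sub)
  if (is.na(S))
    stop_bad("pooled detection rate is 0 or 1: statistic undefined")
  S_perm <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      perm <- sub
      for (i in seq_len(G)) perm[i, ] <- sub[i, sample.int(n)]
      stat(perm)
    }, numeric(1))
  })
  p <- (1 + sum(S_perm >= S, na.rm = TRUE)) / (B + 1)
  structure(list(statistic = S, p_value = p, cell_fractions = colMeans(sub),
                 pooled_rate = mean(sub), n_genes = G, n_cells = n, B = B),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "Concordance over %d genes x %d cells: S = %.4f, permutation p = %.4g (B = %d)\n",
    x$n_genes, x$n_cells, x$statistic, x$p_value, x$B))
  invisible(x)
}
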