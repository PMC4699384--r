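# Rank-product differential-expression statistic with a permutation-based
# estimate of the percentage of false positives (pfp).

#' Rank-product test
#'
#' For each gene, ranks its fold change within each replicate (rank 1 =
#' strongest change in the requested direction, ties broken by average rank)
#' and forms the geometric mean of the per-replicate ranks,
#' \eqn{RP_g = (\prod_i r_{g,i})^{1/k}}. Significance is assessed by
#' permuting the rank vector independently within each replicate: the
#' expected number of genes attaining an equal or smaller RP under the null,
#' divided by the gene's position in the observed RP ordering, gives the pfp
#' (estimated percentage of false positives, an FDR-like quantity).
#'
#' @param fold_changes Numeric matrix, genes x replicates, of per-replicate
#'   log2 fold changes (rownames = gene ids); `k >= 2` replicates required.
#' @param B Number of permutations (>= 100).
#' @param seed Integer seed for the permutation null (required).
#' @param direction `"up"` (rank 1 = largest fold change, default) or
#'   `"down"`.
#' @return Data frame of class `rank_product_result`: `gene`, `rp`, `pfp`,
#'   `direction`, ordered as the input.
#' @export
rank_product <- function(fold_changes, B = 1000L, seed,
                         direction = c("up", "down")) {
  direction <- match.arg(direction)
  fc <- as.matrix(fold_changes)
  if (ncol(fc) < 2L) stop_bad("need k >= 2 replicates")
  if (B < 100L) stop_bad("need B >= 100 permutations")
  seed <- check_seed(seed)
  n <- nrow(fc)
  sgn <- if (direction == "up") -1 else 1
  ranks <- apply(sgn * fc, 2, rank, ties.method = "average")
  rp <- exp(rowMeans(log(ranks)))
  perm_rp <- with_seed(seed, {
    out <- numeric(n * B)
    for (b in seq_len(B)) {
      pr <- apply(ranks, 2, sample)  # permute each replicate's ranks
      out[((b - 1) * n + 1):(b * n)] <- exp(rowMeans(log(pr)))
    }
    out
  })
  perm_sorted <- sort(perm_rp)
  # expected false positives at each observed RP, then divide by position
  efp <- findInterval(rp, perm_sorted) / B
  pos <- rank(rp, ties.method = "max")
  pfp <- efp / pos
  out <- data.frame(gene = rownames(fc) %||% as.character(seq_len(n)),
                    rp = rp, pfp = pfp, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("rank_product_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call differentially up-regulated genes
#'
#' A gene is called up-regulated iff its geometric-mean fold change across
#' replicates is at least `fc_min` AND its rank-product pfp is at most
#' `pfp_max`. Defaults follow the convention of a minimum adjusted p-value of
#' 15% and a minimum fold change of two.
#'
#' @param rp A `rank_product_result` (direction `"up"`).
#' @param fold_changes The genes x replicates log2 fold-change matrix used
#'   for `rp`.
#' @param pfp_max Maximum pfp (default 0.15).
#' @param fc_min Minimum linear-scale fold change (default 2); the gate uses
#'   the geometric mean across replicates, i.e. `2^mean(log2 FC)`.
#' @return Character vector of up-regulated gene ids.
#' @export
call_differential <- function(rp, fold_changes, pfp_max = 0.15, fc_min = 2) {
  if (pfp_max <= 0 || fc_min <= 0) stop_bad("thresholds must be > 0")
  fc <- as.matrix(fold_changes)
  gm_fc <- 2^rowMeans(fc)
  idx <- match(rp$gene, rownames(fc) %||% as.character(seq_len(nrow(fc))))
  up <- gm_fc[idx] >= fc_min & rp$pfp <= pfp_max
  rp$gene[up]
}
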