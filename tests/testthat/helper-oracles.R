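# Independent oracles used across the suite: brute-force or enumeration
# implementations kept deliberately naive and separate from the package's
# code paths.

# Two-group log-rank chi-square by explicit per-event-time tabulation.
logrank_chisq_oracle <- function(times, events, groups) {
  g <- as.character(groups)
  lev <- sort(unique(g))
  stopifnot(length(lev) == 2)
  obs_minus_exp <- 0
  var_sum <- 0
  for (t in sort(unique(times[events == 1]))) {
    at <- times >= t
    n <- sum(at)
    n1 <- sum(at & g == lev[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == lev[1])
    obs_minus_exp <- obs_minus_exp + d1 - d * n1 / n
    if (n > 1)
      var_sum <- var_sum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  obs_minus_exp^2 / var_sum
}

# Naive Efron partial log-likelihood (loops everywhere).
cox_loglik_naive <- function(beta, times, events, x) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    xr <- x[times >= t]
    xd <- x[times == t & events == 1]
    d <- length(xd)
    s0 <- sum(exp(beta * xr))
    s0d <- sum(exp(beta * xd))
    ll <- ll + beta * sum(xd)
    for (l in seq_len(d) - 1) ll <- ll - log(s0 - (l / d) * s0d)
  }
  ll
}

# Grid/golden-section maximization of the naive partial likelihood.
cox_beta_oracle <- function(times, events, x, lower = -5, upper = 5) {
  stats::optimize(function(b) cox_loglik_naive(b, times, events, x),
                  c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}

# BH q-values straight from the definition, O(m^2).
bh_oracle <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    cand <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) m * p[j] / sum(p <= p[j]) else Inf
    }, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# AUC by all-pairs counting with half credit for ties.
auc_pairs_oracle <- function(marker, y) {
  pos <- marker[y == 1]; neg <- marker[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Exhaustive rank-product pfp for k = 2 replicates and small n: enumerate
# every pair of rank permutations as the null.
pfp_exhaustive_oracle <- function(fc) {
  stopifnot(ncol(fc) == 2, nrow(fc) <= 5)
  n <- nrow(fc)
  ranks <- apply(-fc, 2, rank, ties.method = "average")
  rp <- sqrt(ranks[, 1] * ranks[, 2])
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(z) !anyDuplicated(z)), ,
                 drop = FALSE]
  null_rp <- c()
  for (i in seq_len(nrow(perms))) for (j in seq_len(nrow(perms)))
    null_rp <- c(null_rp, sqrt(perms[i, ] * perms[j, ]))
  n_null_sets <- nrow(perms)^2
  vapply(seq_len(n), function(g) {
    efp <- sum(null_rp <= rp[g]) / n_null_sets
    efp / sum(rp <= rp[g])
  }, numeric(1))
}

# Per-base expansion of a coverage table (brute force).
coverage_per_base_oracle <- function(cov, chrom, start, end) {
  vals <- numeric(end - start)
  cc <- cov[cov$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(cc))) {
    for (b in seq(start, end - 1)) {
      if (b >= cc$start[i] && b < cc$end[i])
        vals[b - start + 1] <- vals[b - start + 1] + cc$value[i]
    }
  }
  vals
}

# Small deterministic cohort for IO/pipeline tests.
tiny_cohort <- function(seed = 11L, n = 60L) {
  generate_cohort(cohort_config(n_samples = n, n_genes = 60L,
                                n_prolif_genes = 5L, seed = seed))
}
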