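# Survival-analysis suite: Kaplan-Meier, log-rank, univariate Cox (Efron or
# Breslow ties), Benjamini-Hochberg FDR, and the per-gene copy-number-loss
# scan. All estimators are implemented from first principles; the 'survival'
# package is used only as an independent oracle in the test suite.

check_surv_input <- function(times, events) {
  if (length(times) == 0L) stop_bad("empty survival input")
  if (length(times) != length(events))
    stop_bad("'times' and 'events' must have equal length")
  if (!is.numeric(times) || any(!is.finite(times)) || any(times < 0))
    stop_bad("'times' must be finite and >= 0")
  if (!all(events %in% c(0, 1)))
    stop_bad("'events' must be 0 (censored) or 1 (event)")
  invisible(NULL)
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimate of the survival function
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over the distinct event
#' times. Times at which only censoring occurs reduce the risk set without
#' producing a step.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicator: 1 = event (death from disease), 0 = censored.
#' @return An object of class `km_curve`: a data.frame with one row per
#'   distinct event time and columns `time`, `n_risk`, `n_event`, `n_censor`
#'   (censorings at exactly that time) and `surv`. `S(0^-) = 1` implicitly;
#'   use [km_surv_at()] to evaluate the step function.
#' @examples
#' km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' @export
km_estimate <- function(times, events) {
  check_surv_input(times, events)
  n <- length(times)
  ut <- sort(unique(times))
  idx <- match(times, ut)
  cnt <- tabulate(idx, nbins = length(ut))
  n_risk_all <- rev(cumsum(rev(cnt)))
  d_all <- tabulate(idx[events == 1], nbins = length(ut))
  c_all <- cnt - d_all
  keep <- d_all > 0
  surv <- cumprod(1 - d_all[keep] / n_risk_all[keep])
  out <- data.frame(time = ut[keep], n_risk = n_risk_all[keep],
                    n_event = d_all[keep], n_censor = c_all[keep],
                    surv = surv)
  structure(out, class = c("km_curve", "data.frame"), n_subjects = n)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km A `km_curve` from [km_estimate()].
#' @param t Times at which to evaluate the right-continuous step function.
#' @return Survival probabilities, 1 before the first event time.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (length(i) == 0L) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Log-rank test for differences between survival curves
#'
#' Standard log-rank test with hypergeometric expectation and variance at each
#' distinct event time; chi-square statistic with `k - 1` degrees of freedom.
#' For two groups the hazard ratio is estimated by the log-rank
#' (observed/expected) method:
#' \eqn{HR = (O_1/E_1)/(O_2/E_2)} for the two group levels in order, so
#' swapping the labels inverts it. The result also records which group is
#' "worse" (lower Kaplan-Meier estimate at the last event time) and
#' `hr_worse_vs_better`, the convention used on two-group survival figures.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicator (1 = event, 0 = censored).
#' @param groups Group membership (factor or vector); all groups must be
#'   non-empty and at least one event must occur.
#' @return A list of class `logrank_result` with `observed`, `expected` (per
#'   group), `chisq`, `df`, `p_value`, and for two groups `hr`,
#'   `hr_worse_vs_better` and `worse_group`.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv_input(times, events)
  g <- factor(groups)
  if (length(g) != length(times))
    stop_bad("'groups' must match 'times' in length")
  if (any(table(g) == 0L) || nlevels(g) < 2L)
    stop_bad("need >= 2 non-empty groups")
  if (sum(events) == 0) stop_bad("need >= 1 event")
  lev <- levels(g)
  k <- length(lev)
  # exact index-based tabulation of at-risk and event counts per event time
  ut <- sort(unique(times))
  idx <- match(times, ut)
  n_all <- rev(cumsum(rev(tabulate(idx, nbins = length(ut)))))
  d_all <- tabulate(idx[events == 1], nbins = length(ut))
  ev_keep <- which(d_all > 0)
  ev_times <- ut[ev_keep]
  n_t <- n_all[ev_keep]
  d_t <- d_all[ev_keep]
  n_kt <- matrix(0, length(ev_times), k, dimnames = list(NULL, lev))
  d_kt <- matrix(0, length(ev_times), k, dimnames = list(NULL, lev))
  for (l in lev) {
    sel <- g == l
    n_kt[, l] <- rev(cumsum(rev(tabulate(idx[sel],
                                         nbins = length(ut)))))[ev_keep]
    d_kt[, l] <- tabulate(idx[sel & events == 1],
                          nbins = length(ut))[ev_keep]
  }
  e_kt <- d_t * n_kt / n_t
  O <- stats::setNames(colSums(d_kt), lev)
  E <- stats::setNames(colSums(e_kt), lev)
  U <- (O - E)[seq_len(k - 1)]
  V <- matrix(0, k - 1, k - 1)  # covariance of the score vector
  f <- ifelse(n_t > 1, d_t * (n_t - d_t) / (n_t - 1), 0)
  p_k <- n_kt / n_t
  for (j in seq_along(ev_times)) {
    pj <- p_k[j, seq_len(k - 1)]
    V <- V + f[j] * (diag(pj, k - 1) - tcrossprod(pj))
  }
  chisq <- tryCatch(drop(t(U) %*% solve(V, U)), error = function(e) NA_real_)
  if (!is.finite(chisq)) stop_bad("singular log-rank covariance (a group has no at-risk subjects at event times)")
  p <- stats::pchisq(chisq, df = k - 1, lower.tail = FALSE)
  res <- list(observed = O, expected = E, chisq = chisq, df = k - 1,
              p_value = p)
  if (k == 2L) {
    res$hr <- (O[1] / E[1]) / (O[2] / E[2])
    # orientation for figure-style reporting: worse = lower KM at last event
    s_last <- vapply(lev, function(l) {
      km <- km_estimate(times[g == l], events[g == l])
      if (nrow(km) == 0L) 1 else km_surv_at(km, max(ev_times))
    }, numeric(1))
    worse <- lev[which.min(s_last)]
    better <- lev[lev != worse][1]
    res$worse_group <- worse
    res$hr_worse_vs_better <-
      (O[worse] / E[worse]) / (O[better] / E[better])
  }
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank test:", length(x$observed), "groups\n")
  print(data.frame(observed = x$observed, expected = x$expected))
  cat(sprintf("chisq = %.4g on %d df, p = %.4g\n", x$chisq, x$df, x$p_value))
  if (!is.null(x$hr))
    cat(sprintf("HR (%s vs %s) = %.4g; worse group: %s\n",
                names(x$observed)[1], names(x$observed)[2],
                unname(x$hr), x$worse_group))
  invisible(x)
}

# Precompute the sorted risk-set structure for fast partial-likelihood
# evaluation: observations sorted by time, first-at-risk position and dead
# set per distinct event time, and the Efron l/d fractions.
cox_prep <- function(times, events, x) {
  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]; x_s <- x[ord]
  ev_times <- sort(unique(t_s[e_s == 1]))
  p <- match(ev_times, t_s)  # first index at risk per event time
  dd <- which(e_s == 1)
  jd <- factor(match(t_s[dd], ev_times), levels = seq_along(ev_times))
  d <- as.integer(table(jd))
  rep_j <- rep(seq_along(ev_times), d)
  lfrac <- (sequence(d) - 1) / d[rep_j]  # l/d for l = 0..d-1 per event time
  list(t_s = t_s, x_s = x_s, dd = dd, jd = jd, p = p, d = d,
       rep_j = rep_j, lfrac = lfrac, sum_x_dead = sum(x_s[dd]))
}

# Log-likelihood, gradient and information of the partial likelihood at beta
# (scalar covariate), Efron or Breslow ties; fully vectorized via suffix sums.
cox_loglik_parts <- function(beta, prep, ties) {
  beta <- unname(beta)
  w <- exp(beta * prep$x_s)
  S0R <- rev(cumsum(rev(w)))[prep$p]
  S1R <- rev(cumsum(rev(w * prep$x_s)))[prep$p]
  S2R <- rev(cumsum(rev(w * prep$x_s^2)))[prep$p]
  if (ties == "efron") {
    wd <- w[prep$dd]; xd <- prep$x_s[prep$dd]
    S0D <- as.numeric(rowsum(wd, prep$jd))
    S1D <- as.numeric(rowsum(wd * xd, prep$jd))
    S2D <- as.numeric(rowsum(wd * xd^2, prep$jd))
    j <- prep$rep_j; f <- prep$lfrac
    phi0 <- S0R[j] - f * S0D[j]
    phi1 <- S1R[j] - f * S1D[j]
    phi2 <- S2R[j] - f * S2D[j]
  } else {
    j <- prep$rep_j
    phi0 <- S0R[j]; phi1 <- S1R[j]; phi2 <- S2R[j]
  }
  c(ll = beta * prep$sum_x_dead - sum(log(phi0)),
    gr = prep$sum_x_dead - sum(phi1 / phi0),
    info = sum(phi2 / phi0 - (phi1 / phi0)^2))
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximizes the Cox partial likelihood for a single covariate by
#' Newton-Raphson with step-halving. Ties are handled by the Efron
#' approximation (default) or Breslow. Monotone likelihood (e.g. a binary
#' covariate perfectly separating events) is detected and flagged as
#' non-converged with no coefficient reported.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicator (1 = event, 0 = censored).
#' @param covariate Numeric covariate with positive variance.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol Convergence tolerance on the Newton step (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return A list of class `cox_result`: `beta`, `se`, `z`, `p_value`,
#'   `loglik`, `converged`, `iterations`.
#' @export
cox_univariate <- function(times, events, covariate,
                           ties = c("efron", "breslow"),
                           tol = 1e-8, max_iter = 50L) {
  ties <- match.arg(ties)
  check_surv_input(times, events)
  x <- as.numeric(covariate)
  if (length(x) != length(times))
    stop_bad("'covariate' must match 'times' in length")
  if (any(!is.finite(x))) stop_bad("'covariate' must be finite")
  if (stats::var(x) == 0) stop_bad("constant covariate: variance must be > 0")
  if (sum(events) == 0) stop_bad("need >= 1 event")
  # center+scale for numerical stability; back-transform at the end
  mu <- mean(x); sdx <- stats::sd(x)
  xs <- (x - mu) / sdx
  prep <- cox_prep(times, events, xs)
  beta <- 0
  parts <- cox_loglik_parts(beta, prep, ties)
  converged <- FALSE
  it <- 0L
  bound <- 25  # |beta| beyond this on the sd scale => monotone likelihood
  while (it < max_iter) {
    it <- it + 1L
    if (parts["info"] <= 0 || !is.finite(parts["info"])) break
    step <- unname(parts["gr"] / parts["info"])
    # step-halving: require the log-likelihood not to decrease
    h <- 1
    repeat {
      cand <- beta + h * step
      cand_parts <- cox_loglik_parts(cand, prep, ties)
      if (is.finite(cand_parts["ll"]) &&
          cand_parts["ll"] >= parts["ll"] - 1e-12) break
      h <- h / 2
      if (h < 1e-10) { cand <- beta; cand_parts <- parts; break }
    }
    delta <- cand - beta
    beta <- cand; parts <- cand_parts
    if (abs(beta) > bound) break  # drifting to +-Inf: monotone likelihood
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  if (!converged || abs(beta) > bound || parts["info"] <= 0) {
    res <- list(beta = NA_real_, se = NA_real_, z = NA_real_,
                p_value = NA_real_, loglik = unname(parts["ll"]),
                converged = FALSE, iterations = it, ties = ties)
  } else {
    b <- beta / sdx
    se <- unname(1 / sqrt(parts["info"])) / sdx
    z <- b / se
    res <- list(beta = b, se = se, z = z,
                p_value = 2 * stats::pnorm(-abs(z)),
                loglik = unname(parts["ll"]), converged = TRUE,
                iterations = it, ties = ties)
  }
  class(res) <- "cox_result"
  res
}

#' @export
print.cox_result <- function(x, ...) {
  if (!x$converged) {
    cat("Univariate Cox fit: NOT converged (monotone likelihood?)\n")
  } else {
    cat(sprintf("Univariate Cox (%s ties): beta = %.5g (se %.4g), HR = %.4g, p = %.4g\n",
                x$ties, x$beta, x$se, exp(x$beta), x$p_value))
  }
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment with enforced monotonicity; `q <= 1`.
#'
#' @param pvalues Numeric p-values in \[0, 1\] (NA allowed, propagated).
#' @return Adjusted q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_bad("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m > 0L) {
    ord <- order(pp, decreasing = TRUE)
    qq <- pmin(1, cummin(pp[ord] * m / seq(m, 1)))
    tmp <- numeric(m)
    tmp[ord] <- qq
    q[ok] <- tmp
  }
  q
}

#' Rank-based ROC area under the curve
#'
#' Mann-Whitney AUC of a continuous marker against a binary outcome, with 0.5
#' credit for ties.
#'
#' @param marker Per-sample scalar values.
#' @param outcome Binary outcome (0/1 or logical); both classes required.
#' @return AUC in \[0, 1\]; values above 0.5 mean higher marker in positives.
#' @export
roc_auc <- function(marker, outcome) {
  y <- as.integer(as.logical(outcome))
  if (length(y) != length(marker)) stop_bad("length mismatch")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop_bad("both outcome classes must be present")
  r <- rank(marker)  # average ranks handle ties with 0.5 credit
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-gene survival scan over copy-number loss
#'
#' For each gene (in chromosomal order) fits a univariate Cox model with the
#' binary covariate loss-vs-rest (copy state <= -1 vs > -1), then applies
#' Benjamini-Hochberg FDR across genes and flags `q < fdr_threshold`
#' (default 0.15). Genes with zero loss carriers (or all carriers) are skipped
#' and reported with missing p/q.
#'
#' @param cnv Copy-number matrix, samples x genes (rownames = sample ids),
#'   integer states in \{-2, -1, 0, +1\}.
#' @param clinical Data frame with columns `sample_id`, `time`, `event`.
#' @param genes Character vector of gene ids in chromosome-position order
#'   (default: column order of `cnv`).
#' @param fdr_threshold Significance threshold on q (default 0.15).
#' @param ties Tie handling passed to [cox_univariate()].
#' @return Data frame: `gene`, `position` (rank along the chromosome), `beta`,
#'   `p`, `q`, `significant`, `skipped`.
#' @export
chromosome_scan <- function(cnv, clinical, genes = colnames(cnv),
                            fdr_threshold = 0.15, ties = "efron") {
  if (is.null(colnames(cnv))) stop_bad("'cnv' must have gene column names")
  missing_g <- setdiff(genes, colnames(cnv))
  if (length(missing_g))
    stop_bad("genes absent from cnv table: %s",
             paste(utils::head(missing_g, 5), collapse = ", "))
  idx <- match(clinical$sample_id, rownames(cnv))
  if (anyNA(idx)) stop_bad("clinical samples missing from cnv table")
  res <- data.frame(gene = genes, position = seq_along(genes),
                    beta = NA_real_, p = NA_real_, q = NA_real_,
                    significant = FALSE, skipped = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_along(genes)) {
    loss <- as.numeric(cnv[idx, genes[j]] <= -1)
    if (sum(loss) == 0 || sum(loss) == length(loss)) {
      res$skipped[j] <- TRUE
      next
    }
    fit <- cox_univariate(clinical$time, clinical$event, loss, ties = ties)
    if (fit$converged) {
      res$beta[j] <- fit$beta
      res$p[j] <- fit$p_value
    } else {
      res$skipped[j] <- TRUE
    }
  }
  res$q <- bh_fdr(res$p)
  res$significant <- !is.na(res$q) & res$q < fdr_threshold
  res
}
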