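# Seeded synthetic-data generators. Each emulates the statistical structure
# of one of the study designs (tumor cohort with survival, growth-coupling
# experiment, PRC2 target dataset, single-cell panel) so every downstream
# stage is testable without controlled-access data. All draws flow from one
# seeded generator per call; the seed is a required config field and fixing
# it reproduces byte-identical outputs.

#' Configuration for the synthetic tumor cohort
#'
#' The cohort carries a latent standard-normal proliferation factor `P` per
#' sample. The proliferation gene set loads on `P` with unit slope plus
#' noise; the marker transcript is `P + R` where
#' `R = cnv_effect * copy_state + noise` is its proliferation-independent
#' component; survival is exponential with log-hazard
#' `log(baseline_hazard) + beta_prolif * P + beta_resid * R`, with
#' administrative censoring at an independent Uniform(0, 2/censor_rate) time.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param n_prolif_genes Size of the proliferation gene set (default 54).
#' @param beta_prolif Hazard log-coefficient on the proliferation factor.
#' @param beta_resid Hazard log-coefficient on the proliferation-independent
#'   marker component (negative = higher marker-residual is protective).
#' @param cnv_loss_prob,cnv_gain_prob Per-sample probabilities of hemizygous
#'   loss / gain.
#' @param cnv_effect Log2 expression shift per copy-state unit (default 1,
#'   i.e. dosage-proportional: hemizygous loss halves expression).
#' @param noise_sd Log2 expression noise standard deviation.
#' @param censor_rate Censoring parameter; mean censoring time is
#'   `1/censor_rate`.
#' @param lost_arm_genes Gene ids sharing a co-deleted chromosome-arm
#'   segment; the marker gene should be among them to emulate arm-level loss
#'   of the marker locus.
#' @param baseline_hazard Events per time unit at covariate zero.
#' @param marker_gene,control_gene Ids of the marker transcript and of a
#'   purely proliferation-driven control transcript.
#' @param seed Integer seed (required).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 2000L, n_genes = 150L,
                          n_prolif_genes = 54L,
                          beta_prolif = 0.8, beta_resid = -0.5,
                          cnv_loss_prob = 0.2, cnv_gain_prob = 0.1,
                          cnv_effect = 1.0, noise_sd = 0.5,
                          censor_rate = 0.05,
                          lost_arm_genes = c("EZH2", paste0("ARM_", 1:9)),
                          baseline_hazard = 0.05,
                          marker_gene = "EZH2", control_gene = "ORC6",
                          seed) {
  n_samples <- check_count(n_samples, "n_samples")
  n_genes <- check_count(n_genes, "n_genes")
  n_prolif_genes <- check_count(n_prolif_genes, "n_prolif_genes")
  if (n_prolif_genes >= n_genes)
    stop_bad("n_prolif_genes must be < n_genes")
  check_prob(cnv_loss_prob, "cnv_loss_prob")
  check_prob(cnv_gain_prob, "cnv_gain_prob")
  if (cnv_loss_prob + cnv_gain_prob > 1)
    stop_bad("cnv_loss_prob + cnv_gain_prob must be <= 1")
  check_number(beta_prolif, "beta_prolif")
  check_number(beta_resid, "beta_resid")
  check_number(cnv_effect, "cnv_effect")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(censor_rate, "censor_rate", lower = 0, strict_lower = TRUE)
  check_number(baseline_hazard, "baseline_hazard", lower = 0,
               strict_lower = TRUE)
  seed <- check_seed(seed)
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic tumor cohort
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`:
#'   `expr` (genes x samples log2 matrix), `cnv` (samples x genes integer
#'   states), `clinical` (data frame `sample_id`, `time`, `event`,
#'   `er_status`), `prolif_genes` (the metagene gene-set ids), and `truth`
#'   (latent `P`, `R`, per-sample log-hazard, uncensored times, config echo).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  with_seed(cf$seed, {
    samples <- sprintf("S%04d", seq_len(cf$n_samples))
    prolif_genes <- sprintf("PROLIF_%02d", seq_len(cf$n_prolif_genes))
    arm_extra <- setdiff(cf$lost_arm_genes, cf$marker_gene)
    filler_n <- cf$n_genes - cf$n_prolif_genes - 2L - length(arm_extra)
    if (filler_n < 0) stop_bad("n_genes too small for the named gene sets")
    genes <- c(prolif_genes, cf$marker_gene, cf$control_gene, arm_extra,
               sprintf("FILLER_%03d", seq_len(filler_n)))
    P <- stats::rnorm(cf$n_samples)

    # copy-number states: arm genes share one co-deletion event per sample;
    # every gene may also gain; off-arm genes lose independently
    cnv <- matrix(0L, nrow = cf$n_samples, ncol = length(genes),
                  dimnames = list(samples, genes))
    arm_carrier <- stats::runif(cf$n_samples) < cf$cnv_loss_prob
    for (gn in cf$lost_arm_genes) {
      if (!gn %in% genes) stop_bad("lost_arm_gene '%s' not in gene universe", gn)
      cnv[arm_carrier, gn] <- -1L
    }
    off_arm <- setdiff(genes, cf$lost_arm_genes)
    for (gn in off_arm) {
      u <- stats::runif(cf$n_samples)
      cnv[u < cf$cnv_loss_prob, gn] <- -1L
    }
    for (gn in genes) {
      u <- stats::runif(cf$n_samples)
      gain <- u < cf$cnv_gain_prob & cnv[, gn] == 0L
      cnv[gain, gn] <- 1L
    }

    baseline <- stats::setNames(stats::rnorm(length(genes), 8, 1), genes)
    noise <- function() stats::rnorm(cf$n_samples, 0, cf$noise_sd)
    expr <- matrix(0, nrow = length(genes), ncol = cf$n_samples,
                   dimnames = list(genes, samples))
    for (gn in prolif_genes)
      expr[gn, ] <- baseline[gn] + P + noise()
    expr[cf$control_gene, ] <- baseline[cf$control_gene] + P + noise()
    R <- cf$cnv_effect * cnv[, cf$marker_gene] + noise()
    expr[cf$marker_gene, ] <- baseline[cf$marker_gene] + P + R
    for (gn in setdiff(genes, c(prolif_genes, cf$marker_gene,
                                cf$control_gene)))
      expr[gn, ] <- baseline[gn] + cf$cnv_effect * cnv[, gn] + noise()

    log_h <- log(cf$baseline_hazard) + cf$beta_prolif * P +
      cf$beta_resid * R
    t_event <- stats::rexp(cf$n_samples, rate = exp(log_h))
    t_censor <- stats::runif(cf$n_samples, 0, 2 / cf$censor_rate)
    clinical <- data.frame(
      sample_id = samples,
      time = pmin(t_event, t_censor),
      event = as.integer(t_event <= t_censor),
      er_status = ifelse(stats::runif(cf$n_samples) < 0.75, "pos", "neg"),
      stringsAsFactors = FALSE)

    structure(list(expr = expr, cnv = cnv, clinical = clinical,
                   prolif_genes = prolif_genes,
                   truth = list(P = stats::setNames(P, samples),
                                R = stats::setNames(as.numeric(R), samples),
                                log_hazard = stats::setNames(log_h, samples),
                                time_event = t_event,
                                arm_carrier = stats::setNames(arm_carrier,
                                                              samples),
                                config = cf)),
              class = "synthetic_cohort")
  })
}

#' Configuration for the growth-coupling experiment
#'
#' Emulates in-vitro measurements of growth rate, enzyme abundance and mark
#' abundance under a control arm (enzyme tightly coupled to growth,
#' `E = c0 + c1 g`) and a knockdown arm with a diminished coupling slope.
#'
#' @param growth_rates Growth rates, divisions per cell per hour (> 0).
#' @param c0,c1 Control coupling intercept and slope.
#' @param knockdown_slope Knockdown slope `c1' < c1`.
#' @param alpha,delta Deposition and turnover rates of the mark model.
#' @param noise_cv Coefficient of variation of multiplicative readout noise.
#' @param seed Integer seed (required).
#' @return List of class `growth_experiment_config`.
#' @export
growth_experiment_config <- function(growth_rates = c(0.01, 0.02, 0.03,
                                                      0.04, 0.05),
                                     c0 = 0.2, c1 = 100,
                                     knockdown_slope = 30,
                                     alpha = 0.01, delta = 0,
                                     noise_cv = 0.05, seed) {
  if (any(growth_rates <= 0)) stop_bad("growth rates must be > 0")
  check_number(c0, "c0"); check_number(c1, "c1")
  check_number(knockdown_slope, "knockdown_slope")
  if (knockdown_slope >= c1)
    stop_bad("knockdown_slope must be < control slope c1")
  check_number(alpha, "alpha", lower = 0)
  check_number(delta, "delta", lower = 0)
  check_number(noise_cv, "noise_cv", lower = 0)
  seed <- check_seed(seed)
  structure(as.list(environment()), class = "growth_experiment_config")
}

#' Generate growth / enzyme / mark abundance triplets
#'
#' @param config A [growth_experiment_config()].
#' @return Data frame: `condition` (`control`/`knockdown`), `g`, `E`
#'   (noisy enzyme readout), `m` (noisy steady-state mark readout), plus the
#'   noise-free `E_true`, `m_true`.
#' @export
generate_growth_experiment <- function(config) {
  stopifnot(inherits(config, "growth_experiment_config"))
  cf <- config
  with_seed(cf$seed, {
    rows <- list()
    for (cond in c("control", "knockdown")) {
      slope <- if (cond == "control") cf$c1 else cf$knockdown_slope
      for (g in cf$growth_rates) {
        p <- mark_kinetics_params(cf$alpha, cf$delta, g, c0 = cf$c0,
                                  c1 = slope)
        m <- steady_state_mark(p)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, g = g,
          E = p$E * (1 + stats::rnorm(1, 0, cf$noise_cv)),
          m = m * (1 + stats::rnorm(1, 0, cf$noise_cv)),
          E_true = p$E, m_true = m, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Configuration for the synthetic PRC2 target dataset
#'
#' Plants four gene classes — responsive (mark-positive and up-regulated on
#' enzyme loss), indirect (up-regulated, mark-negative), nonresponsive
#' (mark-positive, unchanged) and null — with promoter mark signal, an
#' expression time course, and a rescue experiment. Early responsive genes
#' carry the low promoter enrichment and derepress at the first non-zero
#' timepoint; late responsive genes carry high enrichment and derepress only
#' at the final timepoint.
#'
#' @param n_genes Gene universe size.
#' @param fraction_responsive,fraction_indirect,fraction_nonresponsive
#'   Planted class fractions (must sum to <= 1; the rest is null).
#' @param fraction_early Fraction of responsive genes that respond early
#'   (default 0.09).
#' @param fraction_non_rescued Fraction of responsive genes not rescued by
#'   the paralogous enzyme (default 0.26).
#' @param promoter_enrichment_high,promoter_enrichment_low Promoter fold
#'   enrichment over background for late/nonresponsive vs early genes.
#' @param timepoints Strictly increasing timepoints starting at 0 (days).
#' @param fold_change_up Planted log2 up-regulation effect.
#' @param k Replicates per condition/timepoint (>= 2).
#' @param noise_sd Log2 expression replicate noise.
#' @param signal_noise_cv Multiplicative noise on coverage bins.
#' @param seed Integer seed (required).
#' @return List of class `targets_config`.
#' @export
targets_config <- function(n_genes = 2000L, fraction_responsive = 0.01,
                           fraction_indirect = 0.005,
                           fraction_nonresponsive = 0.19,
                           fraction_early = 0.09,
                           fraction_non_rescued = 0.26,
                           promoter_enrichment_high = 8,
                           promoter_enrichment_low = 3,
                           timepoints = c(0, 5, 10),
                           fold_change_up = 2, k = 2L, noise_sd = 0.25,
                           signal_noise_cv = 0.1, seed) {
  n_genes <- check_count(n_genes, "n_genes")
  for (nm in c("fraction_responsive", "fraction_indirect",
               "fraction_nonresponsive", "fraction_early",
               "fraction_non_rescued"))
    check_prob(get(nm), nm)
  if (fraction_responsive + fraction_indirect + fraction_nonresponsive > 1)
    stop_bad("class fractions must sum to <= 1")
  if (length(timepoints) < 2L || timepoints[1] != 0 ||
      any(diff(timepoints) <= 0))
    stop_bad("timepoints must be strictly increasing and start at 0")
  check_number(promoter_enrichment_high, "promoter_enrichment_high",
               lower = 1)
  check_number(promoter_enrichment_low, "promoter_enrichment_low", lower = 1)
  check_number(fold_change_up, "fold_change_up")
  k <- check_count(k, "k")
  if (k < 2L) stop_bad("need k >= 2 replicates")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(signal_noise_cv, "signal_noise_cv", lower = 0)
  seed <- check_seed(seed)
  structure(mget(c("n_genes", "fraction_responsive", "fraction_indirect",
                   "fraction_nonresponsive", "fraction_early",
                   "fraction_non_rescued", "promoter_enrichment_high",
                   "promoter_enrichment_low", "timepoints",
                   "fold_change_up", "k", "noise_sd", "signal_noise_cv",
                   "seed")),
            class = "targets_config")
}

# Build a binned coverage table for one condition over the synthetic genome.
build_coverage <- function(ann, region_half, bin_bp, base_level, prom_half,
                           prom_fold_by_gene, noise_cv) {
  n_bins <- as.integer(2 * region_half / bin_bp)
  offs <- -region_half + (seq_len(n_bins) - 1L) * bin_bp
  tss0 <- rep(ann$tss - 1L, each = n_bins)
  starts <- tss0 + rep(offs, times = nrow(ann))
  fold <- ifelse(starts >= tss0 - prom_half & starts < tss0 + prom_half,
                 rep(prom_fold_by_gene, each = n_bins), 1)
  val <- base_level * fold *
    (1 + stats::rnorm(length(starts), 0, noise_cv))
  out <- data.frame(chrom = rep(ann$chrom, each = n_bins), start = starts,
                    end = starts + bin_bp, value = pmax(val, 0),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), ]
}

#' Generate the synthetic PRC2 target dataset
#'
#' @param config A [targets_config()].
#' @return List of class `synthetic_targets`: `signals` (a
#'   [promoter_signal_set()] with conditions `wt` and `ko`), `timecourse`
#'   (a [timecourse_matrix()] of the post-deletion time course), `rescue`
#'   (list of genes x replicates matrices `wt` and `rescue`), and `truth`
#'   (data frame `gene_id`, `class`, `timing`, `rescue`).
#' @export
generate_target_dataset <- function(config) {
  stopifnot(inherits(config, "targets_config"))
  cf <- config
  with_seed(cf$seed, {
    genes <- sprintf("G%04d", seq_len(cf$n_genes))
    n_resp <- round(cf$fraction_responsive * cf$n_genes)
    n_ind <- round(cf$fraction_indirect * cf$n_genes)
    n_nonresp <- round(cf$fraction_nonresponsive * cf$n_genes)
    class <- rep("null", cf$n_genes)
    idx <- sample.int(cf$n_genes)  # random placement of planted classes
    class[idx[seq_len(n_resp)]] <- "responsive"
    class[idx[n_resp + seq_len(n_ind)]] <- "indirect"
    class[idx[n_resp + n_ind + seq_len(n_nonresp)]] <- "nonresponsive"
    timing <- rep(NA_character_, cf$n_genes)
    resp_idx <- which(class == "responsive")
    n_early <- round(cf$fraction_early * n_resp)
    early_idx <- resp_idx[sample.int(n_resp, n_early)]
    timing[resp_idx] <- "late"
    timing[early_idx] <- "early"
    rescue_lab <- rep(NA_character_, cf$n_genes)
    n_nr <- round(cf$fraction_non_rescued * n_resp)
    nr_idx <- resp_idx[sample.int(n_resp, n_nr)]
    rescue_lab[resp_idx] <- "rescued"
    rescue_lab[nr_idx] <- "non_rescued"

    # synthetic genome: one gene per 20-kb region on a single contig,
    # TSS at the region midpoint, alternating strand
    region <- 20000L
    ann <- data.frame(
      gene_id = genes, chrom = "chr1",
      tss = as.integer(seq_len(cf$n_genes) - 1L) * region + region %/% 2L + 1L,
      strand = rep(c("+", "-"), length.out = cf$n_genes),
      stringsAsFactors = FALSE)

    prom_fold <- rep(1, cf$n_genes)
    prom_fold[class == "nonresponsive"] <- cf$promoter_enrichment_high
    prom_fold[class == "responsive"] <-
      ifelse(timing[class == "responsive"] == "early",
             cf$promoter_enrichment_low, cf$promoter_enrichment_high)
    wt_cov <- build_coverage(ann, region_half = 6000L, bin_bp = 100L,
                             base_level = 1, prom_half = 2000L,
                             prom_fold_by_gene = prom_fold,
                             noise_cv = cf$signal_noise_cv)
    ko_cov <- build_coverage(ann, region_half = 6000L, bin_bp = 100L,
                             base_level = 1, prom_half = 2000L,
                             prom_fold_by_gene = rep(1, cf$n_genes),
                             noise_cv = cf$signal_noise_cv)
    signals <- promoter_signal_set(list(wt = wt_cov, ko = ko_cov), ann)

    # post-deletion expression time course: up-regulation switches on at the
    # first non-zero timepoint (early) or only at the final one (late);
    # indirect genes rise at the final timepoint without promoter mark
    base <- stats::rnorm(cf$n_genes, 6, 1)
    tp <- rep(cf$timepoints, each = cf$k)
    reps <- rep(paste0("r", seq_len(cf$k)), times = length(cf$timepoints))
    eff <- matrix(0, nrow = cf$n_genes, ncol = length(tp))
    final_t <- max(cf$timepoints)
    early_t <- cf$timepoints[2]
    for (j in seq_along(tp)) {
      t <- tp[j]
      on <- (class == "responsive" & timing == "early" & t >= early_t) |
        (class == "responsive" & timing == "late" & t >= final_t) |
        (class == "indirect" & t >= final_t)
      on[is.na(on)] <- FALSE
      eff[on, j] <- cf$fold_change_up
    }
    vals <- base + eff +
      matrix(stats::rnorm(cf$n_genes * length(tp), 0, cf$noise_sd),
             nrow = cf$n_genes)
    rownames(vals) <- genes
    tc <- timecourse_matrix(vals, tp, reps)

    # rescue experiment: non-rescued responsive genes stay up vs wild type
    wt_mat <- base +
      matrix(stats::rnorm(cf$n_genes * cf$k, 0, cf$noise_sd),
             nrow = cf$n_genes,
             dimnames = list(genes, paste0("r", seq_len(cf$k))))
    res_eff <- ifelse(!is.na(rescue_lab) & rescue_lab == "non_rescued",
                      cf$fold_change_up, 0)
    rescue_mat <- base + res_eff +
      matrix(stats::rnorm(cf$n_genes * cf$k, 0, cf$noise_sd),
             nrow = cf$n_genes,
             dimnames = list(genes, paste0("r", seq_len(cf$k))))

    structure(list(signals = signals, timecourse = tc,
                   rescue = list(wt = wt_mat, rescue = rescue_mat),
                   truth = data.frame(gene_id = genes, class = class,
                                      timing = timing, rescue = rescue_lab,
                                      stringsAsFactors = FALSE)),
              class = "synthetic_targets")
  })
}

#' Configuration for the synthetic single-cell panel
#'
#' @param n_wt_cells,n_ko_cells Cell counts per genotype (defaults 49 and 37,
#'   the panel sizes of the motivating experiment).
#' @param gene_classes Named list; each element is a list with `n_genes`,
#'   `p_wt`, `p_ko` (per-genotype detection probabilities) and
#'   `deterministic` (all-or-none per cell vs independent per gene).
#'   Defaults: a deterministic `responsive` class (off in most wt cells,
#'   fully derepressed in ko), a stochastic `nonresponsive_sparse` class
#'   (rare in wt, sparsely activated in ko) and a stochastic
#'   `nonresponsive_stable` class insensitive to genotype.
#' @param dye_mislabel_rate Probability a cell's dye label is flipped.
#' @param seed Integer seed (required).
#' @return List of class `single_cell_config`.
#' @export
single_cell_config <- function(n_wt_cells = 49L, n_ko_cells = 37L,
                               gene_classes = list(
                                 responsive = list(n_genes = 8L, p_wt = 0.2,
                                                   p_ko = 1.0,
                                                   deterministic = TRUE),
                                 nonresponsive_sparse = list(
                                   n_genes = 8L, p_wt = 0.1, p_ko = 0.5,
                                   deterministic = FALSE),
                                 nonresponsive_stable = list(
                                   n_genes = 4L, p_wt = 0.8, p_ko = 0.8,
                                   deterministic = FALSE)),
                               dye_mislabel_rate = 0.05, seed) {
  n_wt_cells <- check_count(n_wt_cells, "n_wt_cells")
  n_ko_cells <- check_count(n_ko_cells, "n_ko_cells")
  check_prob(dye_mislabel_rate, "dye_mislabel_rate")
  if (is.null(names(gene_classes)))
    stop_bad("gene_classes must be a named list")
  for (nm in names(gene_classes)) {
    cl <- gene_classes[[nm]]
    check_count(cl$n_genes, paste0(nm, "$n_genes"))
    check_prob(cl$p_wt, paste0(nm, "$p_wt"))
    check_prob(cl$p_ko, paste0(nm, "$p_ko"))
    if (!is.logical(cl$deterministic))
      stop_bad("'%s$deterministic' must be logical", nm)
  }
  seed <- check_seed(seed)
  structure(mget(c("n_wt_cells", "n_ko_cells", "gene_classes",
                   "dye_mislabel_rate", "seed")),
            class = "single_cell_config")
}

#' Generate the synthetic single-cell dataset
#'
#' Deterministic-class genes are all-on or all-off per cell (in wild-type
#' cells the expressing subset is the lowest-enzyme fraction, mirroring
#' derepression in enzyme-low cells); stochastic-class genes are drawn
#' independently per gene. The enzyme transcript (`Ezh2` row) and the
#' SET-domain assay are present in wild-type cells and absent in knockouts;
#' dye labels are flipped with `dye_mislabel_rate`.
#'
#' @param config A [single_cell_config()].
#' @return List of class `synthetic_singlecell`: `expr` (genes x cells log2
#'   matrix including an `Ezh2` row), `cell_meta` (data frame `cell_id`,
#'   `dye`, `set_domain_detected`), `truth` (per-cell true genotype and
#'   mislabel flag; per-gene class).
#' @export
generate_singlecell_dataset <- function(config) {
  stopifnot(inherits(config, "single_cell_config"))
  cf <- config
  with_seed(cf$seed, {
    n <- cf$n_wt_cells + cf$n_ko_cells
    cells <- sprintf("C%03d", seq_len(n))
    genotype <- rep(c("wt", "ko"), c(cf$n_wt_cells, cf$n_ko_cells))
    ezh2 <- ifelse(genotype == "wt",
                   pmax(0.1, stats::rnorm(n, 5, 1)), 0)
    gene_ids <- unlist(lapply(names(cf$gene_classes), function(nm)
      sprintf("%s_%02d", toupper(nm), seq_len(cf$gene_classes[[nm]]$n_genes))))
    gene_class <- rep(names(cf$gene_classes),
                      vapply(cf$gene_classes, function(cl) cl$n_genes,
                             numeric(1)))
    det <- matrix(FALSE, nrow = length(gene_ids), ncol = n,
                  dimnames = list(gene_ids, cells))
    for (nm in names(cf$gene_classes)) {
      cl <- cf$gene_classes[[nm]]
      rows <- gene_class == nm
      for (geno in c("wt", "ko")) {
        cols <- which(genotype == geno)
        p <- if (geno == "wt") cl$p_wt else cl$p_ko
        if (cl$deterministic) {
          if (geno == "wt") {
            # expressing subset = lowest-enzyme cells (fraction p)
            k_on <- round(p * length(cols))
            on_cells <- cols[order(ezh2[cols])][seq_len(k_on)]
          } else {
            on_cells <- cols[stats::runif(length(cols)) < p]
          }
          det[rows, on_cells] <- TRUE
        } else {
          det[rows, cols] <-
            matrix(stats::runif(sum(rows) * length(cols)) < p,
                   nrow = sum(rows))
        }
      }
    }
    expr <- matrix(0, nrow = length(gene_ids), ncol = n,
                   dimnames = list(gene_ids, cells))
    expr[det] <- pmax(0.1, stats::rnorm(sum(det), 4, 1))
    expr <- rbind(Ezh2 = ezh2, expr)
    flipped <- stats::runif(n) < cf$dye_mislabel_rate
    dye_true <- ifelse(genotype == "wt", "DiI", "DiO")
    dye <- ifelse(flipped, ifelse(dye_true == "DiI", "DiO", "DiI"), dye_true)
    structure(list(
      expr = expr,
      cell_meta = data.frame(cell_id = cells, dye = dye,
                             set_domain_detected = genotype == "wt",
                             stringsAsFactors = FALSE),
      truth = list(genotype = stats::setNames(genotype, cells),
                   mislabeled = stats::setNames(flipped, cells),
                   gene_class = stats::setNames(gene_class, gene_ids))),
      class = "synthetic_singlecell")
  })
}
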