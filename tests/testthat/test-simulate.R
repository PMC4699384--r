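# Synthetic-data generators: determinism, validation, planted structure.

test_that("generators are byte-identical under a fixed seed", {
  expect_identical(generate_cohort(cohort_config(n_samples = 50,
                                                 n_genes = 70, seed = 1)),
                   generate_cohort(cohort_config(n_samples = 50,
                                                 n_genes = 70, seed = 1)))
  expect_identical(
    generate_growth_experiment(growth_experiment_config(seed = 2)),
    generate_growth_experiment(growth_experiment_config(seed = 2)))
  cfg <- targets_config(n_genes = 60, seed = 3)
  expect_identical(generate_target_dataset(cfg),
                   generate_target_dataset(cfg))
  expect_identical(
    generate_singlecell_dataset(single_cell_config(seed = 4)),
    generate_singlecell_dataset(single_cell_config(seed = 4)))
  # generators restore the caller's RNG state
  set.seed(99); before <- .Random.seed
  invisible(generate_cohort(cohort_config(n_samples = 20, n_genes = 70,
                                          seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("config validation rejects invalid parameters", {
  expect_error(cohort_config(n_samples = 0, seed = 1), "positive")
  expect_error(cohort_config(cnv_loss_prob = 1.4, seed = 1), "<=")
  expect_error(cohort_config(n_genes = 50, n_prolif_genes = 54, seed = 1),
               "n_prolif_genes")
  expect_error(cohort_config(), "seed")
  expect_error(growth_experiment_config(knockdown_slope = 200, seed = 1),
               "knockdown_slope")
  expect_error(growth_experiment_config(growth_rates = c(0, 0.1), seed = 1),
               "> 0")
  expect_error(targets_config(fraction_responsive = 0.6,
                              fraction_nonresponsive = 0.6, seed = 1),
               "sum")
  expect_error(targets_config(timepoints = c(5, 0, 10), seed = 1),
               "increasing")
  expect_error(single_cell_config(dye_mislabel_rate = 2, seed = 1), "<=")
})

test_that("degenerate cohort: marker tracks the metagene exactly", {
  co <- generate_cohort(cohort_config(n_samples = 80, n_genes = 70,
                                      noise_sd = 0, cnv_effect = 0,
                                      seed = 10))
  mg <- compute_metagene(co$expr, co$prolif_genes)
  marker <- co$expr["EZH2", ]
  expect_equal(order(marker), order(mg))
  expect_equal(unname(cor(marker, mg)), 1, tolerance = 1e-12)
})

test_that("lost-arm genes share identical loss states within each sample", {
  co <- generate_cohort(cohort_config(n_samples = 100, n_genes = 80,
                                      seed = 11))
  arm <- co$truth$config$lost_arm_genes
  states <- co$cnv[, arm]
  loss <- states == -1
  expect_true(all(apply(loss, 1, function(r) all(r) || !any(r))))
  expect_equal(unname(loss[, 1]), unname(co$truth$arm_carrier))
})

test_that("null cohort gives nominal stratification type-I error", {
  # reduced replication: 20 seeds, expect no excess of small p-values
  ps <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(n_samples = 120, n_genes = 60,
                                        n_prolif_genes = 10,
                                        beta_prolif = 0, beta_resid = 0,
                                        seed = 1000 + s))
    grp <- median_stratify(co$expr["EZH2", co$clinical$sample_id])
    logrank_test(co$clinical$time, co$clinical$event, grp)$p_value
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.25)  # 5% nominal; generous at 20 seeds
  expect_gt(min(ps), 0)
})

test_that("growth experiment reproduces the analytic regimes", {
  # noise-free proportional control: mark constant across rates
  g0 <- generate_growth_experiment(
    growth_experiment_config(c0 = 0, delta = 0, noise_cv = 0, seed = 12))
  ctrl <- g0[g0$condition == "control", ]
  expect_equal(diff(range(ctrl$m)), 0, tolerance = 1e-12)
  # noise-free knockdown with c0 > 0: strictly decreasing in g
  g1 <- generate_growth_experiment(
    growth_experiment_config(c0 = 0.5, delta = 0, noise_cv = 0, seed = 13))
  kd <- g1[g1$condition == "knockdown", ]
  expect_true(all(diff(kd$m[order(kd$g)]) < 0))
  # single growth rate: one row per arm
  g2 <- generate_growth_experiment(
    growth_experiment_config(growth_rates = 0.03, seed = 14))
  expect_equal(nrow(g2), 2)
})

test_that("target dataset plants the configured classes exactly", {
  cfg <- targets_config(n_genes = 100, seed = 15)
  ds <- generate_target_dataset(cfg)
  counts <- table(ds$truth$class)
  expect_equal(unname(counts["responsive"]),
               round(cfg$fraction_responsive * 100))
  expect_equal(unname(counts["nonresponsive"]),
               round(cfg$fraction_nonresponsive * 100))
  n_resp <- sum(ds$truth$class == "responsive")
  expect_equal(sum(ds$truth$timing == "early", na.rm = TRUE),
               round(cfg$fraction_early * n_resp))
  # fraction_early = 0: nothing up-regulated before the final timepoint
  ds0 <- generate_target_dataset(targets_config(n_genes = 100,
                                                fraction_early = 0,
                                                seed = 16))
  tc <- ds0$timecourse
  fc_early <- prc2suite:::timecourse_fold_changes(tc, 5)
  expect_true(all(rowMeans(fc_early) < 1))  # below any 2-fold gate
  # flat enrichment: promoter_enrichment calls zero positives
  ds1 <- generate_target_dataset(
    targets_config(n_genes = 60, promoter_enrichment_high = 1,
                   promoter_enrichment_low = 1, seed = 17))
  expect_false(any(promoter_enrichment(ds1$signals)$positive))
})

test_that("single-cell generator: construction guarantees", {
  # no mislabeling: the consistency filter keeps every cell
  sc0 <- generate_singlecell_dataset(
    single_cell_config(dye_mislabel_rate = 0, seed = 18))
  expect_true(all(assign_genotype(sc0$cell_meta)$kept))
  # deterministic class in knockouts (p_ko = 1): every cell expresses all
  bin <- detection_matrix(sc0$expr)
  ko_cells <- names(sc0$truth$genotype)[sc0$truth$genotype == "ko"]
  resp_genes <- names(sc0$truth$gene_class)[
    sc0$truth$gene_class == "responsive"]
  expect_true(all(bin[resp_genes, ko_cells]))
  # stochastic class at p = 0.5 with many cells: frequency 0.5 +- 0.05
  sc1 <- generate_singlecell_dataset(single_cell_config(
    n_wt_cells = 1000, n_ko_cells = 10,
    gene_classes = list(stoch = list(n_genes = 5, p_wt = 0.5, p_ko = 0.5,
                                     deterministic = FALSE)),
    dye_mislabel_rate = 0, seed = 19))
  wt_cells <- names(sc1$truth$genotype)[sc1$truth$genotype == "wt"]
  freqs <- rowMeans(detection_matrix(sc1$expr)[paste0("STOCH_0", 1:5),
                                               wt_cells])
  expect_true(all(abs(freqs - 0.5) < 0.05))
  # mislabel rate is recovered by the filter's drop rate (binomial CI)
  sc2 <- generate_singlecell_dataset(single_cell_config(
    n_wt_cells = 500, n_ko_cells = 500, dye_mislabel_rate = 0.1,
    seed = 20))
  drop <- mean(!assign_genotype(sc2$cell_meta)$kept)
  expect_lt(abs(drop - 0.1), 3 * sqrt(0.1 * 0.9 / 1000))
})
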