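# Rank product, differential calling, promoter enrichment, classification.

test_that("rank_product basics: minimum RP, ties, input validation", {
  fc <- cbind(r1 = c(3, 1, 0.2, -1), r2 = c(2.5, 1.2, 0.1, -0.5))
  rownames(fc) <- paste0("g", 1:4)
  rp <- rank_product(fc, B = 100, seed = 1)
  expect_equal(rp$rp[1], 1)  # ranked 1 in both replicates
  expect_equal(rp$gene, paste0("g", 1:4))
  # tied fold changes get average ranks
  fct <- cbind(c(2, 2, 0), c(1, 1, 0))
  rpt <- rank_product(fct, B = 100, seed = 1)
  expect_equal(rpt$rp[1], rpt$rp[2])
  expect_equal(rpt$rp[1], 1.5)
  expect_error(rank_product(fc[, 1, drop = FALSE], B = 100, seed = 1),
               "k >= 2")
  expect_error(rank_product(fc, B = 10, seed = 1), "B >= 100")
})

test_that("rank_product pfp matches exhaustive enumeration on 4-gene k=2", {
  set.seed(601)
  for (i in 1:3) {
    fc <- matrix(rnorm(8), nrow = 4,
                 dimnames = list(paste0("g", 1:4), NULL))
    oracle <- pfp_exhaustive_oracle(fc)
    rp <- rank_product(fc, B = 4000, seed = 601 + i)
    expect_equal(rp$pfp, oracle, tolerance = 0.05)
  }
})

test_that("pfp-based calling controls false positives on pure-noise data", {
  set.seed(602)
  fc <- matrix(rnorm(400), nrow = 200)
  rownames(fc) <- sprintf("g%03d", 1:200)
  rp <- rank_product(fc, B = 200, seed = 602)
  called <- call_differential(rp, fc, pfp_max = 0.15, fc_min = 1e-9)
  expect_lte(length(called), 0.15 * 200)
})

test_that("call_differential applies both gates", {
  fc <- rbind(a = c(log2(2.5), log2(2.5)),  # FC 2.5
              b = c(log2(1.9), log2(1.9)),  # FC 1.9: fails FC gate
              c = c(-2, -2))
  rp <- data.frame(gene = c("a", "b", "c"), rp = c(1, 2, 3),
                   pfp = c(0.10, 0.01, 0.9), direction = "up")
  expect_equal(call_differential(rp, fc), "a")
  expect_error(call_differential(rp, fc, pfp_max = 0), "> 0")
})

make_signal_fixture <- function(folds, strands = NULL, bin = 100L,
                                noise = 0) {
  n <- length(folds)
  ann <- data.frame(gene_id = paste0("g", seq_len(n)), chrom = "c1",
                    tss = seq_len(n) * 10000L - 5000L + 1L,
                    strand = if (is.null(strands)) rep("+", n) else strands,
                    stringsAsFactors = FALSE)
  wt <- prc2suite:::build_coverage(ann, region_half = 5000L, bin_bp = bin,
                                   base_level = 1, prom_half = 2000L,
                                   prom_fold_by_gene = folds,
                                   noise_cv = noise)
  ko <- prc2suite:::build_coverage(ann, region_half = 5000L, bin_bp = bin,
                                   base_level = 1, prom_half = 2000L,
                                   prom_fold_by_gene = rep(1, n),
                                   noise_cv = noise)
  promoter_signal_set(list(wt = wt, ko = ko), ann)
}

test_that("promoter_enrichment: uniform coverage yields zero positives", {
  sig <- make_signal_fixture(rep(1, 6))
  enr <- promoter_enrichment(sig)
  expect_false(any(enr$positive))
})

test_that("promoter_enrichment calls exactly the planted genes", {
  folds <- rep(c(5, 1), each = 5)
  sig <- make_signal_fixture(folds)
  enr <- promoter_enrichment(sig, threshold_fold = 2)
  expect_equal(enr$positive, folds == 5)
  # enrichment scores reflect the planted fold over background
  bg_adj <- mean(folds == 5) * 5 + mean(folds == 1)  # promoter raises background
  expect_gt(mean(enr$enrichment[folds == 5]), mean(enr$enrichment[folds == 1]))
})

test_that("minus-strand windows mirror plus-strand windows about the TSS", {
  sig <- make_signal_fixture(c(4, 4), strands = c("+", "-"))
  enr <- promoter_enrichment(sig)
  expect_equal(enr$wt_mean[1], enr$wt_mean[2], tolerance = 1e-12)
  prof_p <- tss_density_profile(sig, "g1", window_bp = 3000, bin_bp = 100)
  prof_m <- tss_density_profile(sig, "g2", window_bp = 3000, bin_bp = 100)
  # symmetric planted signal: mirrored profile identical
  expect_equal(prof_p$density, rev(prof_m$density), tolerance = 1e-12)
})

test_that("scaling factors commute with enrichment thresholding", {
  sig <- make_signal_fixture(rep(c(5, 1), 3))
  # applying a knockout scaling factor via the signal set equals pre-scaling
  sig_scaled <- promoter_signal_set(sig$conditions, sig$annotation,
                                    scaling = c(ko = 0.05))
  pre <- sig$conditions
  pre$ko$value <- pre$ko$value * 0.05
  sig_pre <- promoter_signal_set(pre, sig$annotation)
  expect_equal(promoter_enrichment(sig_scaled)$positive,
               promoter_enrichment(sig_pre)$positive)
})

test_that("classify_targets partitions the gene universe", {
  all_genes <- paste0("g", 1:10)
  cls <- classify_targets(c("g1", "g2", "g3"), c("g3", "g4", "g5"),
                          all_genes)
  expect_equal(unname(cls$counts),
               c(1L, 2L, 2L, 5L))  # responsive, indirect, nonresponsive, null
  expect_equal(sum(cls$counts), 10L)
  expect_equal(as.character(cls$labels[["g3"]]), "responsive")
  # disjoint sets: no responsive; up subset of positive: no indirect
  expect_equal(unname(classify_targets("g1", "g2", all_genes)$counts[1]), 0L)
  expect_equal(unname(classify_targets("g2", c("g1", "g2"),
                                       all_genes)$counts[2]), 0L)
  expect_error(classify_targets("zz", "g1", all_genes), "subsets")
})

test_that("normalize_timecourse: ratios to time 0 on both scales", {
  tc <- timecourse_matrix(matrix(c(1, 2, 3, 4), nrow = 1),
                          times = c(0, 5, 0, 5), replicates = c(1, 1, 2, 2))
  rownames(tc) <- "g1"
  norm_log <- normalize_timecourse(tc)
  expect_equal(as.numeric(norm_log), c(0, 1, 0, 1))
  # linear scale: value(t)/value(0)
  lin <- timecourse_matrix(matrix(c(2, 4), nrow = 1), c(0, 5), c(1, 1))
  rownames(lin) <- "g1"
  expect_equal(as.numeric(normalize_timecourse(lin, scale = "linear")),
               c(1, 2))
  # log2 input: output equals 2^(x_t - x_0) after exponentiation
  set.seed(603)
  x <- matrix(rnorm(8, 6), nrow = 2, dimnames = list(c("a", "b"), NULL))
  tcl <- timecourse_matrix(x, c(0, 5, 0, 5), c(1, 1, 2, 2))
  expect_equal(2^normalize_timecourse(tcl)[, 2],
               2^(x[, 2] - x[, 1]), tolerance = 1e-12)
  # zero t0 on linear scale errors naming the gene
  lin0 <- timecourse_matrix(matrix(c(0, 4), nrow = 1), c(0, 5), c(1, 1))
  rownames(lin0) <- "gene_x"
  expect_error(normalize_timecourse(lin0, scale = "linear"), "gene_x")
})

test_that("classify_early_late separates planted timings", {
  set.seed(604)
  n <- 60
  genes <- sprintf("g%02d", 1:n)
  base <- rnorm(n, 6)
  early <- genes[1:3]; late <- genes[4:8]
  tp <- c(0, 0, 5, 5, 10, 10); reps <- c(1, 2, 1, 2, 1, 2)
  # effect of 2 log2 units for early genes from t=5, late genes only at t=10
  vals <- matrix(base, n, 6) + matrix(rnorm(n * 6, 0, 0.2), n)
  for (j in seq_along(tp)) {
    vals[genes %in% early, j] <- vals[genes %in% early, j] +
      ifelse(tp[j] >= 5, 2, 0)
    vals[genes %in% late, j] <- vals[genes %in% late, j] +
      ifelse(tp[j] >= 10, 2, 0)
  }
  rownames(vals) <- genes
  tc <- timecourse_matrix(vals, tp, reps)
  timing <- classify_early_late(tc, c(early, late), 5,
                                de_rule = list(B = 200, seed = 604))
  expect_equal(as.character(timing[early]), rep("early", 3))
  expect_equal(as.character(timing[late]), rep("late", 5))
  expect_true(all(is.na(timing[setdiff(genes, c(early, late))])))
})

test_that("classify_rescue labels planted rescue status", {
  set.seed(605)
  n <- 50
  genes <- sprintf("g%02d", 1:n)
  base <- matrix(rnorm(n * 2, 6, 0.2), n, dimnames = list(genes, NULL))
  resp <- genes[1:10]; stuck <- genes[1:3]
  rescue <- base + ifelse(genes %in% stuck, 2, 0) +
    matrix(rnorm(n * 2, 0, 0.2), n)
  lab <- classify_rescue(base, rescue, resp,
                         de_rule = list(B = 200, seed = 605))
  expect_equal(as.character(lab[stuck]), rep("non_rescued", 3))
  expect_equal(as.character(lab[setdiff(resp, stuck)]), rep("rescued", 7))
  # rescue identical to wild type: everything rescued
  lab_same <- classify_rescue(base, base, resp,
                              de_rule = list(B = 200, seed = 605))
  expect_true(all(lab_same[resp] == "rescued"))
})

test_that("tss_density_profile: single gene equals its own binned signal", {
  sig <- make_signal_fixture(3)
  prof <- tss_density_profile(sig, "g1", window_bp = 2000, bin_bp = 100)
  a <- sig$annotation[1, ]
  tss0 <- a$tss - 1
  own <- vapply(seq_len(40), function(j) {
    s <- tss0 - 2000 + (j - 1) * 100
    prc2suite:::coverage_window_mean(sig$conditions$wt, a$chrom, s, s + 100)
  }, numeric(1))
  expect_equal(prof$density, own)
  expect_error(tss_density_profile(sig, character(0)), "empty")
})
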