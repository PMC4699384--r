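# Command-line pipeline tying the stages together. `run_pipeline()` takes an
# argv-style character vector (subcommand first, then `--key value` flags),
# writes TSV/JSON artifacts plus a provenance file into the output
# directory, and returns an exit status: 0 success, 2 missing input,
# 3 validation/processing failure. A thin Rscript wrapper lives at
# inst/cli/prc2suite.R. Logging goes to stderr; results are never written to
# stdout.

parse_args <- function(args) {
  if (length(args) == 0L) stop_bad("no subcommand given")
  sub <- args[1]
  rest <- args[-1]
  flags <- list()
  i <- 1L
  while (i <= length(rest)) {
    key <- rest[i]
    if (!startsWith(key, "--"))
      stop_bad("unexpected argument '%s' (flags are --key value)", key)
    if (i + 1L > length(rest)) stop_bad("flag '%s' missing a value", key)
    flags[[substring(key, 3)]] <- rest[i + 1L]
    i <- i + 2L
  }
  list(subcommand = sub, flags = flags)
}

log_msg <- function(...) message("[prc2suite] ", sprintf(...))

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

write_provenance <- function(out_dir, subcommand, flags, seed) {
  write_json_out(list(
    tool = "prc2suite",
    version = as.character(utils::packageVersion("prc2suite")),
    subcommand = subcommand,
    parameters = flags,
    seed = seed,
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(out_dir, "provenance.json"))
}

read_config_json <- function(flags) {
  if (is.null(flags$config)) return(list())
  jsonlite::read_json(flags$config, simplifyVector = TRUE)
}

#' Run a pipeline subcommand
#'
#' Subcommands: `simulate-cohort`, `simulate-growth`, `simulate-targets`,
#' `simulate-cells` (synthetic-data generators writing their standard file
#' formats), `prognosis` (marker adjustment + survival suite), `scan`
#' (per-gene copy-number-loss Cox scan), `homeostasis` (trajectory + sweep),
#' `targets` (target classification from bedGraph + time course), and
#' `singlecell` (genotype filter, frequencies, concordance). Parameters come
#' from an optional JSON config (`--config`) with `--key value` flags taking
#' precedence; `--out` names the output directory and `--seed` the RNG seed
#' (always recorded in `provenance.json`).
#'
#' @param args Character vector of command-line arguments.
#' @return (Invisibly) an integer exit status: 0 success, 2 missing input
#'   file, 3 validation or processing failure.
#' @export
run_pipeline <- function(args) {
  status <- tryCatch({
    parsed <- parse_args(args)
    flags <- parsed$flags
    # required input files must exist before anything else runs
    file_flags <- intersect(names(flags),
                            c("config", "expr", "clinical", "cnv", "geneset",
                              "wt-bedgraph", "ko-bedgraph", "annotation",
                              "timecourse", "rescue-wt", "rescue-post",
                              "cells", "cell-meta", "genes"))
    for (f in file_flags) {
      if (!file.exists(flags[[f]])) {
        log_msg("missing input: %s (%s)", flags[[f]], f)
        return(invisible(2L))
      }
    }
    out_dir <- flags$out %||% "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    seed <- if (!is.null(flags$seed)) as.integer(flags$seed) else NULL
    dispatch_subcommand(parsed$subcommand, flags, out_dir, seed)
    write_provenance(out_dir, parsed$subcommand, flags, seed)
    0L
  }, error = function(e) {
    log_msg("error: %s", conditionMessage(e))
    3L
  })
  invisible(status)
}

dispatch_subcommand <- function(sub, flags, out_dir, seed) {
  cfg <- read_config_json(flags)
  if (!is.null(seed)) cfg$seed <- seed
  switch(sub,
    "simulate-cohort" = {
      cc <- do.call(cohort_config, cfg)
      cohort <- generate_cohort(cc)
      write_expression_tsv(cohort$expr, file.path(out_dir, "expression.tsv"))
      write_clinical_tsv(cohort$clinical, file.path(out_dir, "clinical.tsv"))
      write_cnv_tsv(cohort$cnv, file.path(out_dir, "cnv.tsv"))
      writeLines(cohort$prolif_genes, file.path(out_dir, "geneset.txt"))
      write_json_out(cohort$truth[c("P", "R", "log_hazard")],
                     file.path(out_dir, "truth.json"))
      log_msg("cohort written to %s", out_dir)
    },
    "simulate-growth" = {
      gc <- do.call(growth_experiment_config, cfg)
      tab <- generate_growth_experiment(gc)
      utils::write.table(tab, file.path(out_dir, "growth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    "simulate-targets" = {
      tc <- do.call(targets_config, cfg)
      ds <- generate_target_dataset(tc)
      write_bedgraph(ds$signals$conditions$wt,
                     file.path(out_dir, "wt.bedgraph"))
      write_bedgraph(ds$signals$conditions$ko,
                     file.path(out_dir, "ko.bedgraph"))
      utils::write.table(ds$signals$annotation,
                         file.path(out_dir, "annotation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_expression_tsv(unclass(ds$timecourse),
                           file.path(out_dir, "timecourse.tsv"))
      write_expression_tsv(ds$rescue$wt, file.path(out_dir, "rescue_wt.tsv"))
      write_expression_tsv(ds$rescue$rescue,
                           file.path(out_dir, "rescue_post.tsv"))
      utils::write.table(ds$truth, file.path(out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    "simulate-cells" = {
      sc <- do.call(single_cell_config, cfg)
      ds <- generate_singlecell_dataset(sc)
      write_expression_tsv(ds$expr, file.path(out_dir, "cells.tsv"))
      utils::write.table(ds$cell_meta, file.path(out_dir, "cell_meta.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_json_out(lapply(ds$truth, as.list),
                     file.path(out_dir, "truth.json"))
    },
    "prognosis" = {
      for (f in c("expr", "clinical", "geneset", "marker"))
        if (is.null(flags[[f]])) stop_bad("prognosis requires --%s", f)
      expr <- read_expression_tsv(flags$expr)
      clinical <- read_clinical_tsv(flags$clinical)
      prolif <- readLines(flags$geneset)
      prolif <- prolif[nzchar(prolif)]
      res <- marker_prognosis(expr, clinical, flags$marker, prolif)
      out <- list(
        marker = flags$marker,
        raw = list(hr_high_vs_low = res$raw$hr_high_vs_low,
                   logrank_p = res$raw$logrank$p_value,
                   auc = res$raw$auc),
        adjusted = list(hr_high_vs_low = res$adjusted_marker$hr_high_vs_low,
                        logrank_p = res$adjusted_marker$logrank$p_value,
                        auc = res$adjusted_marker$auc),
        fit = list(intercept = res$adjusted$intercept,
                   slope = res$adjusted$slope))
      if (!is.null(flags$cnv)) {
        cnv <- read_cnv_tsv(flags$cnv)
        grp <- stratify_by_cnv(cnv[clinical$sample_id, flags$marker])
        lr <- logrank_test(clinical$time, clinical$event, grp)
        out$cnv_stratification <- list(
          groups = as.list(table(grp)), chisq = lr$chisq, p = lr$p_value)
      }
      write_json_out(out, file.path(out_dir, "results.json"))
      for (which in c("raw", "adjusted_marker")) {
        grp <- res[[which]]$groups
        curves <- do.call(rbind, lapply(levels(grp), function(l) {
          km <- km_estimate(clinical$time[grp == l],
                            clinical$event[grp == l])
          cbind(group = l, as.data.frame(km))
        }))
        utils::write.table(curves,
                           file.path(out_dir, paste0("km_", sub("_marker", "",
                                                                which),
                                                     ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    },
    "scan" = {
      for (f in c("cnv", "clinical"))
        if (is.null(flags[[f]])) stop_bad("scan requires --%s", f)
      cnv <- read_cnv_tsv(flags$cnv)
      clinical <- read_clinical_tsv(flags$clinical)
      genes <- if (!is.null(flags$genes)) {
        g <- readLines(flags$genes); g[nzchar(g)]
      } else colnames(cnv)
      fdr <- as.numeric(flags$fdr %||% 0.15)
      res <- chromosome_scan(cnv, clinical, genes, fdr_threshold = fdr)
      utils::write.table(res, file.path(out_dir, "scan.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    "homeostasis" = {
      p <- mark_kinetics_params(cfg$alpha %||% 1, cfg$delta %||% 0,
                                cfg$g %||% 0.03, E = cfg$E,
                                c0 = cfg$c0, c1 = cfg$c1)
      traj <- simulate_mark_dynamics(p, t_end = cfg$t_end %||% 500,
                                     dt = cfg$dt %||% 0.01,
                                     m0 = cfg$m0 %||% 0.5,
                                     variant = cfg$variant %||% "continuous")
      utils::write.table(as.data.frame(traj),
                         file.path(out_dir, "trajectory.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (!is.null(cfg$c0) && !is.null(cfg$c1)) {
        rates <- cfg$rates %||% c(0.01, 0.02, 0.03, 0.04, 0.05)
        sw <- sweep_growth_rates(cfg$alpha %||% 1, cfg$delta %||% 0,
                                 cfg$c0, cfg$c1, rates)
        utils::write.table(sw, file.path(out_dir, "sweep.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    },
    "targets" = {
      for (f in c("wt-bedgraph", "ko-bedgraph", "annotation", "timecourse"))
        if (is.null(flags[[f]])) stop_bad("targets requires --%s", f)
      ann <- read_annotation_tsv(flags$annotation)
      scaling <- NULL
      if (!is.null(cfg$scaling)) scaling <- unlist(cfg$scaling)
      signals <- promoter_signal_set(
        list(wt = read_bedgraph(flags[["wt-bedgraph"]]),
             ko = read_bedgraph(flags[["ko-bedgraph"]])),
        ann, scaling = scaling)
      tc_raw <- read_expression_tsv(flags$timecourse)
      info <- parse_timecourse_columns(colnames(tc_raw))
      tc <- timecourse_matrix(tc_raw, info$time, info$replicate)
      final_t <- max(info$time)
      fc <- timecourse_fold_changes(tc, final_t)
      rp <- rank_product(fc, B = as.integer(cfg$B %||% 200),
                         seed = cfg$seed %||% 1L)
      up <- call_differential(rp, fc, pfp_max = cfg$pfp_max %||% 0.15,
                              fc_min = cfg$fc_min %||% 2)
      enr <- promoter_enrichment(signals,
                                 window_bp = cfg$window_bp %||% 2000,
                                 threshold_fold = cfg$threshold_fold %||% 2)
      cls <- classify_targets(up, enr$gene_id[enr$positive], rownames(tc))
      timing <- classify_early_late(
        tc, names(cls$labels)[cls$labels == "responsive"],
        early_timepoint = sort(unique(info$time))[2],
        de_rule = list(B = as.integer(cfg$B %||% 200),
                       seed = cfg$seed %||% 1L))
      lab_df <- data.frame(gene_id = names(cls$labels),
                           class = as.character(cls$labels),
                           timing = as.character(timing),
                           stringsAsFactors = FALSE)
      if (!is.null(flags[["rescue-wt"]]) &&
          !is.null(flags[["rescue-post"]])) {
        resc <- classify_rescue(
          read_expression_tsv(flags[["rescue-wt"]]),
          read_expression_tsv(flags[["rescue-post"]]),
          names(cls$labels)[cls$labels == "responsive"],
          de_rule = list(B = as.integer(cfg$B %||% 200),
                         seed = cfg$seed %||% 1L))
        lab_df$rescue <- as.character(resc)
      }
      utils::write.table(lab_df, file.path(out_dir, "labels.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_json_out(as.list(cls$counts), file.path(out_dir, "venn.json"))
    },
    "singlecell" = {
      for (f in c("cells", "cell-meta"))
        if (is.null(flags[[f]])) stop_bad("singlecell requires --%s", f)
      expr <- read_expression_tsv(flags$cells)
      meta <- read_cell_metadata_tsv(flags[["cell-meta"]])
      assigned <- assign_genotype(meta)
      kept <- assigned[assigned$kept, ]
      sub <- expr[, kept$cell_id, drop = FALSE]
      bin <- detection_matrix(sub,
                              threshold = as.numeric(cfg$threshold %||% 0))
      panel <- setdiff(rownames(bin), "Ezh2")
      freq <- expression_frequency(bin[panel, , drop = FALSE],
                                   kept$genotype)
      gene_sets <- if (!is.null(flags$genes)) {
        list(panel = readLines(flags$genes))
      } else list(panel = panel)
      conc <- lapply(gene_sets, function(gs) {
        r <- concordance_score(bin, gs, B = as.integer(cfg$B %||% 1000),
                               seed = cfg$seed %||% 1L)
        list(statistic = r$statistic, p_value = r$p_value)
      })
      write_json_out(list(
        n_cells_in = nrow(assigned), n_cells_kept = nrow(kept),
        dropped = as.list(table(assigned$drop_reason[!assigned$kept])),
        frequencies = freq, concordance = conc),
        file.path(out_dir, "results.json"))
    },
    stop_bad("unknown subcommand '%s'", sub)
  )
  invisible(NULL)
}

# Parse "t<time>_r<rep>" column labels written by the simulators.
parse_timecourse_columns <- function(cols) {
  m <- regmatches(cols, regexec("^t([0-9.]+)_r(.+)$", cols))
  if (any(lengths(m) != 3L))
    stop_bad("time-course columns must be labelled t<time>_r<replicate>")
  list(time = as.numeric(vapply(m, `[`, "", 2L)),
       replicate = vapply(m, `[`, "", 3L))
}
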