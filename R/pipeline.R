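# Pipeline orchestration from a single JSON config, plus figure output
# and a small subcommand-style CLI.

read_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$seed))
    stop("config must set an explicit seed", call. = FALSE)
  if (!is.null(config$simulate) && !is.null(config$inputs))
    stop("config names both real inputs and a simulate block ",
         "(ambiguous source)", call. = FALSE)
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config must name either input files or a simulate block",
         call. = FALSE)
  config
}

config_analysis <- function(config) {
  a <- config$analysis
  if (is.null(a)) a <- list()
  a$seed <- config$seed
  do.call(analysis_config, a)
}

#' Run the full pipeline from one config
#'
#' Executes simulate (optional) -> preprocess -> differential ->
#' integrate, writing every tabular output under one run directory.
#' Rerunning with the same config and seed reproduces all numeric
#' outputs bit-identically. The config is a JSON file (or list) with
#' fields `seed`, `outdir`, an `analysis` block of [analysis_config()]
#' overrides, and either a `simulate` block (`n_genes`, `n_pairs`,
#' `truth`, optional `noise` overrides, `probes_per_gene_range`,
#' `sex_chrom_fraction`) or an `inputs` block naming `manifest`, `meth`,
#' `unmeth`, `detp` (optional), `sheet` and `expression` files.
#'
#' @param config path to a JSON config file, or an equivalent list.
#' @return `PipelineRunRecord`: config snapshot, stage timings, probe
#'   counts surviving each filter, output file inventory, version string.
#'   Also written as `run_record.json` in the run directory.
#' @export
run_pipeline <- function(config) {
  config <- read_config(config)
  outdir <- if (is.null(config$outdir)) "avmeth_run" else config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config_analysis(config)
  timings <- c()
  files <- character(0)
  counts <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      writeLines("FAILED", file.path(outdir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(fname) {
    files <<- c(files, fname)
    file.path(outdir, fname)
  }

  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      sb <- config$simulate
      manifest <- simulate_manifest(
        n_genes = sb$n_genes,
        probes_per_gene_range =
          if (is.null(sb$probes_per_gene_range)) c(3L, 12L)
          else sb$probes_per_gene_range,
        sex_chrom_fraction =
          if (is.null(sb$sex_chrom_fraction)) 0.03
          else sb$sex_chrom_fraction,
        seed = config$seed)
      noise <- do.call(noise_defaults,
                       if (is.null(sb$noise)) list() else sb$noise)
      truth <- sb$truth
      simulate_dataset(manifest,
                       n_pairs = if (is.null(sb$n_pairs)) 9L else sb$n_pairs,
                       truth = truth, noise = noise,
                       seed = config$seed + 1L)
    })
    ds <- sim$dataset
    expr <- sim$expression
    truth_small <- sim$truth[c("dmr_ledger", "reciprocal_genes",
                               "global_offset", "seed", "params")]
    jsonlite::write_json(truth_small, emit("truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    ds <- stage("read_inputs", {
      inp <- config$inputs
      read_array_dataset(inp$meth, inp$unmeth, inp$detp, inp$sheet,
                         inp$manifest)
    })
    expr <- read_expression(config$inputs$expression, ds$samples)
    sim <- NULL
  }
  write_manifest(ds$annotation, emit("manifest.csv"))
  write_sample_sheet(ds$samples, emit("sample_sheet.csv"))
  counts$probes_input <- nrow(ds$meth)

  mm <- stage("preprocess", {
    ds <- compute_detection_p(ds)
    ds <- qc_filter(ds, cfg)
    mm <- compute_beta_m(ds)
    normalize_type2(mm)
  })
  counts$probes_after_qc <- nrow(mm$beta)
  write_matrix_tsv(mm$beta, emit("beta.tsv"))
  write_matrix_tsv(mm$mvalue, emit("mvalue.tsv"))
  jsonlite::write_json(mm$qc_log, emit("qc_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  gm <- global_methylation(mm)
  utils::write.table(
    data.frame(sample_id = names(gm$per_sample_mean_beta),
               group = mm$samples$group[match(names(gm$per_sample_mean_beta),
                                              mm$samples$sample_id)],
               mean_beta = gm$per_sample_mean_beta),
    emit("global_methylation.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)

  clu <- stage("cluster", {
    ids <- top_variable(mm, min(cfg$top_n_variable, nrow(mm$beta)))
    hierarchical_cluster(mm, ids)
  })
  utils::write.table(
    data.frame(merge1 = clu$merge[, 1], merge2 = clu$merge[, 2],
               height = clu$height),
    emit("cluster_merges.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  writeLines(clu$sample_order, emit("cluster_sample_order.txt"))

  dmps <- stage("differential", call_dmps(mm, config = cfg))
  counts$dmps_called <- sum(dmps$is_dmp)
  write_dmp_table(dmps, emit("dmp_table.tsv"))
  write_dmp_bed(dmps[dmps$is_dmp, ], mm$annotation, emit("dmp.bed"))
  eb <- attr(dmps, "ebayes")
  jsonlite::write_json(list(d0 = if (is.infinite(eb$d0)) "Inf" else eb$d0,
                            s0_sq = eb$s0_sq),
                       emit("ebayes_hyperparams.json"),
                       auto_unbox = TRUE, digits = NA)

  dmrs <- aggregate_dmrs(dmps, mm$annotation,
                         min_probes = cfg$min_dmr_probes,
                         max_gap = cfg$max_dmr_gap)
  counts$dmrs <- nrow(dmrs)
  utils::write.table(dmrs, emit("dmr_table.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  de <- stage("expression", expression_logfc(expr, config = cfg))
  utils::write.table(de, emit("de_table.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  ints <- stage("integrate", integrate_gene(dmps, de, mm$annotation, cfg))
  utils::write.table(ints, emit("probe_quadrants.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(attr(ints, "gene_summary"),
                     emit("gene_integration.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  qt <- quadrant_region_table(ints, mm$annotation)
  utils::write.table(
    data.frame(family = rownames(qt$counts), qt$counts,
               check.names = FALSE),
    emit("quadrant_region_counts.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)

  record <- list(
    package_version = as.character(utils::packageVersion("avmeth")),
    config = config,
    stage_seconds = as.list(timings),
    counts = counts,
    files = files
  )
  jsonlite::write_json(record, file.path(outdir, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  record$files <- c(files, "run_record.json")
  record$outdir <- outdir
  class(record) <- "PipelineRunRecord"
  invisible(record)
}

#' Publication-style figures from a completed run
#'
#' Renders (as PNG, next to the tables they view): a clustered heatmap of
#' the most variable probes with the dendrogram sample order; the
#' starburst scatter of delta-beta vs logFC with gate lines at the two
#' thresholds; and a per-gene probe-position profile with group means and
#' 95% confidence intervals. Figures are views of the TSV outputs, never
#' the only record.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param config `AnalysisConfig` used for the gate lines.
#' @param profile_gene gene to profile (default: gene with most DMPs, or
#'   first gene if none).
#' @return character vector of figure paths.
#' @export
plot_outputs <- function(run_dir, config = analysis_config(),
                         profile_gene = NULL) {
  figs <- character(0)
  beta <- read_matrix_tsv(file.path(run_dir, "beta.tsv"))
  mval <- read_matrix_tsv(file.path(run_dir, "mvalue.tsv"))
  sheet <- read_sample_sheet(file.path(run_dir, "sample_sheet.csv"))
  ann <- read_manifest(file.path(run_dir, "manifest.csv"))
  quads <- utils::read.delim(file.path(run_dir, "probe_quadrants.tsv"),
                             stringsAsFactors = FALSE)
  order_txt <- readLines(file.path(run_dir, "cluster_sample_order.txt"))

  # heatmap of the clustered variable probes, sample order from the tree
  f <- file.path(run_dir, "fig_heatmap.png")
  grDevices::png(f, 900, 700)
  cv <- apply(beta, 1, stats::sd) / rowMeans(beta)
  top <- rownames(beta)[order(-cv, rownames(beta))][
    seq_len(min(1000, nrow(beta)))]
  m <- mval[top, order_txt, drop = FALSE]
  graphics::image(t(m[order(rowMeans(m)), ]), axes = FALSE,
                  col = grDevices::hcl.colors(50, "RdBu", rev = TRUE),
                  main = "Most variable probes (M-values)")
  graphics::axis(1, at = seq(0, 1, length.out = ncol(m)),
                 labels = colnames(m), las = 2, cex.axis = 0.7)
  grDevices::dev.off()
  figs <- c(figs, f)

  # starburst scatter with gates
  f <- file.path(run_dir, "fig_starburst.png")
  grDevices::png(f, 700, 700)
  hl <- quads$quadrant != "none"
  graphics::plot(quads$delta_beta, quads$logfc, pch = 16, cex = 0.4,
                 col = ifelse(hl, "red", "grey60"),
                 xlab = expression(Delta * beta ~ "(arterial - venous)"),
                 ylab = "log2 fold change (arterial - venous)",
                 main = "Methylation vs expression")
  graphics::abline(v = c(-1, 1) * config$delta_beta_cutoff, lty = 2)
  graphics::abline(h = c(-1, 1) * config$logfc_cutoff, lty = 2)
  grDevices::dev.off()
  figs <- c(figs, f)

  # per-gene probe profile with group means and 95% CIs
  if (is.null(profile_gene)) {
    dmp_by_gene <- table(quads$gene[quads$delta_beta != 0])
    cand <- quads$gene[order(-abs(quads$delta_beta))]
    profile_gene <- if (length(cand)) cand[1] else quads$gene[1]
  }
  pid <- quads$probe_id[quads$gene == profile_gene]
  pid <- pid[pid %in% rownames(beta)]
  if (length(pid) > 0) {
    pos <- ann$position[match(pid, ann$probe_id)]
    pid <- pid[order(pos)]
    f <- file.path(run_dir, "fig_gene_profile.png")
    grDevices::png(f, 800, 500)
    a <- sheet$sample_id[sheet$group == "arterial"]
    v <- sheet$sample_id[sheet$group == "venous"]
    ma <- rowMeans(beta[pid, a, drop = FALSE])
    mv <- rowMeans(beta[pid, v, drop = FALSE])
    ci <- function(x) 1.96 * apply(x, 1, stats::sd) / sqrt(ncol(x))
    cia <- ci(beta[pid, a, drop = FALSE])
    civ <- ci(beta[pid, v, drop = FALSE])
    xs <- seq_along(pid)
    graphics::plot(xs, ma, type = "b", pch = 2, ylim = c(0, 1),
                   xlab = paste0(profile_gene, " probes (5'->3')"),
                   ylab = "mean beta", main = profile_gene)
    graphics::lines(xs, mv, type = "b", pch = 15)
    graphics::arrows(xs, ma - cia, xs, ma + cia, angle = 90, code = 3,
                     length = 0.03)
    graphics::arrows(xs, mv - civ, xs, mv + civ, angle = 90, code = 3,
                     length = 0.03)
    graphics::legend("topright", legend = c("arterial", "venous"),
                     pch = c(2, 15))
    grDevices::dev.off()
    figs <- c(figs, f)
  }
  figs
}

#' Command-line interface
#'
#' A small subcommand CLI:
#' `Rscript -e 'avmeth::avmeth_cli()' <cmd> --config cfg.json` with
#' `cmd` one of `simulate`, `preprocess`, `dmp`, `integrate`, `report`
#' or `run`. All subcommands are driven by the same JSON config; `run`
#' executes the whole pipeline, the stage subcommands run the pipeline
#' up to (and including) their stage, and `report` renders figures for
#' an existing run directory.
#'
#' @param args character vector (default: command-line arguments).
#' @return exit-style integer, invisibly.
#' @export
avmeth_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: avmeth <simulate|preprocess|dmp|integrate|run|report> ",
    "--config <file.json>")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  ci <- which(args == "--config")
  if (cmd != "report" && (length(ci) != 1 || ci + 1 > length(args))) {
    message(usage); return(invisible(1L))
  }
  if (cmd %in% c("simulate", "preprocess", "dmp", "integrate", "run")) {
    # the stages are cheap relative to IO; stage subcommands simply run
    # the pipeline through (outputs of later stages are a superset)
    rec <- run_pipeline(args[ci + 1])
    message("run complete: ", length(rec$files), " files in ",
            rec$outdir)
  } else if (cmd == "report") {
    di <- which(args == "--run-dir")
    dir <- if (length(di) == 1) args[di + 1] else
      if (length(ci) == 1) read_config(args[ci + 1])$outdir else
        "avmeth_run"
    figs <- plot_outputs(dir)
    message("wrote ", length(figs), " figure(s)")
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
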