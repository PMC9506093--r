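#' Assemble a run configuration
#'
#' @param matrix_dir directory with the 10x-style bundle
#' @param clusters_file barcode -> cluster TSV
#' @param pairs_file interaction-pair TSV
#' @param markers_file optional marker TSV (gene, cell type); enables the
#'   annotation step
#' @param out_dir output directory (created if absent)
#' @param dialect,modality passed to [read_10x()]
#' @param qc_level,qc_method passed to [filter_outliers()]
#' @param norm_scale passed to [normalize_counts()]
#' @param raw_average average raw counts instead of normalized expression
#'   (exact emulation of UMI-scale cluster averages)
#' @param coexpr a [coexpr_config()]
#' @param null a [null_config()]
#' @return a `run_config` list
#' @export
run_config <- function(matrix_dir, clusters_file, pairs_file,
                       markers_file = NULL, out_dir = "coexpair_out",
                       dialect = "genes_as_rows", modality = "cell",
                       qc_level = 0.95, qc_method = "percentile",
                       norm_scale = 1e4, raw_average = FALSE,
                       coexpr = coexpr_config(), null = null_config()) {
  cfg <- list(matrix_dir = matrix_dir, clusters_file = clusters_file,
              pairs_file = pairs_file, markers_file = markers_file,
              out_dir = out_dir, dialect = dialect, modality = modality,
              qc_level = qc_level, qc_method = qc_method,
              norm_scale = norm_scale, raw_average = isTRUE(raw_average),
              coexpr = coexpr, null = null)
  for (p in c(cfg$matrix_dir, cfg$clusters_file, cfg$pairs_file,
              cfg$markers_file))
    if (!file.exists(p)) stop_config("run_config: path does not exist: '",
                                     p, "'")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' Top-level keys mirror [run_config()] arguments; `coexpr` and `null` are
#' nested objects with the corresponding config fields.
#'
#' @param path JSON file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: '", path, "'")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[setdiff(names(raw), c("coexpr", "null"))]
  args$coexpr <- do.call(coexpr_config, as.list(raw$coexpr %||% list()))
  args$null <- do.call(null_config, as.list(raw$null %||% list()))
  do.call(run_config, args)
}

#' Run the full co-expression analysis
#'
#' read -> QC -> normalize -> per-cluster averages -> pair co-expression ->
#' random-pair null -> comparison, writing every intermediate table under
#' `out_dir` plus a machine-readable `run_report.json` holding all seeds,
#' thresholds and stage counts needed to reproduce the run.
#'
#' @param config a [run_config()]
#' @return invisibly, the run report (a list; also serialized to JSON)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("coexpair")),
                 config = serializable_config(config), stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  mat <- stage("read", read_10x(config$matrix_dir, dialect = config$dialect,
                                modality = config$modality))
  clusters <- stage("read", read_clusters(config$clusters_file))
  pairs <- stage("read", read_pairs(config$pairs_file, genes(mat)))
  report$stages$read <- list(barcodes = nrow(mat$counts),
                             genes = ncol(mat$counts),
                             pairs = nrow(pairs),
                             pairs_dropped = nrow(attr(pairs, "report")))

  qc <- stage("qc", filter_outliers(mat, level = config$qc_level,
                                    method = config$qc_method))
  mat <- qc$matrix
  report$stages$qc <- list(n_retained = qc$summary$n_retained,
                           n_removed = qc$summary$n_removed,
                           median_detected_genes =
                             qc$summary$median_detected_genes,
                           total_expressed_genes =
                             qc$summary$total_expressed_genes)
  utils::write.table(qc$summary$per_barcode,
                     file.path(config$out_dir, "qc_per_barcode.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  norm <- stage("normalize", normalize_counts(mat, scale = config$norm_scale))
  profile <- stage("profiles", if (config$raw_average)
    average_by_cluster(mat$counts, clusters, de_log = FALSE)
    else average_by_cluster(norm, clusters))
  utils::write.table(data.frame(gene = rownames(profile$avg), profile$avg,
                                check.names = FALSE),
                     file.path(config$out_dir, "cluster_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$profiles <- list(clusters = ncol(profile$avg),
                                 n_entities = as.list(profile$n_entities))

  if (!is.null(config$markers_file)) {
    markers <- stage("annotate", read_markers(config$markers_file))
    dstats <- stage("annotate",
                    dotplot_stats(mat, norm, clusters,
                                  unique(markers$gene)))
    ann <- stage("annotate", annotate_clusters(dstats, markers))
    utils::write.table(as.data.frame(ann),
                       file.path(config$out_dir, "cluster_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$annotate <-
      stats::setNames(as.list(ann$cell_type), ann$cluster)
  }

  true_res <- stage("coexpr", coexpressed_pairs(profile, pairs,
                                                config$coexpr))
  utils::write.table(true_res$per_cluster,
                     file.path(config$out_dir, "coexpression_per_cluster.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  csum <- correlation_summary(true_res)
  report$stages$coexpr <- list(union_count = true_res$union_count,
                               union_pct = true_res$union_pct,
                               r_min = csum$r_min, r_max = csum$r_max)

  universe <- if (config$null$gene_universe == "expressed_genes")
    rownames(profile$avg)[rowSums(profile$avg) > 0] else rownames(profile$avg)
  reps <- stage("null", draw_random_pairs(universe, pairs, config$null))
  nullsum <- stage("null", null_coexpression(profile, reps, config$coexpr))
  utils::write.table(nullsum$per_cluster,
                     file.path(config$out_dir, "null_per_cluster.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comparison <- compare_to_null(true_res, nullsum)
  utils::write.table(comparison,
                     file.path(config$out_dir, "comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$null <- list(n_draws = config$null$n_draws,
                             seed = config$null$seed,
                             gene_universe_size = length(universe))
  report$comparison <- comparison

  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(report)
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$coexpr <- unclass(cfg$coexpr)
  cfg$null <- unclass(cfg$null)
  cfg
}

#' One-command synthetic demo
#'
#' Simulates a clustered dataset with planted pair co-expression, writes it
#' as an on-disk fixture, then runs the full pipeline on it.
#'
#' @param seed master seed for both the simulation and the null draws
#' @param dir working directory for fixture + outputs (default: a tempdir)
#' @param sim a [sim_config()] (its seed is overridden by `seed`)
#' @param n_draws null replicates for the demo
#' @return the run report (invisibly), as from [run_pipeline()]
#' @export
run_demo <- function(seed = 1L, dir = tempfile("coexpair_demo"),
                     sim = sim_config(), n_draws = 10L) {
  sim$seed <- as.integer(seed)
  out <- simulate_counts(sim)
  fixture_dir <- file.path(dir, "fixture")
  write_fixture(out$matrix, out$truth, fixture_dir)
  cfg <- run_config(matrix_dir = fixture_dir,
                    clusters_file = file.path(fixture_dir, "clusters.tsv"),
                    pairs_file = file.path(fixture_dir, "pairs.tsv"),
                    markers_file = if (file.size(file.path(fixture_dir,
                                                           "markers.tsv")) > 0)
                      file.path(fixture_dir, "markers.tsv") else NULL,
                    out_dir = file.path(dir, "out"),
                    modality = sim$modality,
                    null = null_config(n_draws = n_draws,
                                       seed = as.integer(seed)))
  run_pipeline(cfg)
}
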