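# Orchestration: chained stages over real or synthetic repertoires, with a
# key=value config, per-stage seeds, TSV/JSON artifacts and a run manifest.

#' Default pipeline configuration
#'
#' @param input path to a repertoire TSV (NULL when simulating in-process).
#' @param outdir output directory.
#' @param tree_mode `"nj"`, `"true"` or `"import"`.
#' @param junction_identity_min clonal clustering identity threshold.
#' @param clonal_min_root_div clonal-burst divergence threshold (1%).
#' @param early_threshold early-migration depth threshold (1%).
#' @param near_zero_edge near-zero divergence bin edge for the pairwise curve.
#' @param short_branch burst-filter short-branch threshold.
#' @param min_migration_root_div migrant-classification depth threshold.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param n_shuffle_reps,n_boot replicate counts for the null models.
#' @param stages character vector of stages to run (dependency order is
#'   enforced).
#' @param recluster re-run lineage clustering even if `lineage_id` present.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, outdir = tempfile("gcmigrate_run_"),
                       tree_mode = "nj", junction_identity_min = 0.85,
                       clonal_min_root_div = 0.01, early_threshold = 0.01,
                       near_zero_edge = 0.005, short_branch = 0.002,
                       min_migration_root_div = 0, seed = 1L,
                       n_shuffle_reps = 100L, n_boot = 100L,
                       stages = c("cluster", "spatial", "clock", "trees",
                                  "homogeneity", "fate"),
                       recluster = FALSE) {
  thresholds <- c(junction_identity_min, clonal_min_root_div, early_threshold,
                  near_zero_edge, short_branch, min_migration_root_div)
  if (any(thresholds < 0 | thresholds > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(input = input, outdir = outdir, tree_mode = tree_mode,
                 junction_identity_min = junction_identity_min,
                 clonal_min_root_div = clonal_min_root_div,
                 early_threshold = early_threshold,
                 near_zero_edge = near_zero_edge, short_branch = short_branch,
                 min_migration_root_div = min_migration_root_div,
                 seed = as.integer(seed), n_shuffle_reps = as.integer(n_shuffle_reps),
                 n_boot = as.integer(n_boot), stages = stages,
                 recluster = isTRUE(recluster)),
            class = "run_config")
}

stage_seed <- function(config, stage) {
  # deterministic per-stage seeds, kept below 2^31
  (config$seed * 97L + match(stage, c("cluster", "spatial", "clock", "trees",
                                      "homogeneity", "fate"))) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order (cluster, spatial, clock, trees,
#' homogeneity, fate), writing per-stage TSV/JSON artifacts plus
#' `summary.json` and a `manifest.json` recording seeds and record counts.
#' Identical config and seed give byte-identical summaries. A stage failure
#' halts with the stage name; artifacts of completed stages are retained.
#'
#' @param config a [run_config()].
#' @param records optional in-memory repertoire data frame (overrides
#'   `config$input`).
#' @param truth optional `sim_truth` (required for `tree_mode = "true"`).
#' @param import_trees named list of trees for `tree_mode = "import"`.
#' @return (invisibly) a list of stage results; side effect: files under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config, records = NULL, truth = NULL,
                         import_trees = NULL) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  log <- function(...) message("[gcmigrate] ", ...)
  fail <- function(stage, e) stop("stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)
  if (is.null(records)) {
    if (is.null(config$input)) stop("run_pipeline needs records or config$input")
    records <- read_repertoire_table(config$input)
  }
  records <- compute_root_divergence(records)
  jwrite <- function(x, name) jsonlite::write_json(
    x, file.path(config$outdir, name), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")

  if ("cluster" %in% config$stages) {
    tryCatch({
      if (config$recluster || anyNA(records$lineage_id))
        records <- cluster_lineages(records, config$junction_identity_min)
      res$lineages <- lineage_summary(records)
      write.table(res$lineages, file.path(config$outdir, "lineages.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }, error = function(e) fail("cluster", e))
    log("cluster: ", nrow(res$lineages), " lineages")
  }
  if (anyNA(records$lineage_id)) stop("records lack lineage_id; run the cluster stage")

  if ("spatial" %in% config$stages) {
    tryCatch({
      hist <- follicle_count_histogram(records)
      p_geom <- fit_truncated_geometric(hist)
      shuf <- well_mixed_shuffle(records, n_reps = config$n_shuffle_reps,
                                 seed = stage_seed(config, "spatial"))
      dd <- related_pair_distances(records, seed = stage_seed(config, "spatial"))
      res$spatial <- list(histogram = hist, p_geom = p_geom, shuffle = shuf,
                          distances = dd)
      write.table(data.frame(k = hist$k, count = hist$counts, error = hist$errors),
                  file.path(config$outdir, "follicle_counts.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }, error = function(e) fail("spatial", e))
    log("spatial: p_geom = ", round(res$spatial$p_geom, 3),
        ", tail fraction = ", round(res$spatial$distances$tail_fraction, 3))
  }

  if ("clock" %in% config$stages) {
    tryCatch({
      intra <- is_intrafollicular(records)
      alpha <- fit_exponential_divergence(records$root_divergence[intra])
      curve <- pairwise_migration_curve(records,
                                        near_zero_edge = config$near_zero_edge,
                                        seed = stage_seed(config, "clock"))
      bursts <- clonal_burst_analysis(records,
                                      min_root_div = config$clonal_min_root_div)
      asc <- asc_age_trend(records)
      res$clock <- list(alpha = alpha, curve = curve, bursts = bursts,
                        asc_trend = asc)
      if (!is.null(curve$curve))
        write.table(curve$curve, file.path(config$outdir, "migration_curve.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }, error = function(e) fail("clock", e))
    log("clock: alpha = ", round(res$clock$alpha, 4),
        ", beta = ", round(res$clock$curve$beta, 4))
  }

  trees <- NULL
  if ("trees" %in% config$stages) {
    tryCatch({
      if (config$tree_mode == "true" && is.null(truth))
        stop("tree_mode 'true' requires simulation truth")
      bt <- build_lineage_trees(records, mode = config$tree_mode,
                                truth = truth, import_trees = import_trees)
      trees <- analyze_trees(bt$trees, early_threshold = config$early_threshold)
      rates <- estimate_rates(trees)
      events <- do.call(rbind, lapply(trees, function(t) t$events))
      res$trees <- list(trees = trees, skipped = bt$skipped, rates = rates,
                        size_strata = stratify_rates(trees, "size"),
                        depth_strata = stratify_rates(trees, "depth"))
      write.table(events, file.path(config$outdir, "migration_events.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }, error = function(e) fail("trees", e))
    log("trees: ", length(trees), " trees, m = ",
        round(res$trees$rates$m_global, 2))
  }

  if ("homogeneity" %in% config$stages) {
    if (is.null(trees)) stop("stage 'homogeneity' requires stage 'trees' (phylo_migration)")
    tryCatch({
      hom <- poisson_resample(trees, n_boot = config$n_boot,
                              seed = stage_seed(config, "homogeneity"))
      filt <- burst_filter(trees, records,
                           min_root_div = config$clonal_min_root_div,
                           short_branch = config$short_branch)
      hom_filt <- poisson_resample(filt$trees, n_boot = config$n_boot,
                                   seed = stage_seed(config, "homogeneity"))
      pred <- predict_follicle_counts(records, trees, hom$m_refit,
                                      n_boot = config$n_boot,
                                      seed = stage_seed(config, "homogeneity"))
      res$homogeneity <- list(resample = hom, filtered_resample = hom_filt,
                              excluded = filt$excluded, predicted = pred)
      write.table(data.frame(k = pred$k, predicted = pred$mean_counts,
                             sem = pred$sem, observed = pred$observed_counts),
                  file.path(config$outdir, "predicted_follicle_counts.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }, error = function(e) fail("homogeneity", e))
    log("homogeneity: refit m = ", round(res$homogeneity$resample$m_refit, 2),
        " (filtered ", round(res$homogeneity$filtered_resample$m_refit, 2), ")")
  }

  if ("fate" %in% config$stages) {
    if (is.null(trees)) stop("stage 'fate' requires stage 'trees' (phylo_migration)")
    tryCatch({
      fs <- post_migration_divergence(trees, n_reps = config$n_shuffle_reps,
                                      seed = stage_seed(config, "fate"))
      comp <- migrant_composition(records, trees,
                                  min_migration_root_div = config$min_migration_root_div)
      res$fate <- list(shuffle = fs, composition = comp)
      write.table(comp, file.path(config$outdir, "follicle_composition.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }, error = function(e) fail("fate", e))
    log("fate: migrant-led follicles = ",
        sum(!is.na(res$fate$composition$top_migrant_freq) &
            res$fate$composition$top_migrant_freq >=
            res$fate$composition$top_lineage_freq))
  }

  summary <- list(
    n_records = nrow(records),
    n_intrafollicular = sum(is_intrafollicular(records)),
    n_lineages = length(unique(records$lineage_id)),
    p_geom = res$spatial$p_geom,
    tail_fraction = res$spatial$distances$tail_fraction,
    alpha = res$clock$alpha,
    beta = res$clock$curve$beta,
    intercept_excess = res$clock$curve$intercept_excess,
    p_burst = res$clock$bursts$p_burst,
    aggregate_burst_multifollicular = res$clock$bursts$aggregate_multifollicular,
    n_trees = if (!is.null(trees)) length(trees) else NULL,
    m_global = res$trees$rates$m_global,
    m_refit = res$homogeneity$resample$m_refit,
    m_refit_filtered = res$homogeneity$filtered_resample$m_refit,
    observed_zero_fraction = res$fate$shuffle$observed_zero_fraction,
    shuffled_zero_fraction = res$fate$shuffle$shuffled_zero_fraction)
  jwrite(summary[!vapply(summary, is.null, TRUE)], "summary.json")
  manifest <- list(seed = config$seed,
                   stages = config$stages,
                   config_hash = sum(utf8ToInt(paste(
                     vapply(config[!(names(config) %in% "outdir")],
                            function(v) paste(format(v), collapse = ","), "")
                     , collapse = ";"))),
                   n_records = nrow(records))
  jwrite(manifest, "manifest.json")
  invisible(res)
}

#' Simulate a synthetic tonsil and write its artifacts
#'
#' Wraps [simulate_tonsil()]: writes the repertoire TSV, the follicle map, the
#' parameters as a flat key=value file and (optionally) the ground truth
#' (genealogies as newick, migration events as TSV).
#'
#' @param params a [sim_params()].
#' @param outdir output directory.
#' @param seed RNG seed (logged in the params file).
#' @param write_truth write truth files (default TRUE).
#' @return (invisibly) the simulation list.
#' @export
simulate_command <- function(params, outdir, seed = 1L, write_truth = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_tonsil(params, seed = seed)
  write_repertoire_table(sim$records, file.path(outdir, "repertoire.tsv"))
  write.table(data.frame(follicle_id = sim$fmap$follicle_ids,
                         x = sim$fmap$centroids[, 1L],
                         y = sim$fmap$centroids[, 2L]),
              file.path(outdir, "follicle_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("seed=%d", seed),
               vapply(names(unclass(params)), function(n)
                 sprintf("%s=%s", n, paste(format(params[[n]]), collapse = ",")), "")),
             file.path(outdir, "params.txt"))
  if (write_truth) {
    phys <- Filter(Negate(is.null), lapply(sim$truth$lineages, `[[`, "phy"))
    if (length(phys) > 0L)
      ape::write.tree(do.call(c, lapply(phys, list)) |> (\(x) { class(x) <- "multiPhylo"; x })(),
                      file.path(outdir, "genealogies.nwk"))
    write.table(sim$truth$events, file.path(outdir, "true_migrations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(sim)
}
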