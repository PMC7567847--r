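#' Read a pipeline run configuration
#'
#' Plain-text `key = value` file; `#` lines are comments. Recognised keys
#' (defaults in parentheses): `input`, `specs`, `id_col`, `group_col`,
#' `scale` (photo), `occupancy_threshold` (1/3), `chi_p_threshold` (0.25),
#' `iterations` (50000), `restarts` (50), `ess` (1), `max_parents` (3),
#' `B` (100), `frac` (0.95), `alpha` (1), `threshold` (auto),
#' `infer_source`, `infer_from`, `infer_to`, `seed` (mandatory), `outdir`,
#' and for the simulate stage `n_taxa` (8), `n_edges` (8), `lambda` (0.8),
#' `n_photos` (2000), `photos_per_event` (25).
#'
#' @param path config file path.
#' @param overrides named list applied on top of the file (used for CLI
#'   flags such as a seed override).
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path))
    abort_ecobnet(sprintf("config file not found: %s", path), "ecobnet_usage_error")
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      abort_ecobnet(sprintf("config line %d: expected 'key = value'", i),
                    "ecobnet_parse_error")
    key <- trimws(parts[1L])
    val <- trimws(paste(parts[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg[names(overrides)] <- overrides
  validate_run_config(cfg)
}

#' Validate a pipeline configuration list
#' @param cfg named list of config values.
#' @return The completed config, with defaults filled in.
#' @export
validate_run_config <- function(cfg) {
  defaults <- list(scale = "photo", occupancy_threshold = 1 / 3,
                   chi_p_threshold = 0.25, iterations = 50000, restarts = 50,
                   ess = 1, max_parents = 3, B = 100, frac = 0.95, alpha = 1,
                   n_taxa = 8, n_edges = 8, lambda = 0.8, n_photos = 2000,
                   photos_per_event = 25, outdir = "ecobnet_run")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$seed))
    abort_ecobnet("config must set a seed", "ecobnet_usage_error")
  cfg$seed <- as.integer(cfg$seed)
  for (k in c("occupancy_threshold", "chi_p_threshold", "frac")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      abort_ecobnet(sprintf("config key '%s' must lie in (0, 1), got %s",
                            k, format(v)), "ecobnet_usage_error")
  }
  if (!cfg$scale %in% c("photo", "event"))
    abort_ecobnet("scale must be 'photo' or 'event'", "ecobnet_usage_error")
  structure(cfg, class = "run_config")
}

log_line <- function(cfg, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 sprintf(...))
  cat(msg, "\n", sep = "", file = file.path(cfg$outdir, "run.log"),
      append = TRUE)
}

artifact <- function(cfg, name) file.path(cfg$outdir, name)

#' Pipeline stage: simulate a synthetic survey
#'
#' Writes `input.csv` and `specs.txt` (plus `ground_truth.json`) into the
#' output directory from the config's generator settings, using seed
#' `seed + 1` for the ground truth and `seed + 2` for the community sample.
#'
#' @param cfg a `run_config`.
#' @return The config, with `input`/`specs` pointed at the written files.
#' @export
pipeline_simulate <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  gt <- simulate_ground_truth(n_taxa = cfg$n_taxa, n_edges = cfg$n_edges,
                              lambda = cfg$lambda, seed = cfg$seed + 1L)
  tab <- sample_community(gt, n_photos = cfg$n_photos,
                          photos_per_event = cfg$photos_per_event,
                          seed = cfg$seed + 2L)
  write_samples(tab, artifact(cfg, "input.csv"))
  write_variable_specs(tab$specs, artifact(cfg, "specs.txt"))
  write_ground_truth(gt, artifact(cfg, "ground_truth.json"))
  cfg$input <- artifact(cfg, "input.csv")
  cfg$specs <- artifact(cfg, "specs.txt")
  cfg$id_col <- "sample_id"; cfg$group_col <- "event_id"
  log_line(cfg, "simulate: %d photos, %d taxa, %d edges, lambda=%.2f, seed=%d",
           cfg$n_photos, cfg$n_taxa, cfg$n_edges, cfg$lambda, cfg$seed)
  cfg
}

#' Pipeline stage: load, group, rare-filter and discretize
#'
#' Reads the input CSV, aggregates photos to events when
#' `scale = "event"`, applies the rare-taxon occupancy filter at the
#' analysis scale, and discretizes the surviving variables. Writes
#' `discretized.csv`, `boundaries.json` and `rare_exclusions.json`.
#'
#' @param cfg a `run_config`.
#' @return The discretized table, invisibly.
#' @export
pipeline_discretize <- function(cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  specs <- read_variable_specs(cfg$specs)
  tab <- read_samples(cfg$input, specs, id_col = cfg$id_col,
                      group_col = cfg$group_col)
  if (identical(cfg$scale, "event")) tab <- aggregate_events(tab)
  rare <- exclude_rare(tab, threshold = cfg$occupancy_threshold)
  tab <- subset_table_vars(tab, rare$kept)
  dtable <- discretize_table(tab)
  write_discretized(dtable, artifact(cfg, "discretized.csv"),
                    artifact(cfg, "boundaries.json"))
  write_exclusions(rare$exclusions, artifact(cfg, "rare_exclusions.json"))
  log_line(cfg, "discretize: %d samples x %d vars at %s scale; %d rare var(s) excluded (occupancy < %.4f)",
           length(dtable$sample_ids), length(dtable$vars), cfg$scale,
           nrow(rare$exclusions$excluded_variables), cfg$occupancy_threshold)
  invisible(dtable)
}

subset_table_vars <- function(table, vars) {
  specs <- table$specs[table$specs$name %in% vars, , drop = FALSE]
  abundance_table(table$values[, specs$name, drop = FALSE], specs,
                  sample_ids = table$sample_ids, grouping = table$grouping,
                  scale = table$scale)
}

#' Pipeline stage: contingency pre-filter
#'
#' Reads the discretized artifacts and writes `exclusions.json`, the merge
#' of the rare-variable exclusions and the chi-squared pair exclusions.
#'
#' @param cfg a `run_config`.
#' @return The merged [exclusion_set()], invisibly.
#' @export
pipeline_prefilter <- function(cfg) {
  dtable <- read_discretized(artifact(cfg, "discretized.csv"),
                             artifact(cfg, "boundaries.json"))
  rare <- read_exclusions(artifact(cfg, "rare_exclusions.json"))
  pairs <- contingency_exclusions(dtable, p_threshold = cfg$chi_p_threshold)
  merged <- merge_exclusions(rare, pairs)
  write_exclusions(merged, artifact(cfg, "exclusions.json"))
  log_line(cfg, "prefilter: %d pair(s) excluded at chi-squared p > %.2f",
           nrow(pairs$excluded_pairs), cfg$chi_p_threshold)
  invisible(merged)
}

#' Pipeline stage: single structure search on the full data
#'
#' Writes the best-scoring DAG to `dag.tsv` using seed `seed + 10`.
#'
#' @param cfg a `run_config`.
#' @return The learned `bn_dag`, invisibly.
#' @export
pipeline_learn <- function(cfg) {
  dtable <- read_discretized(artifact(cfg, "discretized.csv"),
                             artifact(cfg, "boundaries.json"))
  excl <- read_exclusions(artifact(cfg, "exclusions.json"))
  settings <- search_settings(n_iterations = cfg$iterations,
                              n_restarts = cfg$restarts, ess = cfg$ess,
                              seed = cfg$seed + 10L,
                              max_parents = cfg$max_parents)
  dag <- greedy_search(dtable, excl, settings)
  write_dag(dag, artifact(cfg, "dag.tsv"))
  log_line(cfg, "learn: %d edges, log score %.4f (%s proposals, seed %d)",
           nrow(dag_edges(dag)), attr(dag, "score"),
           format(attr(dag, "proposals")), cfg$seed + 10L)
  invisible(dag)
}

#' Pipeline stage: bootstrap consensus network
#'
#' Runs the bootstrap (master seed `seed + 20`), derives the occurrence
#' threshold from the mixture model unless the config fixes one, and
#' writes `edge_stats.tsv`, `consensus.tsv`, `consensus.graphml`,
#' `consensus.json`.
#'
#' @param cfg a `run_config`.
#' @return The `consensus_network`, invisibly.
#' @export
pipeline_consensus <- function(cfg) {
  dtable <- read_discretized(artifact(cfg, "discretized.csv"),
                             artifact(cfg, "boundaries.json"))
  excl <- read_exclusions(artifact(cfg, "exclusions.json"))
  settings <- search_settings(n_iterations = cfg$iterations,
                              n_restarts = cfg$restarts, ess = cfg$ess,
                              max_parents = cfg$max_parents)
  ens <- run_bootstrap(dtable, excl, settings, B = cfg$B, frac = cfg$frac,
                       seed = cfg$seed + 20L)
  stats <- edge_stats(ens)
  write.table(stats, artifact(cfg, "edge_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  net <- assemble_consensus(ens, dtable, threshold = cfg$threshold,
                            alpha = cfg$alpha)
  write_network(net, artifact(cfg, "consensus.tsv"))
  write_network(net, artifact(cfg, "consensus.graphml"))
  write_network(net, artifact(cfg, "consensus.json"))
  log_line(cfg, "consensus: B=%d frac=%.2f seed=%d; threshold %.4f; %d edge(s)",
           cfg$B, cfg$frac, cfg$seed + 20L, net$threshold, nrow(net$edges))
  invisible(net)
}

#' Pipeline stage: CPTs and chain inference
#'
#' Fits CPTs on the consensus DAG orientation and, when the config names an
#' inference contrast, writes `inference.json`/`inference.tsv`.
#'
#' @param cfg a `run_config`.
#' @return The `inference_report` (or the `cpt_set` when no contrast is
#'   configured), invisibly.
#' @export
pipeline_infer <- function(cfg) {
  dtable <- read_discretized(artifact(cfg, "discretized.csv"),
                             artifact(cfg, "boundaries.json"))
  net <- read_network(artifact(cfg, "consensus.json"))
  dag <- consensus_to_dag(net)
  cpts <- fit_cpts(dtable, dag, alpha = cfg$alpha)
  write_cpts(cpts, artifact(cfg, "cpts.json"))
  if (is.null(cfg$infer_source)) {
    log_line(cfg, "infer: CPTs written; no contrast configured")
    return(invisible(cpts))
  }
  report <- state_change_report(net, cpts, cfg$infer_source,
                                cfg$infer_from, cfg$infer_to)
  write_report(report, artifact(cfg, "inference.json"),
               artifact(cfg, "inference.tsv"))
  log_line(cfg, "infer: %s %s -> %s; mean |delta p| = %.4f",
           cfg$infer_source, format(cfg$infer_from), format(cfg$infer_to),
           report$mean_delta_p)
  invisible(report)
}

#' Run the full pipeline
#'
#' Chains the stages: (optional) simulate, discretize, prefilter, learn,
#' consensus, infer. Every stage writes its artifacts into `cfg$outdir` and
#' logs its seeds and thresholds to `run.log`; re-running with an
#' identical config reproduces identical artifacts. Stage seeds are
#' derived from the master seed by fixed offsets (+1/+2 simulate, +10
#' learn, +20 bootstrap) so stages can be rerun in isolation.
#'
#' @param config a `run_config` from [read_run_config()] /
#'   [validate_run_config()], or a path to a config file.
#' @param simulate generate the input with [pipeline_simulate()] first
#'   (default: TRUE when the config names no input file).
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, simulate = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(simulate)) simulate <- is.null(cfg$input)
  if (simulate) cfg <- pipeline_simulate(cfg)
  if (is.null(cfg$input) || is.null(cfg$specs))
    abort_ecobnet("config must name input and specs (or enable simulate)",
                  "ecobnet_usage_error")
  stage <- "discretize"
  tryCatch({
    pipeline_discretize(cfg)
    stage <- "prefilter"; pipeline_prefilter(cfg)
    stage <- "learn"; pipeline_learn(cfg)
    stage <- "consensus"; pipeline_consensus(cfg)
    stage <- "infer"; pipeline_infer(cfg)
  }, error = function(e) {
    log_line(cfg, "ABORT in stage %s: %s", stage, conditionMessage(e))
    abort_ecobnet(sprintf("pipeline stage '%s' failed: %s", stage,
                          conditionMessage(e)), "ecobnet_stage_error")
  })
  files <- c("discretized.csv", "boundaries.json", "rare_exclusions.json",
             "exclusions.json", "dag.tsv", "edge_stats.tsv", "consensus.tsv",
             "consensus.graphml", "consensus.json", "cpts.json")
  out <- setNames(file.path(cfg$outdir, files), files)
  invisible(out[file.exists(out)])
}
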