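#' Pipeline commands
#'
#' Configuration-driven entry points tying the modules together. Each takes a
#' validated [read_run_config()] configuration (or a path to one), writes a
#' deterministic directory layout and a `manifest.json` recording the config,
#' its hash, the master seed and the package version - enough to re-run the
#' experiment exactly. A thin shell front end wrapping these functions ships
#' in `inst/cli/subnetbench`.
#'
#' @name pipeline_commands
NULL

#' Generate gold standards and simulated datasets on disk
#'
#' For every FG/BG split in the configured collection and every signal
#' strength on the configured grid, writes `split_XXX/` with `fg.txt`,
#' `bg.txt`, `provenance.json`, and `signal_Y/` subdirectories holding
#' `expression.tsv` (gene ID column + one column per sample), `labels.tsv`
#' and `stats.tsv`. The network is written once as `network.tsv`. Outputs
#' are byte-identical across repeated runs of the same configuration.
#'
#' @param config A `run_config` (or YAML path).
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty `out_dir`.
#' @return `out_dir`, invisibly.
#' @rdname pipeline_commands
#' @export
cmd_simulate <- function(config, out_dir, force = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  prepare_out_dir(out_dir, force)
  net <- config_network(cfg)
  write_edge_list(net, file.path(out_dir, "network.tsv"))
  splits <- config_splits(cfg, net)
  model <- cfg$simulation$model %||% "VM"
  grid <- cfg$simulation$signal_grid %||% default_signal_grid(model)
  pair_index <- 0L
  for (si in seq_along(splits)) {
    split_dir <- file.path(out_dir, sprintf("split_%03d", si))
    write_gold_standard(splits[[si]], split_dir)
    for (strength in grid) {
      pair_index <- pair_index + 1L
      config_i <- config_from_signal(
        model, strength,
        n_cases = cfg$simulation$n_cases %||% 100L,
        n_controls = cfg$simulation$n_controls %||% 10L,
        seed = derive_seed(cfg$seed, 2000L + pair_index)
      )
      dataset <- simulate_expression(net, splits[[si]], config_i)
      write_expression_dataset(dataset, file.path(split_dir, paste0("signal_", strength)))
    }
  }
  write_manifest(out_dir, cfg, extra = list(
    n_splits = length(splits),
    n_failed_splits = nrow(attr(splits, "failures")),
    signal_grid = as.numeric(grid)
  ))
  invisible(out_dir)
}

#' Sparsity metrics for an FG set stored on disk
#'
#' @param network_path Edge-list file of the network.
#' @param fg_path Text file with one FG node ID per line.
#' @param format Edge-list format (`"tsv"` or `"sif"`).
#' @param out Optional path for a JSON report.
#' @return The [sparsity_report()] tibble, invisibly if `out` is given.
#' @rdname pipeline_commands
#' @export
cmd_sparsity <- function(network_path, fg_path, format = "tsv", out = NULL) {
  net <- read_edge_list(network_path, format = format)
  fg <- readLines(fg_path)
  fg <- trimws(fg)
  fg <- fg[nzchar(fg)]
  report <- sparsity_report(net, fg)
  if (!is.null(out)) {
    jsonlite::write_json(as.list(report), out, auto_unbox = TRUE, digits = NA)
    return(invisible(report))
  }
  report
}

#' Score stored predictions against stored gold standards
#'
#' `gold_dir` contains `split_XXX/` directories as written by
#' [cmd_simulate()]; `predictions_dir` contains, for each split directory
#' name, a subdirectory with one `<method>.txt` file (one node ID per line)
#' per method. Results are written as a long-format CSV.
#'
#' @param gold_dir Directory of gold standards.
#' @param predictions_dir Directory of prediction files.
#' @param out Path for the results CSV (default
#'   `file.path(predictions_dir, "results.csv")`).
#' @return The results tibble.
#' @rdname pipeline_commands
#' @export
cmd_evaluate <- function(gold_dir, predictions_dir, out = NULL) {
  split_dirs <- sort(list.dirs(gold_dir, recursive = FALSE))
  split_dirs <- split_dirs[grepl("split_", basename(split_dirs))]
  if (length(split_dirs) == 0) abort("no split_* directories found in gold_dir.")
  rows <- list()
  for (sd in split_dirs) {
    split <- read_gold_standard(sd)
    pred_dir <- file.path(predictions_dir, basename(sd))
    if (!dir.exists(pred_dir)) next
    for (pf in sort(list.files(pred_dir, pattern = "\\.txt$", full.names = TRUE))) {
      nodes <- readLines(pf)
      nodes <- trimws(nodes)
      nodes <- nodes[nzchar(nodes)]
      pred <- prediction(nodes, method_name = sub("\\.txt$", "", basename(pf)))
      rows[[length(rows) + 1]] <- dplyr::mutate(
        evaluate_prediction(split, pred),
        split_id = basename(sd), .before = 1
      )
    }
  }
  if (length(rows) == 0) abort("no prediction files found.")
  res <- dplyr::bind_rows(rows)
  out <- out %||% file.path(predictions_dir, "results.csv")
  utils::write.csv(res, out, row.names = FALSE)
  res
}

#' Run the full configured benchmark
#'
#' Builds the network, split collection and adapters from the configuration
#' and executes the complete sweep with [run_benchmark()], writing
#' `results.csv` (one row per run), `aggregate.csv` (per method x signal
#' strength) and the manifest. Repeating the command with the same
#' configuration yields identical CSVs.
#'
#' @rdname pipeline_commands
#' @export
cmd_benchmark <- function(config, out_dir, force = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  adapters <- config_adapters(cfg)
  if (length(adapters) == 0) {
    adapters <- list(adapter_top_n(), adapter_greedy_module())
  }
  prepare_out_dir(out_dir, force)
  net <- config_network(cfg)
  splits <- config_splits(cfg, net)
  model <- cfg$simulation$model %||% "VM"
  grid <- cfg$simulation$signal_grid %||% default_signal_grid(model)
  sim_grid <- lapply(grid, function(s) {
    config_from_signal(model, s,
                       n_cases = cfg$simulation$n_cases %||% 100L,
                       n_controls = cfg$simulation$n_controls %||% 10L)
  })
  ip_grid <- list()
  for (ad in cfg$adapters %||% list()) {
    if (!is.null(ad$ip_grid)) ip_grid[[ad$name]] <- ad$ip_grid
  }
  results <- run_benchmark(net, splits, sim_grid, adapters,
                           ip_grid = ip_grid,
                           seed = derive_seed(cfg$seed, 3000L))
  utils::write.csv(tibble::as_tibble(results),
                   file.path(out_dir, "results.csv"), row.names = FALSE)
  utils::write.csv(aggregate_results(results),
                   file.path(out_dir, "aggregate.csv"), row.names = FALSE)
  write_manifest(out_dir, cfg, extra = list(
    n_runs = nrow(results),
    n_failed_runs = sum(results$status != "ok")
  ))
  invisible(results)
}
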