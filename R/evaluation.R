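#' Predicted subnetworks
#'
#' A *prediction* is the node set an enrichment method reports for one
#' dataset, together with the method name and the internal-parameter (IP)
#' values used - e.g. an expected module size, an allowed-exceptions count or
#' an FDR cutoff, depending on the method. When a method reports several
#' modules, the union of their node sets is evaluated.
#'
#' @param node_ids Character vector of predicted node IDs (may be empty).
#' @param method_name Method label.
#' @param internal_params Named list of IP values (may be empty).
#' @return An object of class `prediction`.
#' @export
prediction <- function(node_ids, method_name, internal_params = list()) {
  structure(
    list(
      node_ids = unique(as.character(node_ids)),
      method_name = as.character(method_name),
      internal_params = internal_params
    ),
    class = "prediction"
  )
}

#' Score a prediction against a gold standard
#'
#' Node-level confusion counts with the foreground as the positive class:
#' every predicted FG node is a true positive, every predicted BG node a
#' false positive, every missed FG node a false negative. Precision, recall
#' and the F-measure (F1, the harmonic mean) follow; an empty prediction
#' scores F = 0 by convention, as does a zero-denominator precision.
#' Predicted IDs absent from the split's node universe are rejected with an
#' error naming them.
#'
#' @param split A [gold_standard_split()].
#' @param pred A [prediction()] (or a bare character vector of node IDs).
#' @return A one-row tibble: `method`, `n_pred`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_measure`, plus split provenance columns
#'   (`generator`, `n_fg`, `achieved_avg_distance`).
#' @export
evaluate_prediction <- function(split, pred) {
  stopifnot(inherits(split, "gold_standard_split"))
  if (!inherits(pred, "prediction")) {
    pred <- prediction(pred, method_name = "unnamed")
  }
  universe <- c(split$fg_nodes, split$bg_nodes)
  unknown <- setdiff(pred$node_ids, universe)
  if (length(unknown) > 0) {
    abort(paste0(
      "prediction contains IDs absent from the network: ",
      paste(utils::head(unknown, 10), collapse = ", "),
      if (length(unknown) > 10) sprintf(" (and %d more)", length(unknown) - 10) else ""
    ))
  }
  tp <- length(intersect(pred$node_ids, split$fg_nodes))
  fp <- length(pred$node_ids) - tp
  fn <- length(split$fg_nodes) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(
    method = pred$method_name,
    n_pred = length(pred$node_ids),
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f_measure = f,
    generator = split$generator,
    n_fg = length(split$fg_nodes),
    achieved_avg_distance = split$achieved_avg_distance
  )
}

#' Built-in baseline adapters
#'
#' Two minimal reference methods ship with the harness so the evaluation
#' pipeline can be exercised without any external tool:
#'
#' * `adapter_top_n()` - the `n` genes with the smallest p-values, ignoring
#'   topology entirely. Under no signal its hit count against a size-`n` FG
#'   is exactly hypergeometric, which makes it the calibration baseline.
#' * `adapter_greedy_module()` - seeds at the most significant gene and
#'   repeatedly adds the adjacent gene with the smallest p-value until the
#'   module has `n` nodes; a minimal aggregate-score method whose output
#'   always induces a connected subgraph.
#'
#' Both take the target size from `internal_params$n` at run time (falling
#' back to the constructor default). Ties in p-values are broken by absolute
#' t-statistic, then by gene ID, so runs are deterministic.
#'
#' @param n Default module size.
#' @return A `method_adapter` object for [run_method_adapter()].
#' @name builtin_adapters
NULL

new_method_adapter <- function(name, fun = NULL, command = NULL, defaults = list()) {
  structure(
    list(name = name, fun = fun, command = command, defaults = defaults),
    class = "method_adapter"
  )
}

#' @rdname builtin_adapters
#' @export
adapter_top_n <- function(n = 20L) {
  new_method_adapter(
    "top_n_differential",
    fun = function(net, dataset, stats, params) {
      size <- params$n %||% n
      ord <- order(stats$p, -abs(stats$t), stats$gene)
      stats$gene[ord][seq_len(min(size, nrow(stats)))]
    },
    defaults = list(n = n)
  )
}

#' @rdname builtin_adapters
#' @export
adapter_greedy_module <- function(n = 20L) {
  new_method_adapter(
    "greedy_module",
    fun = function(net, dataset, stats, params) {
      size <- params$n %||% n
      ids <- igraph::V(net)$name
      p <- stats$p[match(ids, stats$gene)]
      tval <- abs(stats$t[match(ids, stats$gene)])
      ord_key <- order(p, -tval, ids)
      module <- ids[ord_key[1]]
      while (length(module) < size) {
        nbr_idx <- unique(unlist(igraph::adjacent_vertices(net, module)))
        frontier <- setdiff(ids[nbr_idx], module)
        if (length(frontier) == 0) break
        fi <- match(frontier, ids)
        pick <- frontier[order(p[fi], -tval[fi], frontier)][1]
        module <- c(module, pick)
      }
      module
    },
    defaults = list(n = n)
  )
}

#' Wrap an external tool as a method adapter
#'
#' External subnetwork-extraction tools plug into the harness through a
#' subprocess contract: the command template is executed with the
#' placeholders `{network}` (edge-list TSV), `{expression}` (matrix TSV),
#' `{stats}` (per-gene statistics TSV), `{params}` (IP values as JSON) and
#' `{out}` substituted by file paths; the tool must write one node ID per
#' line to `{out}` or, if `{out}` is not used in the template, to stdout.
#' Stdout/stderr and wall time are captured; a non-zero exit or unreadable
#' output raises an adapter error carrying the captured log.
#'
#' @param name Method label.
#' @param command Command template string (see above).
#' @param defaults Default internal parameters.
#' @return A `method_adapter`.
#' @export
external_adapter <- function(name, command, defaults = list()) {
  new_method_adapter(name, command = command, defaults = defaults)
}

#' @export
print.method_adapter <- function(x, ...) {
  cat(sprintf("<method_adapter> %s (%s)\n", x$name,
              if (is.null(x$command)) "builtin" else "external command"))
  invisible(x)
}

#' Run a method adapter on one dataset
#'
#' Executes a built-in or external adapter against a network and a simulated
#' (or real) dataset and returns a validated [prediction()]. Differential
#' statistics are computed on demand if not supplied. For external adapters
#' the input files are materialised in a temporary directory and the
#' subprocess log and wall time are attached to the prediction as attributes
#' `log` and `wall_time`.
#'
#' @param adapter A `method_adapter`.
#' @param net An interaction network.
#' @param dataset An [simulate_expression()] result.
#' @param internal_params Named list of IP values for this run.
#' @param stats Optional precomputed [differential_stats()] tibble.
#' @return A [prediction()].
#' @export
run_method_adapter <- function(adapter, net, dataset, internal_params = list(),
                               stats = NULL) {
  stopifnot(inherits(adapter, "method_adapter"))
  net <- as_interaction_network(net)
  stats <- stats %||% differential_stats(dataset)
  params <- utils::modifyList(adapter$defaults, internal_params)
  t0 <- proc.time()[["elapsed"]]

  if (!is.null(adapter$fun)) {
    nodes <- adapter$fun(net, dataset, stats, params)
    log <- character(0)
  } else {
    work <- tempfile("adapter_")
    dir.create(work)
    on.exit(unlink(work, recursive = TRUE), add = TRUE)
    paths <- list(
      network = file.path(work, "network.tsv"),
      expression = file.path(work, "expression.tsv"),
      stats = file.path(work, "stats.tsv"),
      params = file.path(work, "params.json"),
      out = file.path(work, "out.txt")
    )
    write_edge_list(net, paths$network)
    write_expression_dataset(dataset, work, stats = stats)
    file.rename(file.path(work, "expression.tsv"), paths$expression)
    jsonlite::write_json(params, paths$params, auto_unbox = TRUE, digits = NA)
    cmd <- adapter$command
    uses_out <- grepl("{out}", cmd, fixed = TRUE)
    for (key in names(paths)) {
      cmd <- gsub(paste0("{", key, "}"), paths[[key]], cmd, fixed = TRUE)
    }
    log <- suppressWarnings(system(cmd, intern = TRUE))
    status <- attr(log, "status") %||% 0L
    if (status != 0) {
      abort(
        sprintf("adapter '%s' exited with status %d.", adapter$name, status),
        class = "subnetbench_adapter_error", log = as.character(log)
      )
    }
    nodes <- if (uses_out) {
      if (!file.exists(paths$out)) {
        abort(sprintf("adapter '%s' wrote no output file.", adapter$name),
              class = "subnetbench_adapter_error", log = as.character(log))
      }
      readLines(paths$out)
    } else {
      as.character(log)
    }
    nodes <- trimws(nodes)
    nodes <- nodes[nzchar(nodes)]
  }
  wall <- proc.time()[["elapsed"]] - t0

  unknown <- setdiff(nodes, igraph::V(net)$name)
  if (length(unknown) > 0) {
    abort(
      paste0("adapter '", adapter$name, "' returned unknown node IDs: ",
             paste(utils::head(unknown, 10), collapse = ", ")),
      class = "subnetbench_adapter_error", log = as.character(log)
    )
  }
  out <- prediction(nodes, adapter$name, params)
  attr(out, "log") <- as.character(log)
  attr(out, "wall_time") <- wall
  out
}

#' Run a full benchmark sweep
#'
#' The evaluation protocol behind the framework: the Cartesian sweep of
#' gold-standard splits x simulation configurations x adapters x
#' internal-parameter settings, one scored run per combination. Each
#' (split, configuration) dataset is simulated once with a seed derived
#' deterministically from `seed`, then shared across adapters and IP values.
#' A failing run is recorded in the result table (`status = "failed"` with
#' the error message) without aborting the sweep.
#'
#' @param net An interaction network.
#' @param splits List of [gold_standard_split()] objects.
#' @param sim_grid List of [simulation_config()] objects (their `seed` fields
#'   are overridden by derived per-run seeds).
#' @param adapters List of `method_adapter` objects.
#' @param ip_grid Named list: for each adapter name, a list of
#'   internal-parameter settings (each a named list). Adapters without an
#'   entry run once with their defaults.
#' @param seed Master seed for dataset simulation.
#' @param sparsity Include the per-split sparsity metrics in the output
#'   (default TRUE; computing Steiner-tree proximity on many large splits can
#'   dominate runtime, so batch callers may disable it).
#' @return A tibble of class `benchmark_result`, one row per run, with split
#'   provenance, model and signal strength, sparsity metrics (if requested),
#'   confusion counts and scores, `status` and `error` columns.
#' @export
run_benchmark <- function(net, splits, sim_grid, adapters, ip_grid = list(),
                          seed = 1L, sparsity = TRUE) {
  net <- as_interaction_network(net)
  if (length(splits) == 0 || length(sim_grid) == 0 || length(adapters) == 0) {
    abort("splits, sim_grid and adapters must all be non-empty.")
  }
  adapter_names <- vapply(adapters, function(a) a$name, character(1))
  ip_sets <- lapply(adapter_names, function(nm) {
    sets <- ip_grid[[nm]] %||% list(list())
    if (length(sets) == 0) list(list()) else sets
  })
  names(ip_sets) <- adapter_names

  sparsity_tbl <- if (sparsity) {
    dplyr::bind_rows(lapply(seq_along(splits), function(i) {
      dplyr::mutate(sparsity_report(net, splits[[i]]), split_id = i)
    }))
  } else NULL

  rows <- list()
  pair_index <- 0L
  for (si in seq_along(splits)) {
    split <- splits[[si]]
    for (ci in seq_along(sim_grid)) {
      pair_index <- pair_index + 1L
      config <- sim_grid[[ci]]
      config$seed <- derive_seed(seed, pair_index)
      dataset <- simulate_expression(net, split, config)
      stats <- differential_stats(dataset)
      for (ai in seq_along(adapters)) {
        adapter <- adapters[[ai]]
        for (ip in ip_sets[[adapter$name]]) {
          run <- tryCatch({
            pred <- run_method_adapter(adapter, net, dataset, ip, stats = stats)
            dplyr::mutate(
              evaluate_prediction(split, pred),
              status = "ok", error = NA_character_
            )
          }, error = function(e) {
            tibble::tibble(
              method = adapter$name, n_pred = NA_integer_,
              tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
              precision = NA_real_, recall = NA_real_, f_measure = NA_real_,
              generator = split$generator, n_fg = length(split$fg_nodes),
              achieved_avg_distance = split$achieved_avg_distance,
              status = "failed", error = conditionMessage(e)
            )
          })
          run <- dplyr::mutate(
            run,
            split_id = si,
            split_seed = split$seed,
            k = split$params$k %||% NA_real_,
            model = config$model,
            signal_strength = signal_strength(config),
            sim_seed = config$seed,
            ip = as.character(jsonlite::toJSON(ip, auto_unbox = TRUE, digits = NA)),
            .before = 1
          )
          rows[[length(rows) + 1]] <- run
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(sparsity_tbl)) {
    out <- dplyr::left_join(out, dplyr::select(sparsity_tbl, -"n_fg"), by = "split_id")
  }
  class(out) <- c("benchmark_result", class(out))
  out
}

#' Aggregate benchmark results
#'
#' Summarises a long result table per group: mean, median, standard
#' deviation, quartiles and count of the F-measure, plus mean precision and
#' recall. Failed runs are excluded (their count is reported in `n_failed`).
#'
#' @param rows A [run_benchmark()] result (or compatible tibble).
#' @param group_by Character vector of grouping columns, e.g.
#'   `c("method", "signal_strength")`.
#' @return A tibble with one row per group.
#' @export
aggregate_results <- function(rows, group_by = c("method", "signal_strength")) {
  if (nrow(rows) == 0) abort("`rows` is empty.")
  if (!"status" %in% names(rows)) rows$status <- "ok"
  unknown <- setdiff(group_by, names(rows))
  if (length(unknown) > 0) {
    abort(paste0("unknown grouping field(s): ", paste(unknown, collapse = ", ")))
  }
  rows |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n = sum(.data$status == "ok"),
      n_failed = sum(.data$status != "ok"),
      mean_f = mean(.data$f_measure[.data$status == "ok"]),
      median_f = stats::median(.data$f_measure[.data$status == "ok"]),
      sd_f = stats::sd(.data$f_measure[.data$status == "ok"]),
      q25_f = stats::quantile(.data$f_measure[.data$status == "ok"], 0.25, names = FALSE),
      q75_f = stats::quantile(.data$f_measure[.data$status == "ok"], 0.75, names = FALSE),
      mean_precision = mean(.data$precision[.data$status == "ok"]),
      mean_recall = mean(.data$recall[.data$status == "ok"]),
      .groups = "drop"
    )
}
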