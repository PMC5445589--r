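# YAML run configuration: schema validation and materialisation.

config_schema <- list(
  top = c("version", "seed", "network", "fg_selection", "simulation", "adapters"),
  network = c("path", "format", "synthetic"),
  synthetic = c("model", "n_nodes", "params"),
  fg_selection = c("generator", "n", "k", "alpha", "count", "max_restarts"),
  simulation = c("model", "signal_grid", "n_cases", "n_controls"),
  adapter = c("name", "builtin", "command", "ip_grid", "defaults")
)

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("unknown key(s) in %s: %s", where,
                  paste(unknown, collapse = ", ")))
  }
}

#' Read and validate a run configuration
#'
#' A YAML file drives the pipeline commands ([cmd_simulate()],
#' [cmd_benchmark()]). The schema is strict: unknown keys anywhere are
#' errors, so typos fail before any work starts. Top-level keys:
#'
#' * `seed` (required) - master seed; every source of randomness derives
#'   from it.
#' * `network` (required) - either `path` + `format` (`tsv`/`sif`) or a
#'   `synthetic` block (`model`, `n_nodes`, `params`).
#' * `fg_selection` (required) - `generator` (`SAE`/`AVDk`), `n` (default
#'   20), `count` (default 1); for AVDk also `k` (default 3), `alpha`
#'   (default 1), `max_restarts` (default 50).
#' * `simulation` (required) - `model` (`VM`/`VV`), `signal_grid` (defaults
#'   to [default_signal_grid()]), `n_cases` (default 100), `n_controls`
#'   (default 10).
#' * `adapters` (optional; benchmark only) - list of blocks with `name`,
#'   either `builtin` (`top_n_differential`/`greedy_module`) or `command`
#'   (template, see [external_adapter()]), optional `defaults` and
#'   `ip_grid` (list of named IP settings).
#'
#' @param path Path to the YAML file, or a pre-parsed list.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) abort("configuration must be a YAML mapping.")
  check_keys(cfg, config_schema$top, "configuration")
  for (key in c("seed", "network", "fg_selection", "simulation")) {
    if (is.null(cfg[[key]])) abort(sprintf("missing required key: %s", key))
  }
  if (!is_scalar_number(cfg$seed)) abort("`seed` must be a single integer.")

  check_keys(cfg$network, config_schema$network, "network")
  if (is.null(cfg$network$path) && is.null(cfg$network$synthetic)) {
    abort("network needs either `path` or a `synthetic` block.")
  }
  if (!is.null(cfg$network$synthetic)) {
    check_keys(cfg$network$synthetic, config_schema$synthetic, "network.synthetic")
  }

  check_keys(cfg$fg_selection, config_schema$fg_selection, "fg_selection")
  gen <- cfg$fg_selection$generator %||% "AVDk"
  if (!gen %in% c("SAE", "AVDk")) {
    abort("fg_selection.generator must be 'SAE' or 'AVDk'.")
  }

  check_keys(cfg$simulation, config_schema$simulation, "simulation")
  model <- cfg$simulation$model %||% "VM"
  if (!model %in% c("VM", "VV")) abort("simulation.model must be 'VM' or 'VV'.")

  for (ad in cfg$adapters %||% list()) {
    check_keys(ad, config_schema$adapter, "adapters entry")
    if (is.null(ad$name)) abort("every adapter needs a `name`.")
    if (is.null(ad$builtin) && is.null(ad$command)) {
      abort(sprintf("adapter '%s' needs `builtin` or `command`.", ad$name))
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

# Build the network a config describes.
config_network <- function(cfg) {
  if (!is.null(cfg$network$path)) {
    read_edge_list(cfg$network$path, format = cfg$network$format %||% "tsv")
  } else {
    syn <- cfg$network$synthetic
    generate_synthetic_network(
      model = syn$model %||% "preferential_attachment",
      n_nodes = syn$n_nodes %||% 500L,
      model_params = syn$params %||% list(),
      seed = derive_seed(cfg$seed, 0)
    )
  }
}

# Build the split collection a config describes.
config_splits <- function(cfg, net) {
  fs <- cfg$fg_selection
  generate_fg_collection(
    net,
    count = fs$count %||% 1L,
    generator = fs$generator %||% "AVDk",
    params = list(
      n = fs$n %||% 20L, k = fs$k %||% 3, alpha = fs$alpha %||% 1,
      max_restarts = fs$max_restarts %||% 50L
    ),
    seed = derive_seed(cfg$seed, 1000L)
  )
}

# Instantiate the adapters a config describes.
config_adapters <- function(cfg) {
  lapply(cfg$adapters %||% list(), function(ad) {
    if (!is.null(ad$builtin)) {
      a <- switch(ad$builtin,
        top_n_differential = adapter_top_n(),
        greedy_module = adapter_greedy_module(),
        abort(sprintf("unknown builtin adapter: %s", ad$builtin))
      )
      a$name <- ad$name
      a$defaults <- utils::modifyList(a$defaults, ad$defaults %||% list())
      a
    } else {
      external_adapter(ad$name, ad$command, defaults = ad$defaults %||% list())
    }
  })
}

config_hash <- function(cfg) {
  rlang::hash(unclass(cfg))
}

prepare_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir, all.files = TRUE, no.. = TRUE)) > 0 && !force) {
    abort(sprintf("output directory '%s' is non-empty; use force = TRUE to overwrite.", out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  invisible(out_dir)
}

write_manifest <- function(out_dir, cfg, extra = list()) {
  manifest <- c(
    list(
      config = unclass(cfg),
      config_hash = config_hash(cfg),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("subnetbench")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    extra
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)
  invisible(manifest)
}
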