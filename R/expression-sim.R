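#' Configure an expression simulation
#'
#' Two Gaussian models separate foreground (FG) from background (BG) genes in
#' a case/control design. Each matrix entry is drawn independently from a
#' normal distribution chosen by its (gene class, sample class) cell:
#'
#' * **VM (varying mean)** - FG genes in cases follow `N(mu_fg, v)`, FG genes
#'   in controls `N(mu_fgc, v)`, BG genes `N(0, v)` everywhere; `v = 1` by
#'   default. Signal strength is the mean difference `mu_fg - mu_fgc`.
#' * **VV (varying variance)** - FG genes in cases follow `N(mu, v_fg)`; FG
#'   genes in controls and all BG genes follow `N(mu, v_bg)`; `mu = 0` by
#'   default. Signal strength is the variance ratio `v_fg / v_bg`.
#'
#' The default design has 100 case (patient) samples and 10 controls.
#'
#' @param model `"VM"` or `"VV"`.
#' @param n_cases,n_controls Samples per class (defaults 100 and 10).
#' @param seed Integer seed for the simulation.
#' @param mu_fg,mu_fgc,v VM parameters: FG case mean, FG control mean, common
#'   variance (default 1).
#' @param mu,v_fg,v_bg VV parameters: common mean (default 0), FG case
#'   variance, BG variance.
#' @return An object of class `simulation_config`.
#' @seealso [simulate_expression()], [signal_strength()]
#' @export
simulation_config <- function(model = c("VM", "VV"),
                              n_cases = 100L, n_controls = 10L, seed = 1L,
                              mu_fg = NULL, mu_fgc = NULL, v = 1,
                              mu = 0, v_fg = NULL, v_bg = NULL) {
  model <- match.arg(model)
  if (!is_count(n_cases) || !is_count(n_controls)) {
    abort("`n_cases` and `n_controls` must be positive integers.")
  }
  if (model == "VM") {
    if (!is_scalar_number(mu_fg) || !is_scalar_number(mu_fgc)) {
      abort("VM model requires numeric `mu_fg` and `mu_fgc`.")
    }
    if (!is_scalar_number(v) || v <= 0) abort("`v` must be strictly positive.")
    pars <- list(mu_fg = mu_fg, mu_fgc = mu_fgc, v = v)
  } else {
    if (!is_scalar_number(v_fg) || !is_scalar_number(v_bg) || v_fg <= 0 || v_bg <= 0) {
      abort("VV model requires strictly positive `v_fg` and `v_bg`.")
    }
    if (!is_scalar_number(mu)) abort("`mu` must be numeric.")
    pars <- list(mu = mu, v_fg = v_fg, v_bg = v_bg)
  }
  structure(
    c(list(model = model, n_cases = as.integer(n_cases),
           n_controls = as.integer(n_controls), seed = as.integer(seed)),
      pars),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  pars <- x[setdiff(names(x), c("model", "n_cases", "n_controls", "seed"))]
  cat(sprintf(
    "<simulation_config> %s | %d cases + %d controls | %s | signal strength %.3g | seed %d\n",
    x$model, x$n_cases, x$n_controls,
    paste(names(pars), unlist(pars), sep = "=", collapse = ", "),
    signal_strength(x), x$seed
  ))
  invisible(x)
}

#' Signal strength of a simulation configuration
#'
#' VM: the mean difference `mu_fg - mu_fgc`. VV: the variance ratio
#' `v_fg / v_bg`. Higher values separate FG from BG expression more strongly,
#' making the hidden module easier to recover.
#'
#' @param config A [simulation_config()].
#' @return A number.
#' @export
signal_strength <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$model == "VM") config$mu_fg - config$mu_fgc else config$v_fg / config$v_bg
}

#' Simulate a case/control expression dataset
#'
#' Draws one expression value per (gene, sample) cell from the normal
#' distribution the configuration assigns to that cell (see
#' [simulation_config()]). Rows are all network nodes in vertex order;
#' columns are `n_cases` case samples followed by `n_controls` controls.
#' Entries are independent: no gene-gene correlation structure is modelled.
#' The same `(net, split, config)` including seed reproduces the matrix
#' bitwise.
#'
#' @param net An interaction network.
#' @param split A [gold_standard_split()] belonging to `net`.
#' @param config A [simulation_config()].
#' @return An object of class `expression_dataset`: a list with `values`
#'   (genes x samples numeric matrix), `sample_labels` (`"case"`/`"control"`),
#'   `gene_ids`, and the generating `config`/`split` provenance.
#' @export
simulate_expression <- function(net, split, config) {
  net <- as_interaction_network(net)
  stopifnot(inherits(split, "gold_standard_split"),
            inherits(config, "simulation_config"))
  check_split_network(split, net)

  gene_ids <- igraph::V(net)$name
  n_genes <- length(gene_ids)
  n_samples <- config$n_cases + config$n_controls
  labels <- c(rep("case", config$n_cases), rep("control", config$n_controls))
  is_fg <- gene_ids %in% split$fg_nodes
  is_case <- labels == "case"

  mu_mat <- matrix(0, n_genes, n_samples)
  sd_mat <- matrix(0, n_genes, n_samples)
  if (config$model == "VM") {
    sd_mat[] <- sqrt(config$v)
    mu_mat[is_fg, is_case] <- config$mu_fg
    mu_mat[is_fg, !is_case] <- config$mu_fgc
  } else {
    mu_mat[] <- config$mu
    sd_mat[] <- sqrt(config$v_bg)
    sd_mat[is_fg, is_case] <- sqrt(config$v_fg)
  }

  z <- with_seed(config$seed, matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples))
  values <- mu_mat + sd_mat * z
  rownames(values) <- gene_ids
  colnames(values) <- sprintf("s%03d", seq_len(n_samples))

  structure(
    list(
      values = values,
      sample_labels = labels,
      gene_ids = gene_ids,
      config = config,
      split = split
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %d genes x %d samples (%d case, %d control) | model %s\n",
    nrow(x$values), ncol(x$values),
    sum(x$sample_labels == "case"), sum(x$sample_labels == "control"),
    x$config$model
  ))
  invisible(x)
}

#' Per-gene differential-expression statistics
#'
#' Welch's (unequal-variance) two-sample t-test of case vs. control columns,
#' one test per gene. The Welch form is the appropriate default here because
#' the varying-variance simulation model breaks variance homogeneity by
#' design. Genes that are constant within both classes get `p = 1` when the
#' class means are equal (no evidence of change) and `p = 0` with an infinite
#' t-statistic when they differ. Raw p-values are accompanied by
#' Benjamini-Hochberg adjusted ones and by per-class means, plus a z-score of
#' the t-statistic for tools that prefer scores over p-values.
#'
#' @param dataset An [simulate_expression()] result.
#' @return A tibble with one row per gene: `gene`, `t`, `p`, `p_adj`,
#'   `mean_case`, `mean_control`, `z`.
#' @export
differential_stats <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  is_case <- dataset$sample_labels == "case"
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    abort("differential statistics require at least 2 samples per class.")
  }
  cases <- dataset$values[, is_case, drop = FALSE]
  controls <- dataset$values[, !is_case, drop = FALSE]

  res <- vapply(seq_len(nrow(cases)), function(i) {
    x <- cases[i, ]
    y <- controls[i, ]
    if (stats::var(x) < .Machine$double.eps && stats::var(y) < .Machine$double.eps) {
      d <- mean(x) - mean(y)
      if (abs(d) < .Machine$double.eps) c(0, 1) else c(sign(d) * Inf, 0)
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      c(unname(tt$statistic), tt$p.value)
    }
  }, numeric(2))

  tibble::tibble(
    gene = dataset$gene_ids,
    t = res[1, ],
    p = res[2, ],
    p_adj = stats::p.adjust(res[2, ], method = "BH"),
    mean_case = rowMeans(cases),
    mean_control = rowMeans(controls),
    z = stats::qnorm(pmax(pmin(res[2, ] / 2, 1 - 1e-16), 1e-300), lower.tail = FALSE) * sign(res[1, ])
  )
}

#' Write an expression dataset and its statistics to disk
#'
#' Writes the matrix as TSV (first column `gene`, header row of sample IDs),
#' a companion sample-label TSV, and the differential statistics TSV - the
#' tool-facing input files of the benchmark.
#'
#' @param dataset An [simulate_expression()] result.
#' @param dir Output directory (created if needed).
#' @param stats Optional precomputed [differential_stats()] tibble.
#' @return `dir`, invisibly.
#' @export
write_expression_dataset <- function(dataset, dir, stats = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- data.frame(gene = rownames(dataset$values), dataset$values,
                    check.names = FALSE)
  utils::write.table(mat, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(dataset$values), class = dataset$sample_labels),
    file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  stats <- stats %||% differential_stats(dataset)
  utils::write.table(as.data.frame(stats), file.path(dir, "stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Default signal-strength grids
#'
#' The shipped parameter sweeps: VM mean differences
#' `{0, 0.25, 0.5, 1, 1.5, 2}` and VV variance ratios `{1, 2, 4, 8}`
#' (signal strength 0 and 1 respectively mean "no signal"). Both are
#' user-overridable wherever a grid is accepted.
#'
#' @param model `"VM"` or `"VV"`.
#' @return A numeric vector of signal strengths.
#' @export
default_signal_grid <- function(model = c("VM", "VV")) {
  model <- match.arg(model)
  if (model == "VM") c(0, 0.25, 0.5, 1, 1.5, 2) else c(1, 2, 4, 8)
}

#' Build a simulation config from a signal strength
#'
#' Convenience constructor used by grid sweeps: a VM config with
#' `mu_fg = strength`, `mu_fgc = 0`, `v = 1`, or a VV config with
#' `v_fg = strength * v_bg`, `v_bg = 1`, `mu = 0`.
#'
#' @param model `"VM"` or `"VV"`.
#' @param strength Desired signal strength (VM difference or VV ratio).
#' @inheritParams simulation_config
#' @return A [simulation_config()].
#' @export
config_from_signal <- function(model = c("VM", "VV"), strength,
                               n_cases = 100L, n_controls = 10L, seed = 1L) {
  model <- match.arg(model)
  if (model == "VM") {
    simulation_config("VM", n_cases, n_controls, seed,
                      mu_fg = strength, mu_fgc = 0, v = 1)
  } else {
    if (strength <= 0) abort("a VV signal strength (variance ratio) must be positive.")
    simulation_config("VV", n_cases, n_controls, seed,
                      mu = 0, v_fg = strength, v_bg = 1)
  }
}
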