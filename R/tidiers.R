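#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a gold-standard split
#'
#' @param x A [gold_standard_split()].
#' @param ... Unused.
#' @return A tibble with one row per node: `node`, `class`
#'   (`"FG"`/`"BG"`).
#' @export
tidy.gold_standard_split <- function(x, ...) {
  tibble::tibble(
    node = c(x$fg_nodes, x$bg_nodes),
    class = rep(c("FG", "BG"), c(length(x$fg_nodes), length(x$bg_nodes)))
  )
}

#' @rdname tidy.gold_standard_split
#' @return For `glance()`: a one-row tibble summarising the split.
#' @export
glance.gold_standard_split <- function(x, ...) {
  tibble::tibble(
    generator = x$generator,
    n_fg = length(x$fg_nodes),
    n_bg = length(x$bg_nodes),
    k = x$params$k %||% NA_real_,
    alpha = x$params$alpha %||% NA_real_,
    seed = x$seed,
    achieved_avg_distance = x$achieved_avg_distance
  )
}

#' Tidy an expression dataset into long form
#'
#' @param x An [simulate_expression()] result.
#' @param ... Unused.
#' @return A tibble with one row per (gene, sample) cell: `gene`,
#'   `gene_class` (`"FG"`/`"BG"`), `sample`, `sample_class`, `value`.
#' @export
tidy.expression_dataset <- function(x, ...) {
  fg <- x$split$fg_nodes
  tibble::tibble(
    gene = rep(x$gene_ids, times = ncol(x$values)),
    gene_class = rep(ifelse(x$gene_ids %in% fg, "FG", "BG"), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    sample_class = rep(x$sample_labels, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' @rdname tidy.expression_dataset
#' @return For `glance()`: a one-row design summary.
#' @export
glance.expression_dataset <- function(x, ...) {
  tibble::tibble(
    model = x$config$model,
    n_genes = nrow(x$values),
    n_cases = sum(x$sample_labels == "case"),
    n_controls = sum(x$sample_labels == "control"),
    n_fg = length(x$split$fg_nodes),
    signal_strength = signal_strength(x$config),
    seed = x$config$seed
  )
}

#' Plot expression distributions by gene and sample class
#'
#' Density of simulated expression values per (gene class, sample class)
#' cell - the visual check that the varying-mean or varying-variance signal
#' landed where the model puts it.
#'
#' @param object An [simulate_expression()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expression_dataset <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$value, colour = .data$sample_class)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~ .data$gene_class, scales = "free_y") +
    ggplot2::labs(
      x = "expression value", colour = "sample class",
      title = sprintf("%s model, signal strength %.3g",
                      object$config$model, signal_strength(object$config))
    ) +
    ggplot2::theme_minimal()
}

#' Plot benchmark performance
#'
#' Mean F-measure against signal strength (one line per method), with one
#' standard deviation as error bars - the standard summary view of a sweep.
#'
#' @param object A [run_benchmark()] result.
#' @param x Variable for the horizontal axis, `"signal_strength"` (default)
#'   or `"k"` (sparsity level).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_result <- function(object, x = c("signal_strength", "k"), ...) {
  x <- match.arg(x)
  agg <- aggregate_results(tibble::as_tibble(object), group_by = c("method", x))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data[[x]], y = .data$mean_f,
                                    colour = .data$method, group = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mean_f - .data$sd_f, 0),
                                        ymax = pmin(.data$mean_f + .data$sd_f, 1)),
                           width = 0.05) +
    ggplot2::labs(
      x = if (x == "k") "target average FG distance k (sparsity)" else "signal strength",
      y = "mean F-measure", colour = "method"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
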