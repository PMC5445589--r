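eval_fixture <- function(n_nodes = 100, fg_n = 20, seed = 1) {
  net <- generate_synthetic_network("preferential_attachment", n_nodes, seed = seed)
  split <- seed_and_extend(net, fg_n, seed = seed + 1)
  list(net = net, split = split)
}

test_that("confusion counts and F-measure follow the node-level definitions", {
  fx <- eval_fixture()
  fg <- fx$split$fg_nodes
  bg <- fx$split$bg_nodes

  perfect <- evaluate_prediction(fx$split, prediction(fg, "oracle"))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f_measure, 1)

  half <- evaluate_prediction(fx$split, prediction(c(fg[1:10], bg[1:10]), "half"))
  expect_equal(half$tp, 10)
  expect_equal(half$fp, 10)
  expect_equal(half$fn, 10)
  expect_equal(half$precision, 0.5)
  expect_equal(half$recall, 0.5)
  expect_equal(half$f_measure, 0.5)

  empty <- evaluate_prediction(fx$split, prediction(character(0), "empty"))
  expect_equal(empty$tp, 0)
  expect_equal(empty$f_measure, 0)

  expect_error(
    evaluate_prediction(fx$split, prediction(c(fg[1], "ghost1"), "bad")),
    "ghost1"
  )
})

test_that("tp + fn always equals |FG| and F is the harmonic mean", {
  fx <- eval_fixture()
  universe <- c(fx$split$fg_nodes, fx$split$bg_nodes)
  for (seed in 1:25) {
    nodes <- with_seed_helper(seed, sample(universe, sample(0:40, 1)))
    r <- evaluate_prediction(fx$split, prediction(nodes, "rand"))
    expect_equal(r$tp + r$fn, length(fx$split$fg_nodes))
    expect_equal(r$f_measure * (r$precision + r$recall),
                 2 * r$precision * r$recall, tolerance = 1e-12)
    expect_lte(r$f_measure, max(r$precision, r$recall) + 1e-12)
  }
})

test_that("builtin adapters honour the size contract and connectivity", {
  fx <- eval_fixture()
  d <- simulate_expression(fx$net, fx$split,
                           simulation_config("VM", mu_fg = 2, mu_fgc = 0, seed = 5))
  st <- differential_stats(d)

  top <- run_method_adapter(adapter_top_n(20), fx$net, d, stats = st)
  expect_length(top$node_ids, 20)
  expect_equal(top$method_name, "top_n_differential")

  mod <- run_method_adapter(adapter_greedy_module(20), fx$net, d, stats = st)
  expect_length(mod$node_ids, 20)
  expect_true(igraph::is_connected(igraph::induced_subgraph(fx$net, mod$node_ids)))

  # internal params override the constructor default
  small <- run_method_adapter(adapter_top_n(20), fx$net, d,
                              internal_params = list(n = 5), stats = st)
  expect_length(small$node_ids, 5)
})

test_that("strong signal lets both baselines recover the module", {
  fx <- eval_fixture()
  d <- simulate_expression(fx$net, fx$split,
                           simulation_config("VM", mu_fg = 3, mu_fgc = 0, seed = 6))
  st <- differential_stats(d)
  for (ad in list(adapter_top_n(20), adapter_greedy_module(20))) {
    pred <- run_method_adapter(ad, fx$net, d, stats = st)
    r <- evaluate_prediction(fx$split, pred)
    expect_gt(r$f_measure, 0.8)
  }
})

test_that("external adapters run through the subprocess contract", {
  fx <- eval_fixture(n_nodes = 40, fg_n = 8)
  d <- simulate_expression(fx$net, fx$split,
                           simulation_config("VM", mu_fg = 2, mu_fgc = 0, seed = 7))
  # a minimal external tool: take the top-5 genes from the stats file
  script <- withr::local_tempfile(fileext = ".R", lines = c(
    'args <- commandArgs(trailingOnly = TRUE)',
    'st <- read.delim(args[1])',
    'writeLines(st$gene[order(st$p)][1:5], args[2])'
  ))
  ad <- external_adapter("tiny_tool", paste("Rscript", script, "{stats}", "{out}"))
  pred <- run_method_adapter(ad, fx$net, d)
  expect_length(pred$node_ids, 5)
  expect_true(all(pred$node_ids %in% igraph::V(fx$net)$name))
  expect_true(is.numeric(attr(pred, "wall_time")))

  failing <- external_adapter("broken", "Rscript -e 'quit(status=1)'")
  expect_error(run_method_adapter(failing, fx$net, d),
               class = "subnetbench_adapter_error")

  liar <- external_adapter("liar", "Rscript -e 'cat(\"not_a_node\\n\")'")
  expect_error(run_method_adapter(liar, fx$net, d),
               class = "subnetbench_adapter_error")
})

test_that("run_benchmark sweeps the full Cartesian grid deterministically", {
  net <- generate_synthetic_network("preferential_attachment", 80, seed = 4)
  splits <- generate_fg_collection(net, 2, "SAE", params = list(n = 10), seed = 2)
  sim_grid <- list(config_from_signal("VM", 0.5, n_cases = 20, n_controls = 5),
                   config_from_signal("VM", 2, n_cases = 20, n_controls = 5))
  adapters <- list(adapter_top_n(10))
  ip_grid <- list(top_n_differential = list(list(n = 5), list(n = 10), list(n = 20)))

  res <- run_benchmark(net, splits, sim_grid, adapters, ip_grid, seed = 7)
  expect_equal(nrow(res), 2 * 2 * 1 * 3)
  expect_true(all(res$status == "ok"))
  expect_setequal(unique(res$signal_strength), c(0.5, 2))
  # sparsity metrics joined per split
  expect_true(all(is.finite(res$global_proximity)))

  res2 <- run_benchmark(net, splits, sim_grid, adapters, ip_grid, seed = 7)
  expect_identical(res$f_measure, res2$f_measure)
  expect_identical(res$tp, res2$tp)

  expect_error(run_benchmark(net, list(), sim_grid, adapters), "non-empty")
})

test_that("one failing adapter does not poison the sweep", {
  net <- generate_synthetic_network("preferential_attachment", 60, seed = 4)
  splits <- generate_fg_collection(net, 2, "SAE", params = list(n = 8), seed = 2)
  sim_grid <- list(config_from_signal("VM", 1, n_cases = 10, n_controls = 5))
  boom <- structure(
    list(name = "boom",
         fun = function(net, dataset, stats, params) stop("kaput"),
         command = NULL, defaults = list()),
    class = "method_adapter"
  )
  res <- run_benchmark(net, splits, sim_grid,
                       list(boom, adapter_top_n(8)), seed = 3)
  expect_equal(sum(res$status == "failed"), 2)
  expect_equal(sum(res$status == "ok"), 2)
  expect_true(all(grepl("kaput", res$error[res$status == "failed"])))
  expect_true(all(is.finite(res$f_measure[res$status == "ok"])))
})

test_that("aggregation reports the spread statistics per group", {
  rows <- tibble::tibble(
    method = c("m1", "m1", "m2"),
    signal_strength = c(1, 1, 1),
    precision = c(0.5, 1, 0.25),
    recall = c(0.5, 1, 0.25),
    f_measure = c(0.5, 1, 0.25),
    status = "ok"
  )
  agg <- aggregate_results(rows)
  expect_equal(nrow(agg), 2)
  m1 <- agg[agg$method == "m1", ]
  expect_equal(m1$mean_f, 0.75)
  expect_equal(m1$n, 2)
  m2 <- agg[agg$method == "m2", ]
  expect_equal(m2$mean_f, 0.25)
  expect_equal(m2$median_f, 0.25)
  expect_equal(m2$sd_f, NA_real_)

  expect_error(aggregate_results(rows, "nonexistent_field"), "unknown grouping")
  expect_error(aggregate_results(rows[0, ]), "empty")
})

test_that("autoplot renders a benchmark summary", {
  net <- generate_synthetic_network("preferential_attachment", 60, seed = 4)
  splits <- generate_fg_collection(net, 2, "SAE", params = list(n = 8), seed = 2)
  sim_grid <- list(config_from_signal("VM", 0, n_cases = 10, n_controls = 5),
                   config_from_signal("VM", 2, n_cases = 10, n_controls = 5))
  res <- run_benchmark(net, splits, sim_grid, list(adapter_top_n(8)), seed = 3)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("permuting FG labels after simulation collapses performance to chance", {
  net <- generate_synthetic_network("preferential_attachment", 150, seed = 9)
  fs <- vapply(1:30, function(seed) {
    split <- seed_and_extend(net, 15, seed = seed)
    d <- simulate_expression(net, split,
                             simulation_config("VM", mu_fg = 3, mu_fgc = 0,
                                               n_cases = 30, n_controls = 10,
                                               seed = seed))
    st <- differential_stats(d)
    shuffled_fg <- with_seed_helper(seed + 1000,
                                    sample(igraph::V(net)$name, 15))
    shuffled <- gold_standard_split(
      fg_nodes = shuffled_fg,
      bg_nodes = setdiff(igraph::V(net)$name, shuffled_fg),
      generator = "SAE", params = list(n = 15), seed = seed
    )
    pred <- run_method_adapter(adapter_top_n(15), net, d, stats = st)
    evaluate_prediction(shuffled, pred)$f_measure
  }, numeric(1))
  # chance overlap: E[tp] = 15 * 15 / 150 = 1.5, E[F] = 0.1
  expect_lt(mean(fs), 0.2)
})
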