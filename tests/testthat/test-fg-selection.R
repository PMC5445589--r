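test_that("average pairwise distance matches hand-enumerated values", {
  p5 <- make_path(5) # a-b-c-d-e
  expect_equal(average_pairwise_distance(p5, c("a", "c", "e")), 8 / 3)
  expect_equal(average_pairwise_distance(p5, c("a", "b")), 1)
  k6 <- make_complete(6)
  expect_equal(average_pairwise_distance(k6, c("k1", "k3", "k5")), 1)
  expect_error(average_pairwise_distance(p5, "a"), "at least 2")
})

test_that("average pairwise distance agrees with an independent BFS oracle", {
  for (seed in 1:8) {
    net <- random_connected_graph(20, p = 0.2, seed = seed)
    W <- igraph::V(net)$name[c(1, 4, 9, 13, 18)]
    D <- bfs_distances(net)
    sub <- D[W, W]
    expect_equal(average_pairwise_distance(net, W), mean(sub[upper.tri(sub)]))
  }
})

test_that("disconnected pairs are rejected with an error", {
  g <- named_graph(c("a", "b", "x", "y"))
  expect_error(average_pairwise_distance(g, c("a", "x")), "disconnected")
})

test_that("seed_and_extend returns a connected FG of exactly n nodes", {
  net <- generate_synthetic_network("preferential_attachment", 100, seed = 3)
  for (seed in 1:10) {
    sp <- seed_and_extend(net, n = 20, seed = seed)
    expect_length(sp$fg_nodes, 20)
    expect_true(igraph::is_connected(igraph::induced_subgraph(net, sp$fg_nodes)))
    expect_setequal(c(sp$fg_nodes, sp$bg_nodes), igraph::V(net)$name)
    expect_length(intersect(sp$fg_nodes, sp$bg_nodes), 0)
  }
})

test_that("seed_and_extend overshoot samples the final frontier", {
  star <- make_star(50)
  # any seed works: from a leaf, the second layer (all other leaves) overshoots
  sp <- seed_and_extend(star, n = 20, seed = 5)
  expect_length(sp$fg_nodes, 20)
  expect_true(igraph::is_connected(igraph::induced_subgraph(star, sp$fg_nodes)))
  expect_true("hub" %in% sp$fg_nodes)
})

test_that("seed_and_extend stalls gracefully on small components", {
  g <- named_graph(c("a", "b", "b", "c", "c", "d",
                     "p", "q", "q", "r", "r", "s"))
  expect_warning(seed_and_extend(g, n = 20, seed = 1), "stalled")
  sp <- suppressWarnings(seed_and_extend(g, n = 20, seed = 1))
  expect_length(sp$fg_nodes, 4) # one whole component
  expect_true(igraph::is_connected(igraph::induced_subgraph(g, sp$fg_nodes)))
})

test_that("seed_and_extend is deterministic under a fixed seed", {
  net <- generate_synthetic_network("preferential_attachment", 200, seed = 1)
  a <- seed_and_extend(net, 20, seed = 11)
  b <- seed_and_extend(net, 20, seed = 11)
  expect_identical(a$fg_nodes, b$fg_nodes)
})

test_that("avd_k_greedy hits the tolerance band and records the average", {
  net <- generate_synthetic_network("preferential_attachment", 300, seed = 2)
  for (seed in 1:5) {
    sp <- avd_k_greedy(net, n = 20, k = 3, alpha = 1, seed = seed)
    expect_length(sp$fg_nodes, 20)
    achieved <- average_pairwise_distance(net, sp$fg_nodes)
    expect_equal(sp$achieved_avg_distance, achieved)
    expect_gte(achieved, 2)
    expect_lte(achieved, 4)
  }
})

test_that("complete graphs pin the AVD_k feasibility boundary", {
  k10 <- make_complete(10)
  sp <- avd_k_greedy(k10, n = 5, k = 1, alpha = 0, seed = 1)
  expect_equal(sp$achieved_avg_distance, 1)
  err <- expect_error(
    avd_k_greedy(k10, n = 5, k = 3, alpha = 1, seed = 1, max_restarts = 3),
    class = "subnetbench_infeasible"
  )
  expect_equal(err$best_achieved, 1)
})

test_that("avd_k_exhaustive enumerates exactly the in-band subsets", {
  c6 <- make_cycle(6)
  sols <- avd_k_exhaustive(c6, n = 3, k = 2, alpha = 0)
  keys <- vapply(sols, function(s) paste(sort(s), collapse = ","), character(1))
  expect_true("v0,v2,v4" %in% keys)
  # independent check: recompute every C(6,3) subset's average from BFS
  D <- bfs_distances(c6)
  all_sets <- utils::combn(igraph::V(c6)$name, 3, simplify = FALSE)
  expected <- Filter(function(s) {
    sub <- D[s, s]
    isTRUE(all.equal(mean(sub[upper.tri(sub)]), 2))
  }, all_sets)
  expect_setequal(keys, vapply(expected, function(s) paste(sort(s), collapse = ","), character(1)))

  p5 <- make_path(5)
  sols2 <- avd_k_exhaustive(p5, n = 2, k = 4, alpha = 0)
  expect_length(sols2, 1)
  expect_setequal(sols2[[1]], c("a", "e"))

  # a tolerance covering the diameter admits every subset
  sols3 <- avd_k_exhaustive(p5, n = 3, k = 2, alpha = 4)
  expect_length(sols3, choose(5, 3))
})

test_that("the enumeration guard rejects oversized instances", {
  net <- generate_synthetic_network("preferential_attachment", 200, seed = 1)
  expect_error(avd_k_exhaustive(net, n = 10, k = 3), "guard")
})

test_that("greedy solutions are exhaustive solutions, and greedy finds one when any exists", {
  n_graphs <- 0
  for (seed in 1:40) {
    nv <- 8 + (seed %% 7)
    net <- random_connected_graph(nv, p = 0.3, seed = 100 + seed)
    for (k in c(1, 2)) {
      sols <- avd_k_exhaustive(net, n = 4, k = k, alpha = 0.5)
      sol_keys <- vapply(sols, function(s) paste(sort(s), collapse = ","), character(1))
      res <- tryCatch(
        avd_k_greedy(net, n = 4, k = k, alpha = 0.5, seed = seed, max_restarts = 200),
        subnetbench_infeasible = function(e) NULL
      )
      if (length(sols) == 0) {
        expect_null(res)
      } else {
        expect_false(is.null(res))
        expect_true(paste(sort(res$fg_nodes), collapse = ",") %in% sol_keys)
      }
      n_graphs <- n_graphs + 1
    }
  }
  expect_gte(n_graphs, 80)
})

test_that("generate_fg_collection is deterministic and size-correct", {
  net <- generate_synthetic_network("preferential_attachment", 200, seed = 5)
  col1 <- generate_fg_collection(net, 10, "AVDk",
                                 params = list(n = 15, k = 3, alpha = 1), seed = 99)
  col2 <- generate_fg_collection(net, 10, "AVDk",
                                 params = list(n = 15, k = 3, alpha = 1), seed = 99)
  expect_length(col1, 10)
  expect_identical(lapply(col1, `[[`, "fg_nodes"), lapply(col2, `[[`, "fg_nodes"))
  for (sp in col1) expect_length(sp$fg_nodes, 15)

  single <- generate_fg_collection(net, 1, "AVDk",
                                   params = list(n = 15, k = 3, alpha = 1), seed = 99)
  direct <- avd_k_greedy(net, n = 15, k = 3, alpha = 1,
                         seed = derive_seed_for_test(99, 1),
                         dist_matrix = igraph::distances(net))
  expect_identical(single[[1]]$fg_nodes, direct$fg_nodes)
})

test_that("infeasible collections abort past the failure threshold", {
  k10 <- make_complete(10)
  expect_error(
    generate_fg_collection(k10, 4, "AVDk",
                           params = list(n = 5, k = 4, alpha = 0.5, max_restarts = 2),
                           seed = 1),
    "failed"
  )
})

test_that("SAE induces connected subgraphs; AVDk need not", {
  net <- generate_synthetic_network("preferential_attachment", 300, seed = 8)
  sae <- generate_fg_collection(net, 5, "SAE", params = list(n = 20), seed = 3)
  for (sp in sae) {
    expect_true(igraph::is_connected(igraph::induced_subgraph(net, sp$fg_nodes)))
  }
  avdk <- generate_fg_collection(net, 10, "AVDk",
                                 params = list(n = 20, k = 4, alpha = 1), seed = 3)
  connectedness <- vapply(avdk, function(sp) {
    igraph::is_connected(igraph::induced_subgraph(net, sp$fg_nodes))
  }, logical(1))
  expect_true(any(!connectedness))
})

test_that("gold standards round-trip through the on-disk format", {
  net <- generate_synthetic_network("preferential_attachment", 100, seed = 2)
  sp <- avd_k_greedy(net, n = 10, k = 3, alpha = 1, seed = 4)
  dir <- withr::local_tempdir()
  write_gold_standard(sp, dir)
  expect_true(all(file.exists(file.path(dir, c("fg.txt", "bg.txt", "provenance.json")))))
  back <- read_gold_standard(dir)
  expect_identical(back$fg_nodes, sp$fg_nodes)
  expect_identical(back$bg_nodes, sp$bg_nodes)
  expect_equal(back$achieved_avg_distance, sp$achieved_avg_distance)
  expect_equal(back$generator, "AVDk")
  expect_equal(back$params$k, 3)
})

test_that("tidy and glance summarise splits", {
  net <- generate_synthetic_network("preferential_attachment", 50, seed = 2)
  sp <- seed_and_extend(net, 10, seed = 1)
  td <- generics::tidy(sp)
  expect_equal(nrow(td), 50)
  expect_equal(sum(td$class == "FG"), 10)
  gl <- generics::glance(sp)
  expect_equal(gl$n_fg, 10)
  expect_equal(gl$generator, "SAE")
})
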