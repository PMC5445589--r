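#' Gold-standard foreground/background splits
#'
#' A *gold-standard split* partitions the nodes of an interaction network into
#' a foreground (FG) set - the nodes a pathway-enrichment method should
#' recover - and a background (BG) set containing everything else. Splits are
#' produced by [seed_and_extend()] (connected FG sets) or [avd_k_greedy()]
#' (FG sets with a target average pairwise distance, i.e. controllable
#' sparsity).
#'
#' @param fg_nodes,bg_nodes Character vectors of node IDs; disjoint, jointly
#'   covering the network's node set.
#' @param generator `"SAE"` or `"AVDk"`.
#' @param params Named list of generation parameters (`n`; for AVDk also `k`
#'   and `alpha`).
#' @param seed Integer seed used for the generation.
#' @param achieved_avg_distance Average pairwise shortest-path distance of the
#'   FG set (AVDk only; `NA` otherwise).
#' @param network_name Label of the source network.
#' @return An object of class `gold_standard_split`.
#' @export
gold_standard_split <- function(fg_nodes, bg_nodes, generator, params, seed,
                                achieved_avg_distance = NA_real_,
                                network_name = NA_character_) {
  fg_nodes <- as.character(fg_nodes)
  bg_nodes <- as.character(bg_nodes)
  if (length(fg_nodes) == 0) abort("foreground set must be non-empty.")
  if (length(intersect(fg_nodes, bg_nodes)) > 0) {
    abort("foreground and background sets must be disjoint.")
  }
  structure(
    list(
      fg_nodes = fg_nodes,
      bg_nodes = bg_nodes,
      generator = match.arg(generator, c("SAE", "AVDk")),
      params = params,
      seed = as.integer(seed),
      achieved_avg_distance = as.double(achieved_avg_distance),
      network_name = network_name
    ),
    class = "gold_standard_split"
  )
}

#' @export
print.gold_standard_split <- function(x, ...) {
  cat(sprintf(
    "<gold_standard_split> %s | FG %d nodes, BG %d nodes%s\n",
    x$generator, length(x$fg_nodes), length(x$bg_nodes),
    if (!is.na(x$achieved_avg_distance)) {
      sprintf(" | avg pairwise distance %.3f", x$achieved_avg_distance)
    } else ""
  ))
  invisible(x)
}

# Check that a split's node universe matches a network's; used by downstream
# modules before simulation or scoring.
check_split_network <- function(split, net) {
  universe <- c(split$fg_nodes, split$bg_nodes)
  if (!setequal(universe, igraph::V(net)$name)) {
    abort("split does not belong to this network: node sets differ.")
  }
  invisible(TRUE)
}

#' Select a connected foreground set by seed-and-extend
#'
#' Picks a seed node uniformly at random, then grows the foreground
#' breadth-first: each iteration adds the entire next neighbourhood layer. If
#' adding a full layer would overshoot the target size `n`, exactly enough
#' nodes are sampled uniformly at random from that frontier to reach `n`, so
#' the result is always connected. If growth stalls because the seed's
#' component has fewer than `n` nodes, the whole component is returned with a
#' warning and the short size is recorded.
#'
#' @param net An interaction network.
#' @param n Target foreground size (default 20).
#' @param seed Integer seed.
#' @return A [gold_standard_split()] with `generator = "SAE"`.
#' @export
seed_and_extend <- function(net, n = 20L, seed = 1L) {
  net <- as_interaction_network(net)
  if (!is_count(n)) abort("`n` must be a positive integer.")
  n <- as.integer(n)
  ids <- igraph::V(net)$name
  if (length(ids) == 0) abort("network is empty.")

  fg <- with_seed(seed, {
    s <- sample_vec(ids, 1)
    current <- s
    repeat {
      if (length(current) >= n) break
      nbr_idx <- unique(unlist(igraph::adjacent_vertices(net, current)))
      frontier <- setdiff(ids[nbr_idx], current)
      if (length(frontier) == 0) break # stalled: component exhausted
      if (length(current) + length(frontier) <= n) {
        current <- c(current, frontier)
      } else {
        current <- c(current, sample_vec(frontier, n - length(current)))
      }
    }
    current
  })
  if (length(fg) < n) {
    warn(sprintf(
      "seed_and_extend: growth stalled at %d nodes (target %d); the seed's component is exhausted.",
      length(fg), n
    ))
  }
  gold_standard_split(
    fg_nodes = fg,
    bg_nodes = setdiff(ids, fg),
    generator = "SAE",
    params = list(n = n),
    seed = seed,
    network_name = igraph::graph_attr(net, "name") %||% NA_character_
  )
}

#' Average pairwise shortest-path distance of a node set
#'
#' Mean unweighted shortest-path (hop) distance over all unordered pairs of
#' `W`. This is the sparsity functional that average-distance-k selection
#' targets.
#'
#' @param net An interaction network.
#' @param W Character vector of node IDs, `length(W) >= 2`.
#' @return A non-negative number.
#' @examples
#' p5 <- generate_synthetic_network("ring_lattice", 5, seed = 1) # C5
#' average_pairwise_distance(p5, c("g1", "g3"))
#' @export
average_pairwise_distance <- function(net, W) {
  net <- as_interaction_network(net)
  W <- unique(as.character(W))
  if (length(W) < 2) abort("`W` must contain at least 2 nodes.")
  missing <- setdiff(W, igraph::V(net)$name)
  if (length(missing) > 0) {
    abort(paste0("nodes not in network: ", paste(missing, collapse = ", ")))
  }
  D <- igraph::distances(net, v = W, to = W)
  vals <- D[upper.tri(D)]
  if (any(!is.finite(vals))) {
    abort("`W` contains a disconnected pair (infinite distance).")
  }
  mean(vals)
}

# Average of the upper triangle of a precomputed distance submatrix.
avg_dist_from_matrix <- function(D, idx) {
  sub <- D[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Select a foreground set with target average pairwise distance (greedy)
#'
#' Solves the average-distance-k (AVD_k) selection problem heuristically:
#' find `n` nodes whose average pairwise shortest-path distance lies in
#' `[k - alpha, k + alpha]`. Exact solution is NP-complete; this greedy
#' heuristic runs in polynomial time. Starting from a random node, it
#' repeatedly adds the candidate `c` minimising
#' `|k * choose(|W| + 1, 2) - (current pair-distance sum + sum of d(c, w))|`,
#' i.e. the deviation of the running pair-distance sum from its target,
#' breaking ties uniformly at random. If the completed set misses the
#' tolerance band it restarts from a new random node, up to `max_restarts`
#' times, then signals an infeasibility error reporting the best (closest to
#' `k`) average achieved.
#'
#' Candidates are restricted to the start node's connected component so all
#' distances are finite. Unlike [seed_and_extend()], the returned set need not
#' induce a connected subgraph - deregulated genes need not be direct
#' neighbours in the interaction network.
#'
#' @param net An interaction network.
#' @param n Foreground size (>= 2; default 20).
#' @param k Target average pairwise distance, in hops.
#' @param alpha Tolerance around `k` (default 1).
#' @param seed Integer seed (start node and tie-breaks).
#' @param max_restarts Restart budget (default 50).
#' @param dist_matrix Optional precomputed `igraph::distances(net)` matrix
#'   (row/column names = node IDs); supplied by batch drivers to avoid
#'   recomputation.
#' @return A [gold_standard_split()] with `generator = "AVDk"` and the
#'   achieved average distance recorded.
#' @seealso [avd_k_exhaustive()] for the exact small-instance solver.
#' @export
avd_k_greedy <- function(net, n = 20L, k = 3, alpha = 1, seed = 1L,
                         max_restarts = 50L, dist_matrix = NULL) {
  net <- as_interaction_network(net)
  if (!is_count(n) || n < 2) abort("`n` must be an integer >= 2.")
  if (!is_scalar_number(k) || k <= 0) abort("`k` must be a positive number.")
  if (!is_scalar_number(alpha) || alpha < 0) abort("`alpha` must be non-negative.")
  n <- as.integer(n)
  ids <- igraph::V(net)$name
  D <- dist_matrix %||% igraph::distances(net)

  lo <- k - alpha
  hi <- k + alpha
  n_pairs <- choose(n, 2)

  result <- with_seed(seed, {
    best_avg <- NA_real_
    best_set <- NULL
    found <- NULL
    for (restart in seq_len(max_restarts)) {
      start <- sample.int(length(ids), 1)
      comp <- which(is.finite(D[start, ]))
      if (length(comp) < n) next
      W <- start
      cur_sum <- 0
      while (length(W) < n) {
        cand <- setdiff(comp, W)
        d_cand <- if (length(W) == 1) {
          D[W, cand]
        } else {
          colSums(D[W, cand, drop = FALSE])
        }
        target_sum <- k * choose(length(W) + 1, 2)
        score <- abs(target_sum - (cur_sum + d_cand))
        winners <- cand[score == min(score)]
        pick <- sample_vec(winners, 1)
        cur_sum <- cur_sum + if (length(W) == 1) D[W, pick] else sum(D[W, pick])
        W <- c(W, pick)
      }
      avg <- cur_sum / n_pairs
      if (is.null(best_set) || abs(avg - k) < abs(best_avg - k)) {
        best_avg <- avg
        best_set <- W
      }
      if (avg >= lo && avg <= hi) {
        found <- list(ok = TRUE, W = W, avg = avg)
        break
      }
    }
    found %||% list(ok = FALSE, W = best_set, avg = best_avg)
  })

  if (!result$ok) {
    abort(
      sprintf(
        "AVD_k infeasible after %d restart(s): best achieved average distance %.4f, target %.4g +/- %.4g.",
        max_restarts, result$avg, k, alpha
      ),
      class = "subnetbench_infeasible",
      best_achieved = result$avg
    )
  }
  fg <- ids[result$W]
  gold_standard_split(
    fg_nodes = fg,
    bg_nodes = setdiff(ids, fg),
    generator = "AVDk",
    params = list(n = n, k = k, alpha = alpha),
    seed = seed,
    achieved_avg_distance = result$avg,
    network_name = igraph::graph_attr(net, "name") %||% NA_character_
  )
}

#' Enumerate all exact solutions of the average-distance-k problem
#'
#' Brute-force oracle for small instances: enumerates every size-`n` node
#' subset and keeps those whose average pairwise shortest-path distance lies
#' in `[k - alpha, k + alpha]`. Guarded to at most 10^6 subsets; beyond that
#' an error advises [avd_k_greedy()]. Subsets containing a disconnected pair
#' have infinite average distance and are never solutions.
#'
#' @inheritParams avd_k_greedy
#' @return A list of character vectors (the solution sets), possibly empty.
#' @export
avd_k_exhaustive <- function(net, n, k, alpha = 1) {
  net <- as_interaction_network(net)
  if (!is_count(n) || n < 2) abort("`n` must be an integer >= 2.")
  ids <- igraph::V(net)$name
  n_subsets <- choose(length(ids), n)
  if (n_subsets > 1e6) {
    abort(sprintf(
      "choose(%d, %d) = %.3g subsets exceeds the enumeration guard (1e6); use avd_k_greedy().",
      length(ids), n, n_subsets
    ))
  }
  D <- igraph::distances(net)
  lo <- k - alpha
  hi <- k + alpha
  sets <- utils::combn(length(ids), n, simplify = FALSE)
  keep <- vapply(sets, function(idx) {
    avg <- avg_dist_from_matrix(D, idx)
    is.finite(avg) && avg >= lo && avg <= hi
  }, logical(1))
  lapply(sets[keep], function(idx) ids[idx])
}

#' Generate a collection of gold-standard splits
#'
#' Produces `count` splits with per-split seeds derived deterministically from
#' the master seed (`seed + index`), so the same call always yields the same
#' collection. Individual AVD_k infeasibilities are tolerated and recorded;
#' if more than half the slots fail, the whole call aborts. Duplicate FG sets
#' are permitted but counted and reported.
#'
#' @param net An interaction network.
#' @param count Number of splits to generate.
#' @param generator `"SAE"` or `"AVDk"`.
#' @param params Named list: `n` (FG size); for AVDk also `k`, `alpha`
#'   (default 1) and `max_restarts` (default 50).
#' @param seed Master seed.
#' @return A list of [gold_standard_split()] objects, with attributes
#'   `failures` (tibble of failed slots) and `n_duplicate_fg`.
#' @export
generate_fg_collection <- function(net, count, generator = c("SAE", "AVDk"),
                                   params = list(n = 20L), seed = 1L) {
  generator <- match.arg(generator)
  net <- as_interaction_network(net)
  if (!is_count(count)) abort("`count` must be a positive integer.")
  count <- as.integer(count)
  D <- if (generator == "AVDk") igraph::distances(net) else NULL

  one <- function(i) {
    s <- derive_seed(seed, i)
    if (generator == "SAE") {
      seed_and_extend(net, n = params$n %||% 20L, seed = s)
    } else {
      avd_k_greedy(
        net,
        n = params$n %||% 20L,
        k = params$k %||% 3,
        alpha = params$alpha %||% 1,
        seed = s,
        max_restarts = params$max_restarts %||% 50L,
        dist_matrix = D
      )
    }
  }

  splits <- vector("list", count)
  failures <- list()
  for (i in seq_len(count)) {
    res <- tryCatch(one(i), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- tibble::tibble(
        index = i, message = conditionMessage(res)
      )
    } else {
      splits[[i]] <- res
    }
  }
  ok <- !vapply(splits, is.null, logical(1))
  if (sum(!ok) > count / 2) {
    abort(sprintf(
      "generate_fg_collection: %d of %d generations failed; check feasibility of the parameters.",
      sum(!ok), count
    ))
  }
  splits <- splits[ok]
  keys <- vapply(splits, function(s) paste(sort(s$fg_nodes), collapse = "|"), character(1))
  n_dup <- sum(duplicated(keys))
  if (n_dup > 0) {
    inform(sprintf("generate_fg_collection: %d duplicate FG set(s) among %d splits.", n_dup, length(splits)))
  }
  attr(splits, "failures") <- if (length(failures)) dplyr::bind_rows(failures) else tibble::tibble(index = integer(), message = character())
  attr(splits, "n_duplicate_fg") <- n_dup
  splits
}

#' Write a gold-standard split to disk
#'
#' Emits `fg.txt` and `bg.txt` (one node ID per line) plus a JSON provenance
#' sidecar `provenance.json` recording generator, parameters, seed and the
#' achieved average distance.
#'
#' @param split A [gold_standard_split()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gold_standard <- function(split, dir) {
  stopifnot(inherits(split, "gold_standard_split"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(split$fg_nodes, file.path(dir, "fg.txt"))
  writeLines(split$bg_nodes, file.path(dir, "bg.txt"))
  prov <- list(
    generator = split$generator,
    params = split$params,
    seed = split$seed,
    achieved_avg_distance = split$achieved_avg_distance,
    network_name = split$network_name
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Read a gold-standard split from disk
#'
#' Counterpart of [write_gold_standard()].
#'
#' @param dir Directory containing `fg.txt`, `bg.txt` and optionally
#'   `provenance.json`.
#' @return A [gold_standard_split()].
#' @export
read_gold_standard <- function(dir) {
  fg <- readLines(file.path(dir, "fg.txt"))
  bg <- readLines(file.path(dir, "bg.txt"))
  prov_path <- file.path(dir, "provenance.json")
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path) else list()
  gold_standard_split(
    fg_nodes = fg, bg_nodes = bg,
    generator = prov$generator %||% "SAE",
    params = prov$params %||% list(n = length(fg)),
    seed = prov$seed %||% NA_integer_,
    achieved_avg_distance = prov$achieved_avg_distance %||% NA_real_,
    network_name = prov$network_name %||% NA_character_
  )
}
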