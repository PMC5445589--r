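# Small named graphs built in code, plus independent oracles used to
# cross-check the package's graph algorithms.

derive_seed_for_test <- function(seed, i) subnetbench:::derive_seed(seed, i)

# seeded evaluation without touching global RNG state
with_seed_helper <- function(seed, code) subnetbench:::with_seed(seed, code)

named_graph <- function(edges, nodes = NULL) {
  g <- igraph::make_graph(edges, directed = FALSE)
  if (!is.null(nodes)) g <- g + igraph::vertices(setdiff(nodes, igraph::V(g)$name))
  as_interaction_network(g)
}

make_path <- function(n) {
  ids <- letters[seq_len(n)]
  named_graph(as.vector(rbind(ids[-n], ids[-1])))
}

make_cycle <- function(n) {
  ids <- paste0("v", seq_len(n) - 1)
  named_graph(as.vector(rbind(ids, c(ids[-1], ids[1]))))
}

make_complete <- function(n) {
  ids <- paste0("k", seq_len(n))
  pairs <- utils::combn(ids, 2)
  named_graph(as.vector(pairs))
}

make_star <- function(n_leaves) {
  leaves <- sprintf("leaf%02d", seq_len(n_leaves))
  named_graph(as.vector(rbind("hub", leaves)))
}

# connected G(n, p) with named vertices; deterministic under seed
random_connected_graph <- function(n, p = 0.3, seed = 1) {
  generate_synthetic_network("erdos_renyi", n, model_params = list(p = p), seed = seed)
}

# Independent all-pairs BFS distances (no igraph shortest-path code).
bfs_distances <- function(net) {
  ids <- igraph::V(net)$name
  adj <- lapply(seq_along(ids), function(i) {
    as.integer(igraph::neighbors(net, i))
  })
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      for (v in adj[[u]]) {
        if (!is.finite(dist[v])) {
          dist[v] <- dist[u] + 1
          queue <- c(queue, v)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

# Exact minimum Steiner tree size (edge count) by enumeration over node
# supersets of fg; feasible only for small graphs.
exact_steiner_size <- function(net, fg) {
  ids <- igraph::V(net)$name
  fg <- unique(fg)
  if (length(fg) <= 1) return(0)
  others <- setdiff(ids, fg)
  for (extra in 0:length(others)) {
    candidates <- if (extra == 0) list(character(0)) else
      utils::combn(others, extra, simplify = FALSE)
    sizes <- integer(0)
    for (add in candidates) {
      sub <- igraph::induced_subgraph(net, c(fg, add))
      if (igraph::is_connected(sub)) {
        sizes <- c(sizes, igraph::vcount(sub) - 1)
      }
    }
    if (length(sizes) > 0) return(min(sizes))
  }
  stop("fg not connectable")
}
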