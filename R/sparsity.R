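#' Global foreground proximity
#'
#' Size, in edges, of a (near-)minimal tree covering the foreground set in
#' the network - the "shortest path covering the FG nodes". Formalised as the
#' minimum Steiner tree, which is NP-hard, so the classical metric-closure
#' 2-approximation is used: build the complete graph on the FG nodes weighted
#' by pairwise shortest-path distances, take its minimum spanning tree,
#' expand every MST edge into a shortest path in the network, and count the
#' edges of a spanning tree of the union. The result is at most twice the
#' optimum. For `|FG| <= 3` the exact optimum is computed directly (the
#' pairwise distance for two nodes; the best median-vertex spider,
#' `min_v sum_i d(v, t_i)`, for three). Lower values mean the FG set sits
#' more compactly in the network.
#'
#' @param net An interaction network.
#' @param fg Character vector of FG node IDs (pairwise connected in `net`).
#' @return A non-negative number of edges; 0 for a single node.
#' @export
global_fg_proximity <- function(net, fg) {
  net <- as_interaction_network(net)
  fg <- unique(as.character(fg))
  missing <- setdiff(fg, igraph::V(net)$name)
  if (length(missing) > 0) {
    abort(paste0("FG nodes not in network: ", paste(missing, collapse = ", ")))
  }
  if (length(fg) <= 1) return(0)
  D <- igraph::distances(net, v = fg, to = fg)
  if (any(!is.finite(D[upper.tri(D)]))) {
    abort("FG contains a disconnected pair; proximity is undefined.")
  }
  if (length(fg) == 2) return(D[1, 2])
  if (length(fg) == 3) {
    # optimal 3-terminal Steiner tree: a spider through the best median vertex
    to_fg <- igraph::distances(net, to = fg)
    return(min(rowSums(to_fg)))
  }
  # metric closure on FG, weighted by hop distances
  closure <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                                 weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(closure, weights = igraph::E(closure)$weight)
  mst_edges <- igraph::as_edgelist(mst, names = TRUE)
  # expand each closure edge into an actual shortest path; the union of these
  # paths is connected and covers FG, so its spanning tree has |nodes| - 1 edges
  covered <- fg
  for (i in seq_len(nrow(mst_edges))) {
    p <- igraph::shortest_paths(net, from = mst_edges[i, 1],
                                to = mst_edges[i, 2], output = "vpath")
    covered <- union(covered, names(p$vpath[[1]]))
  }
  length(covered) - 1
}

#' Global foreground connectivity
#'
#' Arithmetic mean of the FG nodes' degrees *in the full network* (not the
#' FG-induced subgraph). High-degree FG nodes are easier for enrichment
#' methods to reach.
#'
#' @inheritParams global_fg_proximity
#' @return Mean degree, a non-negative number.
#' @export
global_fg_connectivity <- function(net, fg) {
  net <- as_interaction_network(net)
  fg <- unique(as.character(fg))
  if (length(fg) == 0) abort("`fg` must be non-empty.")
  missing <- setdiff(fg, igraph::V(net)$name)
  if (length(missing) > 0) {
    abort(paste0("FG nodes not in network: ", paste(missing, collapse = ", ")))
  }
  mean(igraph::degree(net, v = fg))
}

#' Local foreground density
#'
#' Edge density of the FG-induced subgraph: induced edges divided by
#' `choose(|FG|, 2)`. 1 for a clique, 0 when no two FG nodes are adjacent.
#' Undefined (an error) for fewer than two FG nodes, so degenerate
#' configurations surface early.
#'
#' @inheritParams global_fg_proximity
#' @return A number in `[0, 1]`.
#' @export
local_fg_density <- function(net, fg) {
  net <- as_interaction_network(net)
  fg <- unique(as.character(fg))
  if (length(fg) < 2) abort("local density requires at least 2 FG nodes.")
  missing <- setdiff(fg, igraph::V(net)$name)
  if (length(missing) > 0) {
    abort(paste0("FG nodes not in network: ", paste(missing, collapse = ", ")))
  }
  sub <- igraph::induced_subgraph(net, fg)
  igraph::ecount(sub) / choose(length(fg), 2)
}

#' Sparsity report for a gold-standard split
#'
#' The three measures of how an FG set is distributed over the network -
#' global proximity (approximate Steiner-tree size), global connectivity
#' (mean full-network degree) and local density (induced edge density) -
#' plus the average pairwise shortest-path distance.
#'
#' @param net An interaction network.
#' @param split A [gold_standard_split()] (or a character vector of FG IDs).
#' @return A one-row tibble: `n_fg`, `global_proximity`,
#'   `global_connectivity`, `local_density`, `avg_pairwise_distance`.
#' @export
sparsity_report <- function(net, split) {
  fg <- if (inherits(split, "gold_standard_split")) split$fg_nodes else as.character(split)
  tibble::tibble(
    n_fg = length(fg),
    global_proximity = global_fg_proximity(net, fg),
    global_connectivity = global_fg_connectivity(net, fg),
    local_density = if (length(fg) >= 2) local_fg_density(net, fg) else NA_real_,
    avg_pairwise_distance = if (length(fg) >= 2) average_pairwise_distance(net, fg) else NA_real_
  )
}
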