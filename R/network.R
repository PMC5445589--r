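#' Interaction networks
#'
#' All algorithms in subnetbench operate on an *interaction network*: an
#' undirected simple [igraph][igraph::igraph-package] graph with unique,
#' non-empty character vertex names. Protein-protein interaction exports
#' (HPRD- or I2D-style edge lists, SIF files) are read with
#' [read_edge_list()]; self-contained synthetic substrates come from
#' [generate_synthetic_network()].
#'
#' `as_interaction_network()` validates (and, where unambiguous, coerces) an
#' igraph object: direction is dropped, multi-edges and self-loops are
#' removed, and vertex names are checked.
#'
#' @param graph An igraph object.
#' @param name Free-text label stored as the graph's `name` attribute.
#' @return A validated undirected simple igraph object with named vertices.
#' @export
as_interaction_network <- function(graph, name = NULL) {
  if (!igraph::is_igraph(graph)) {
    abort("`graph` must be an igraph object.")
  }
  if (igraph::is_directed(graph)) {
    graph <- igraph::as_undirected(graph, mode = "collapse")
  }
  graph <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE)
  ids <- igraph::V(graph)$name
  if (is.null(ids)) {
    abort("interaction network vertices must be named (character node IDs).")
  }
  ids <- as.character(ids)
  if (anyNA(ids) || any(!nzchar(ids))) {
    abort("node identifiers must be non-empty strings.")
  }
  if (anyDuplicated(ids)) {
    abort("node identifiers must be unique.")
  }
  if (!is.null(name)) {
    graph <- igraph::set_graph_attr(graph, "name", as.character(name))
  }
  graph
}

#' Read an interaction network from an edge-list file
#'
#' Supports two plain-text formats used by common PPI exports:
#' * `tsv` - two columns (tab- or whitespace-delimited), one interaction per
#'   line; extra columns (confidence scores etc.) are ignored.
#' * `sif` - `node1 interaction-type node2`; the middle column is ignored.
#'
#' Lines starting with `#` are comments. Edge direction is ignored: duplicate
#' lines, reversed duplicates and self-loops are dropped and the number of
#' dropped records is reported with a message. Node IDs are taken verbatim
#' (case-sensitive); no identifier mapping is performed.
#'
#' @param path Path to the edge-list file.
#' @param format `"tsv"` (default) or `"sif"`.
#' @param name Optional label for the network; defaults to the file name.
#' @return An interaction network (undirected simple igraph).
#' @seealso [write_edge_list()] for the canonical output format.
#' @export
read_edge_list <- function(path, format = c("tsv", "sif"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("edge-list file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    abort(paste0("edge-list file is empty (no data lines): ", path))
  }
  min_cols <- if (format == "sif") 3L else 2L
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields < min_cols)) {
    bad <- idx[which(n_fields < min_cols)[1]]
    abort(sprintf(
      "malformed %s line %d: expected at least %d columns, found %d.",
      toupper(format), bad, min_cols, n_fields[which(n_fields < min_cols)[1]]
    ))
  }
  from <- vapply(fields, `[[`, character(1), 1L)
  to <- vapply(fields, `[[`, character(1), if (format == "sif") 3L else 2L)

  n_raw <- length(from)
  graph <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  graph <- as_interaction_network(graph, name = name %||% basename(path))
  n_dropped <- n_raw - igraph::ecount(graph)
  if (n_dropped > 0) {
    inform(sprintf(
      "read_edge_list: dropped %d duplicate/self-loop record(s) out of %d.",
      n_dropped, n_raw
    ))
  }
  graph
}

#' Write an interaction network as a canonical TSV edge list
#'
#' Endpoints are sorted lexicographically within each line and lines are
#' sorted, so equal networks serialize byte-identically. Reading the file back
#' with [read_edge_list()] recovers the same node and edge set (isolated
#' nodes, which an edge list cannot carry, are the one exception and trigger a
#' warning).
#'
#' @param net An interaction network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  net <- as_interaction_network(net)
  iso <- sum(igraph::degree(net) == 0)
  if (iso > 0) {
    warn(sprintf("%d isolated node(s) cannot be represented in an edge list.", iso))
  }
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) > 0) {
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, 2:1]
    lines <- paste(el[, 1], el[, 2], sep = "\t")
    lines <- sort(lines)
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a network to its largest connected component
#'
#' Shortest-path-based foreground selection is only well-defined within one
#' component, so restricting to the largest connected component (LCC) is
#' exposed as an explicit step. Ties between equally large components are
#' broken in favour of the component containing the lexicographically
#' smallest node ID.
#'
#' @param net An interaction network.
#' @return The induced subgraph on the largest component.
#' @export
largest_connected_component <- function(net) {
  net <- as_interaction_network(net)
  if (igraph::vcount(net) == 0) {
    abort("network is empty.")
  }
  comp <- igraph::components(net)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    ids <- igraph::V(net)$name
    min_member <- vapply(best, function(ci) min(ids[comp$membership == ci]), character(1))
    best <- best[order(min_member)][1]
  }
  sub <- igraph::induced_subgraph(net, which(comp$membership == best))
  if (igraph::ecount(sub) < igraph::ecount(net)) {
    inform(sprintf(
      "largest_connected_component: kept %d of %d nodes.",
      igraph::vcount(sub), igraph::vcount(net)
    ))
  }
  sub
}

#' Generate a connected synthetic interaction network
#'
#' Test substrate standing in for real PPI downloads. Three models:
#' * `preferential_attachment` - Barabasi-Albert scale-free graph; degree
#'   distribution loosely resembles PPI networks. `model_params$m` edges per
#'   new node (default 2).
#' * `ring_lattice` - deterministic circulant graph; `model_params$degree`
#'   (even, default 2) neighbours per node.
#' * `erdos_renyi` - G(n, p) with `model_params$p`; regenerated (up to
#'   `model_params$max_attempts`, default 100) until connected.
#'
#' The same `(model, n_nodes, model_params, seed)` always yields an identical
#' graph. Vertices are named `g001, g002, ...`.
#'
#' @param model One of `"preferential_attachment"`, `"ring_lattice"`,
#'   `"erdos_renyi"`.
#' @param n_nodes Number of nodes (>= 2).
#' @param model_params Named list of model parameters (see above).
#' @param seed Integer seed; all randomness is local to the call.
#' @return A connected interaction network.
#' @examples
#' net <- generate_synthetic_network("preferential_attachment", 100, seed = 1)
#' igraph::vcount(net)
#' @export
generate_synthetic_network <- function(model = c("preferential_attachment",
                                                 "ring_lattice",
                                                 "erdos_renyi"),
                                       n_nodes, model_params = list(),
                                       seed = 1L) {
  model <- match.arg(model)
  if (!is_count(n_nodes) || n_nodes < 2) {
    abort("`n_nodes` must be an integer >= 2.")
  }
  n_nodes <- as.integer(n_nodes)
  node_ids <- sprintf(paste0("g%0", nchar(n_nodes), "d"), seq_len(n_nodes))

  graph <- with_seed(seed, {
    switch(model,
      preferential_attachment = {
        m <- model_params$m %||% 2
        igraph::sample_pa(n_nodes, power = 1, m = m, directed = FALSE)
      },
      ring_lattice = {
        degree <- model_params$degree %||% 2
        if (!is_count(degree) || degree %% 2 != 0 || degree >= n_nodes) {
          abort("`degree` must be a positive even integer smaller than `n_nodes`.")
        }
        igraph::make_lattice(length = n_nodes, dim = 1, nei = degree / 2,
                             periodic = TRUE)
      },
      erdos_renyi = {
        p <- model_params$p %||% stop("erdos_renyi requires `model_params$p`.")
        max_attempts <- model_params$max_attempts %||% 100
        g <- NULL
        for (attempt in seq_len(max_attempts)) {
          g <- igraph::sample_gnp(n_nodes, p)
          if (igraph::is_connected(g)) break
          g <- NULL
        }
        if (is.null(g)) {
          abort(sprintf(
            "could not generate a connected G(%d, %g) graph in %d attempts; increase p.",
            n_nodes, p, max_attempts
          ))
        }
        g
      }
    )
  })
  igraph::V(graph)$name <- node_ids
  net <- as_interaction_network(graph, name = sprintf("%s_n%d_seed%d", model, n_nodes, seed))
  if (!igraph::is_connected(net)) {
    # preferential attachment and ring lattices are connected by construction;
    # this is a safety net, not an expected path
    abort("generated network is not connected.")
  }
  net
}
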