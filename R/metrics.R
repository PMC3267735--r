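#' Nodal connectivity degree
#'
#' Number of direct neighbours of each voxel; the sum over nodes equals twice
#' the edge count.
#'
#' @param G A `functional_graph` or igraph object.
#' @return Integer vector named by node id.
#' @export
nodal_degree <- function(G) {
  fg <- as_fgraph(G)
  k <- igraph::degree(fg$graph)
  names(k) <- fg$node_ids
  k
}

#' Nodal clustering coefficient
#'
#' Watts-Strogatz local clustering: the fraction of a voxel's neighbour pairs
#' that are themselves connected, i.e. edges among neighbours divided by
#' `k_i (k_i - 1) / 2`. Nodes of degree < 2 are assigned 0 so the metric map
#' is complete.
#'
#' @param G A `functional_graph` or igraph object.
#' @return Numeric vector in `[0, 1]`, named by node id.
#' @export
nodal_clustering <- function(G) {
  fg <- as_fgraph(G)
  ci <- igraph::transitivity(fg$graph, type = "local", isolates = "zero")
  names(ci) <- fg$node_ids
  ci
}

#' Nodal characteristic path length
#'
#' Mean unweighted shortest-path distance (minimal number of edges) from each
#' voxel to every other voxel. Defined only on a connected graph; restrict to
#' the largest component first (see [restrict_to_largest()]).
#'
#' @param G A connected `functional_graph` or igraph object.
#' @return Numeric vector (>= 1 for non-trivial graphs), named by node id.
#' @export
nodal_path_length <- function(G) {
  fg <- as_fgraph(G)
  if (igraph::components(fg$graph)$no != 1)
    stop("graph is disconnected; restrict to the largest component first")
  d <- igraph::distances(fg$graph)
  li <- rowSums(d) / (fg$n_nodes - 1)
  names(li) <- fg$node_ids
  li
}

#' Global network metrics with small-world coefficients
#'
#' Means of the nodal metrics over the (connected) graph, normalized against
#' a null model: `gamma = C / C_rand`, `lambda = L / L_rand`,
#' `sigma = gamma / lambda`. A small-world network shows `gamma >> 1`,
#' `lambda ~ 1`, hence `sigma >> 1`.
#'
#' @param G A connected `functional_graph` (typically from
#'   [restrict_to_largest()]).
#' @param null_summary A `null_ensemble` summary (or list with `C_rand`,
#'   `L_rand`), e.g. from [null_ensemble()] or [theoretical_null()].
#' @return A `global_metrics` object with fields `K`, `C`, `L`, `gamma`,
#'   `lambda`, `sigma`, `n_nodes`.
#' @export
global_metrics <- function(G, null_summary) {
  fg <- as_fgraph(G)
  k <- mean(nodal_degree(fg))
  c_mean <- mean(nodal_clustering(fg))
  l_mean <- mean(nodal_path_length(fg))
  gamma <- c_mean / null_summary$C_rand
  lambda <- l_mean / null_summary$L_rand
  structure(list(K = k, C = c_mean, L = l_mean,
                 gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 n_nodes = fg$n_nodes),
            class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf(
    "Global metrics (N = %d): K = %.2f, C = %.3f, L = %.3f | gamma = %.2f, lambda = %.2f, sigma = %.2f\n",
    x$n_nodes, x$K, x$C, x$L, x$gamma, x$lambda, x$sigma))
  invisible(x)
}

#' Export a nodal metrics table
#'
#' @param G A connected `functional_graph`.
#' @param path CSV output path (columns `node_id`, `K_i`, `C_i`, `L_i`).
#' @export
write_metrics_csv <- function(G, path) {
  fg <- as_fgraph(G)
  df <- data.frame(node_id = fg$node_ids,
                   K_i = as.integer(nodal_degree(fg)),
                   C_i = nodal_clustering(fg),
                   L_i = nodal_path_length(fg))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
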