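#' Theoretical random-graph null values
#'
#' Closed-form null expectations for an uncorrelated random graph with `N`
#' nodes and mean degree `K`: `C_rand = K / N` and
#' `L_rand = ln(N) / ln(K)`.
#'
#' @param N Number of nodes (>= 2).
#' @param K Mean degree (> 1).
#' @return List with `C_rand` and `L_rand`.
#' @export
theoretical_null <- function(N, K) {
  if (N < 2) stop("N must be at least 2")
  if (K <= 1) stop("K must exceed 1")
  list(C_rand = K / N, L_rand = log(N) / log(K))
}

#' Degree-preserving randomization by double edge swaps
#'
#' Maslov-Sneppen rewiring: repeatedly picks two edges and swaps their
#' endpoints, accepting a swap only if it creates no self-loop or duplicate
#' edge. Every node keeps its exact degree. If no swap could be applied (for
#' example a triangle, the unique simple graph on its degree sequence) the
#' input is returned unchanged with a warning.
#'
#' @param G A `functional_graph` or igraph object with at least 2 edges.
#' @param swap_factor Attempted swaps as a multiple of the edge count
#'   (default 10).
#' @param seed Integer seed; deterministic given the seed.
#' @return A rewired `functional_graph` with the same degree sequence.
#' @export
rewire_preserving_degree <- function(G, swap_factor = 10, seed = 1L) {
  fg <- as_fgraph(G)
  ne <- igraph::ecount(fg$graph)
  if (ne < 2) stop("need at least 2 edges to rewire")
  niter <- ceiling(swap_factor * ne)
  rg <- with_seed(seed,
    igraph::rewire(fg$graph, igraph::keeping_degseq(loops = FALSE,
                                                    niter = niter)))
  if (identical(sort_edge_pairs(rg), sort_edge_pairs(fg$graph)) &&
      igraph::vcount(fg$graph) <= 8)
    warning("no valid degree-preserving swap; graph returned unchanged")
  structure(list(graph = rg, threshold = fg$threshold, n_nodes = fg$n_nodes,
                 node_ids = fg$node_ids, roi = fg$roi),
            class = "functional_graph")
}

sort_edge_pairs <- function(g) {
  e <- igraph::as_edgelist(g, names = FALSE)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Null ensemble of degree-preserving random graphs
#'
#' Generates `n_replicates` rewired copies of a graph and summarizes the
#' clustering coefficient and characteristic path length across the
#' ensemble. Rewired replicates may fragment; each replicate's metrics are
#' computed on its largest component, mirroring the treatment of the
#' empirical graphs (set `reject_disconnected = TRUE` to instead resample
#' until connected).
#'
#' @param G A connected `functional_graph`.
#' @param n_replicates Ensemble size (default 1000).
#' @param seed Master seed; replicate seeds are derived deterministically.
#' @param swap_factor Swap attempts per edge for each replicate.
#' @param keep_replicates If `TRUE`, per-replicate C and L values are
#'   retained in the summary.
#' @param reject_disconnected If `TRUE`, disconnected replicates are redrawn
#'   (up to 50 attempts each).
#' @return A `null_ensemble` with `C_rand`, `L_rand`, `n_replicates`, `seed`
#'   and optionally `per_replicate`.
#' @export
null_ensemble <- function(G, n_replicates = 1000L, seed = 1L,
                          swap_factor = 10, keep_replicates = FALSE,
                          reject_disconnected = FALSE) {
  fg <- as_fgraph(G)
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  deg_obs <- sort(as.integer(igraph::degree(fg$graph)))
  cs <- numeric(n_replicates)
  ls <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    attempt <- 0L
    repeat {
      rep_seed <- seed_for(seed, 7L, r, attempt)
      rg <- rewire_preserving_degree(fg, swap_factor, seed = rep_seed)
      if (!identical(sort(as.integer(igraph::degree(rg$graph))), deg_obs))
        stop("internal error: degree sequence not preserved")
      connected <- igraph::components(rg$graph)$no == 1
      if (connected || !reject_disconnected || attempt >= 50L) break
      attempt <- attempt + 1L
    }
    gc <- restrict_to_largest(rg)
    cs[r] <- mean(nodal_clustering(gc))
    ls[r] <- mean(nodal_path_length(gc))
  }
  structure(list(C_rand = mean(cs), L_rand = mean(ls),
                 n_replicates = as.integer(n_replicates), seed = seed,
                 per_replicate = if (keep_replicates)
                   list(C = cs, L = ls) else NULL),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "Null ensemble (%d degree-preserving rewires): C_rand = %.4f, L_rand = %.3f\n",
    x$n_replicates, x$C_rand, x$L_rand))
  invisible(x)
}

#' Persist a null-ensemble summary as JSON
#'
#' @param x A `null_ensemble`.
#' @param path Output path.
#' @export
write_null_summary <- function(x, path) {
  jsonlite::write_json(list(C_rand = x$C_rand, L_rand = x$L_rand,
                            n_replicates = x$n_replicates, seed = x$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
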