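#' Voxel-wise synchronization matrix
#'
#' Zero-lag Pearson correlations between all pairs of voxel time series.
#'
#' @param ts A `clean_series`, `bold_series` or voxels x timepoints matrix.
#' @return A `sync_matrix`: symmetric N x N correlation matrix (field
#'   `values`) with the originating ROI, if known.
#' @export
correlation_matrix <- function(ts) {
  y <- series_matrix(ts)
  if (ncol(y) < 3) stop("need at least 3 timepoints")
  sds <- apply(y, 1, stats::sd)
  if (any(sds < .Machine$double.eps * 100)) {
    bad <- which(sds < .Machine$double.eps * 100)
    stop("constant voxel series at indices: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  m <- stats::cor(t(y))
  m <- (m + t(m)) / 2
  structure(list(values = m,
                 roi = if (is.list(ts)) ts$roi else NULL),
            class = "sync_matrix")
}

sync_values <- function(M) if (inherits(M, "sync_matrix")) M$values else as.matrix(M)

#' @export
print.sync_matrix <- function(x, ...) {
  v <- x$values[upper.tri(x$values)]
  cat("Synchronization matrix:", nrow(x$values), "voxels | off-diagonal r:",
      sprintf("median %.3f, range [%.3f, %.3f]\n",
              stats::median(v), min(v), max(v)))
  invisible(x)
}

#' Threshold a synchronization matrix into an undirected graph
#'
#' An edge joins voxels i and j exactly when their correlation strictly
#' exceeds `T`. Negative and zero correlations never form edges, and boundary
#' equality is excluded.
#'
#' @param M A `sync_matrix` or symmetric matrix.
#' @param T Correlation threshold in (0, 1).
#' @return A `functional_graph`: wrapper around an undirected simple
#'   [igraph::graph] over all N voxels (including isolates), carrying the
#'   threshold and node ids.
#' @export
threshold_graph <- function(M, T) {
  m <- sync_values(M)
  if (T <= 0 || T >= 1) stop("threshold T must lie in (0, 1)")
  n <- nrow(m)
  ut <- which(upper.tri(m) & m > T, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(ut))
    g <- igraph::add_edges(g, as.vector(t(ut)))
  structure(list(graph = g, threshold = T, n_nodes = n,
                 node_ids = seq_len(n),
                 roi = if (inherits(M, "sync_matrix")) M$roi else NULL),
            class = "functional_graph")
}

as_fgraph <- function(g) {
  if (inherits(g, "functional_graph")) return(g)
  stopifnot(inherits(g, "igraph"))
  structure(list(graph = g, threshold = NA_real_,
                 n_nodes = igraph::vcount(g),
                 node_ids = seq_len(igraph::vcount(g)), roi = NULL),
            class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  cat("Functional graph:", x$n_nodes, "nodes,", igraph::ecount(x$graph),
      "edges", if (!is.na(x$threshold)) paste0("(T = ", x$threshold, ")"),
      "\n")
  invisible(x)
}

#' Largest connected component
#'
#' @param G A `functional_graph` or igraph object.
#' @return List with `nodes` (indices of the largest component, ties broken
#'   by the component containing the lowest node index) and `fraction`
#'   (size / N).
#' @export
largest_component <- function(G) {
  fg <- as_fgraph(G)
  comp <- igraph::components(fg$graph)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    firsts <- vapply(best, function(b) min(which(comp$membership == b)),
                     integer(1))
    best <- best[which.min(firsts)]
  }
  nodes <- fg$node_ids[comp$membership == best]
  list(nodes = nodes, fraction = length(nodes) / fg$n_nodes)
}

#' Adaptive percolation threshold scan
#'
#' Raises the correlation threshold from `t0` in steps of `step` until the
#' largest connected component of the thresholded graph no longer contains at
#' least `criterion` of all nodes; `T_max` is the last passing grid value.
#'
#' @param M A `sync_matrix` or symmetric matrix.
#' @param t0 Scan start (default 0.1).
#' @param step Grid step (default 0.002).
#' @param criterion Required largest-component node fraction (default 0.95,
#'   compared as `>=`).
#' @param full_grid If `TRUE`, continue past the first failure up to the
#'   maximum off-diagonal correlation (for percolation-trajectory plots).
#' @return A `threshold_scan`: fields `T_grid`, `largest_component_fraction`,
#'   `T_max`, plus scan metadata.
#' @export
scan_tmax <- function(M, t0 = 0.1, step = 0.002, criterion = 0.95,
                      full_grid = FALSE) {
  m <- sync_values(M)
  n <- nrow(m)
  max_r <- max(m[upper.tri(m)])
  # grid covers t0 .. first point at/above the maximum correlation (where
  # the graph is empty and the criterion necessarily fails)
  k_hi <- max(0L, as.integer(ceiling((max_r - t0) / step)))
  grid <- t0 + (0:k_hi) * step
  # candidate edges, sorted by descending correlation; walking the grid from
  # the top down and union-finding incrementally yields the largest-component
  # fraction at every grid point in one pass (edge sets are nested in T)
  ut <- which(upper.tri(m) & m > t0)
  w <- m[ut]
  ord <- order(w, decreasing = TRUE)
  ei <- ((ut - 1L) %% n) + 1L
  ej <- ((ut - 1L) %/% n) + 1L
  ei <- ei[ord]; ej <- ej[ord]; w <- w[ord]
  parent <- seq_len(n)
  size <- rep(1L, n)
  largest <- 1L
  frac_desc <- numeric(k_hi + 1L)
  e <- 1L
  n_e <- length(w)
  for (k in (k_hi + 1L):1L) {
    T <- grid[k]
    while (e <= n_e && w[e] > T) {
      a <- ei[e]
      while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
      b <- ej[e]
      while (parent[b] != b) { parent[b] <- parent[parent[b]]; b <- parent[b] }
      if (a != b) {
        if (size[a] < size[b]) { tmp <- a; a <- b; b <- tmp }
        parent[b] <- a
        size[a] <- size[a] + size[b]
        if (size[a] > largest) largest <- size[a]
      }
      e <- e + 1L
    }
    frac_desc[k] <- largest / n
  }
  frac <- frac_desc
  pass <- frac >= criterion
  if (!pass[1])
    stop("largest component below criterion already at T = ", t0,
         " (data too weakly connected)")
  first_fail <- if (any(!pass)) which(!pass)[1] else length(grid) + 1L
  t_max <- grid[first_fail - 1L]
  keep <- if (full_grid) seq_along(grid) else seq_len(min(first_fail, length(grid)))
  structure(list(T_grid = grid[keep], largest_component_fraction = frac[keep],
                 T_max = t_max, criterion = criterion, comparison = ">=",
                 t0 = t0, step = step),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf(
    "Threshold scan: T_max = %.3f (criterion %s %.2f, grid %.3f by %.3f, %d points)\n",
    x$T_max, x$comparison, x$criterion, x$t0, x$step, length(x$T_grid)))
  invisible(x)
}

#' Common group threshold
#'
#' The single threshold used for all nodal maps: the minimum per-dataset
#' `T_max`, so that every dataset's graph retains at least the criterion
#' fraction of nodes in its largest component.
#'
#' @param t_maxes Numeric vector of per-dataset `T_max` values (or a list of
#'   `threshold_scan` objects).
#' @return The minimum, a scalar.
#' @export
group_common_threshold <- function(t_maxes) {
  if (is.list(t_maxes))
    t_maxes <- vapply(t_maxes, function(x)
      if (inherits(x, "threshold_scan")) x$T_max else as.numeric(x), double(1))
  if (!length(t_maxes)) stop("no T_max values supplied")
  min(t_maxes)
}

#' Restrict a graph to its largest connected component
#'
#' @param G A `functional_graph`.
#' @return A `functional_graph` induced by the largest component; the node
#'   ids of retained voxels are kept in `node_ids`, dropped voxels are
#'   recorded in `missing_nodes`.
#' @export
restrict_to_largest <- function(G) {
  fg <- as_fgraph(G)
  lc <- largest_component(fg)
  keep <- match(lc$nodes, fg$node_ids)
  sub <- igraph::induced_subgraph(fg$graph, keep)
  structure(list(graph = sub, threshold = fg$threshold,
                 n_nodes = length(keep), node_ids = fg$node_ids[keep],
                 missing_nodes = setdiff(fg$node_ids, lc$nodes),
                 roi = fg$roi),
            class = "functional_graph")
}

#' Export a graph as an edge list
#'
#' Writes `node_i node_j` pairs (0-based voxel ordinals) as whitespace-
#' delimited text.
#'
#' @param G A `functional_graph`.
#' @param path Output file.
#' @export
write_edgelist <- function(G, path) {
  fg <- as_fgraph(G)
  e <- igraph::as_edgelist(fg$graph, names = FALSE)
  e <- matrix(fg$node_ids[e] - 1L, ncol = 2)
  utils::write.table(e, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a graph adjacency matrix in MatrixMarket format
#'
#' @param G A `functional_graph`.
#' @param path Output `.mtx` file.
#' @export
write_adjacency_mtx <- function(G, path) {
  fg <- as_fgraph(G)
  e <- igraph::as_edgelist(fg$graph, names = FALSE)
  a <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = c(fg$n_nodes, fg$n_nodes), symmetric = TRUE)
  Matrix::writeMM(a, path)
  invisible(path)
}
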