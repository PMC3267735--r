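# Brute-force oracles, written independently of the package's code paths.

# random symmetric adjacency matrix of an Erdos-Renyi graph
random_adj <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(runif(length(up)) < p)
  a + t(a)
}

adj_of <- function(g) {
  fg <- if (inherits(g, "functional_graph")) g$graph else g
  as.matrix(igraph::as_adjacency_matrix(fg, sparse = FALSE))
}

fgraph_from_adj <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

oracle_degree <- function(a) {
  k <- integer(nrow(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    if (a[i, j] == 1) k[i] <- k[i] + 1L
  k
}

# triangle-enumeration clustering; 0 for degree < 2
oracle_clustering <- function(a) {
  n <- nrow(a)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- 0L
    for (u in seq_along(nb)) for (v in seq_along(nb))
      if (u < v && a[nb[u], nb[v]] == 1) links <- links + 1L
    ci[i] <- links / (k * (k - 1) / 2)
  }
  ci
}

# Floyd-Warshall all-pairs shortest paths (unweighted)
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_mean_path <- function(a) {
  d <- oracle_distances(a)
  rowSums(d) / (nrow(a) - 1)
}

# Warshall transitive closure -> connected component labels
oracle_components <- function(a) {
  n <- nrow(a)
  r <- (a == 1) | diag(TRUE, n)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (r[i, k] && r[k, j]) r[i, j] <- TRUE
  labels <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      lab <- lab + 1L
      labels[r[i, ]] <- lab
    }
  }
  labels
}

# literal grid-scan oracle for T_max: evaluate every grid point directly
oracle_scan_tmax <- function(m, t0 = 0.1, step = 0.002, criterion = 0.95) {
  n <- nrow(m)
  k <- 0
  t_max <- NA_real_
  repeat {
    T <- t0 + k * step
    a <- (m > T) * 1
    diag(a) <- 0
    frac <- max(table(oracle_components(a))) / n
    if (frac >= criterion) t_max <- T else break
    k <- k + 1
    if (T > 1) break
  }
  t_max
}

# exact sign-flip enumeration oracle for one-voxel cluster correction
oracle_signflip_p <- function(d, forming_p = 0.05) {
  n <- length(d)
  tcrit <- qt(1 - forming_p / 2, n - 1)
  tstat <- function(v) mean(v) / (sd(v) / sqrt(n))
  grid <- expand.grid(rep(list(c(-1, 1)), n))
  supra <- apply(grid, 1, function(s) {
    v <- s * d
    if (sd(v) == 0) return(FALSE)
    abs(tstat(v)) > tcrit
  })
  mean(supra)
}

sort_edges <- function(e) {
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}
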