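test_that("correlation matrix matches its definition", {
  set.seed(1)
  y <- matrix(rnorm(5 * 20), 5, 20)
  M <- correlation_matrix(y)$values
  # definitional oracle: covariance over product of standard deviations
  for (i in 1:5) for (j in 1:5) {
    num <- mean((y[i, ] - mean(y[i, ])) * (y[j, ] - mean(y[j, ])))
    den <- sqrt(mean((y[i, ] - mean(y[i, ]))^2) * mean((y[j, ] - mean(y[j, ]))^2))
    expect_equal(M[i, j], num / den, tolerance = 1e-12)
  }
  expect_equal(M, t(M), tolerance = 1e-15)

  # identical rows correlate at 1; orthogonal sinusoids at ~0
  tt <- seq(0, 2 * pi, length.out = 41)[-41]
  y2 <- rbind(sin(tt), cos(tt), sin(tt))
  M2 <- correlation_matrix(y2)$values
  expect_equal(M2[1, 3], 1, tolerance = 1e-12)
  expect_lt(abs(M2[1, 2]), 1e-6)

  expect_error(correlation_matrix(rbind(rep(1, 20), rnorm(20))), "constant")
  expect_error(correlation_matrix(y[, 1:2]), "3 timepoints")
})

test_that("thresholding uses a strict inequality and drops negatives", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.5
  m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.4
  e <- function(g) sort_edges(igraph::as_edgelist(g$graph, names = FALSE))
  g <- threshold_graph(m, 0.35)
  expect_equal(e(g), rbind(c(1, 2), c(2, 3)))
  expect_equal(igraph::ecount(threshold_graph(m, 0.6)$graph), 0)
  # boundary equality excluded: at T = 0.4 only the 0.5 edge remains
  expect_equal(igraph::ecount(threshold_graph(m, 0.4)$graph), 1)
  # negative correlations never form edges
  mn <- diag(2); mn[1, 2] <- mn[2, 1] <- -0.9
  expect_equal(igraph::ecount(threshold_graph(mn, 0.1)$graph), 0)
  expect_error(threshold_graph(m, 1.2), "\\(0, 1\\)")
})

test_that("largest component matches the closure oracle", {
  a <- random_adj(20, 0.2, seed = 5)
  fg <- voxgraph:::as_fgraph(fgraph_from_adj(a))
  lc <- largest_component(fg)
  labels <- oracle_components(a)
  sizes <- table(labels)
  expect_equal(length(lc$nodes), max(sizes))
  expect_equal(lc$fraction, max(sizes) / 20)
  best <- as.integer(names(sizes)[sizes == max(sizes)])
  expect_true(all(lc$nodes %in% which(labels %in% best)))

  # two components of sizes 3 and 2
  a2 <- matrix(0, 5, 5)
  a2[1, 2] <- a2[2, 3] <- a2[4, 5] <- 1
  a2 <- a2 + t(a2)
  expect_equal(largest_component(voxgraph:::as_fgraph(fgraph_from_adj(a2)))$fraction, 0.6)
})

test_that("the threshold scan reproduces the exhaustive oracle", {
  m <- diag(4)
  m[1, 2] <- m[2, 1] <- 0.9
  m[2, 3] <- m[3, 2] <- 0.9
  m[3, 4] <- m[4, 3] <- 0.30
  m[1, 3] <- m[3, 1] <- 0.05
  m[1, 4] <- m[4, 1] <- 0.05
  m[2, 4] <- m[4, 2] <- 0.05
  sc <- scan_tmax(m)
  expect_equal(sc$T_max, 0.298, tolerance = 1e-9)
  expect_equal(sc$T_max, oracle_scan_tmax(m), tolerance = 1e-9)

  # fully connected matrix: scan exhausts the grid below the common value
  mc <- matrix(0.9, 5, 5); diag(mc) <- 1
  sc2 <- scan_tmax(mc)
  expect_lt(sc2$T_max, 0.9)
  expect_gte(sc2$T_max, 0.9 - 0.002)

  expect_error(scan_tmax(matrix(0, 4, 4) + diag(4)), "weakly connected")
})

test_that("scan trajectories are monotone and edge counts decrease in T", {
  roi <- make_roi(40, "slab", seed = 2)
  ses <- simulate_session(roi, n_timepoints = 80, seed = 3)
  M <- correlation_matrix(preprocess_series(ses$bold, ses$nuisance))
  sc <- scan_tmax(M, full_grid = TRUE)
  expect_false(is.unsorted(rev(sc$largest_component_fraction)))
  ecounts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(T)
    igraph::ecount(threshold_graph(M, T)$graph), double(1))
  expect_false(is.unsorted(rev(ecounts)))
  # below the minimum off-diagonal entry the graph is complete
  m <- M$values
  tlow <- min(m[upper.tri(m)]) - 0.01
  if (tlow > 0) {
    g <- threshold_graph(M, tlow)
    expect_equal(igraph::ecount(g$graph), choose(nrow(m), 2))
  }
})

test_that("the group threshold is the minimum T_max", {
  expect_equal(group_common_threshold(c(0.352, 0.40, 0.39)), 0.352)
  expect_equal(group_common_threshold(0.2), 0.2)
  expect_equal(group_common_threshold(c(0.40, 0.352, 0.39)), 0.352)
  expect_error(group_common_threshold(numeric(0)), "no T_max")
})

test_that("restriction to the largest component records dropped nodes", {
  a <- matrix(0, 5, 5)
  a[1, 2] <- a[2, 3] <- a[1, 3] <- 1
  a <- a + t(a)
  fg <- voxgraph:::as_fgraph(fgraph_from_adj(a))
  r <- restrict_to_largest(fg)
  expect_equal(sort(r$node_ids), 1:3)
  expect_setequal(r$missing_nodes, 4:5)
  # connected input is the identity
  k4 <- voxgraph:::as_fgraph(fgraph_from_adj(matrix(1, 4, 4) - diag(4)))
  expect_equal(restrict_to_largest(k4)$n_nodes, 4)
})

test_that("graphs export as edge lists and MatrixMarket adjacency", {
  a <- random_adj(10, 0.3, seed = 1)
  fg <- voxgraph:::as_fgraph(fgraph_from_adj(a))
  f1 <- tempfile(fileext = ".txt")
  write_edgelist(fg, f1)
  el <- as.matrix(read.table(f1))
  expect_equal(nrow(el), sum(a) / 2)
  expect_true(all(el >= 0 & el <= 9))
  f2 <- tempfile(fileext = ".mtx")
  write_adjacency_mtx(fg, f2)
  back <- as.matrix(Matrix::readMM(f2))
  expect_equal(unname(back != 0), unname(a == 1))
})
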