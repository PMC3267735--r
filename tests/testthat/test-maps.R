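test_that("degree maps scale to a unit maximum", {
  m <- normalize_degree_map(c(2, 4, 8))
  expect_equal(m$values, c(0.25, 0.5, 1))
  expect_equal(normalize_degree_map(c(3, 3, 3))$values, c(1, 1, 1))
  expect_error(normalize_degree_map(c(0, 0)), "positive")
})

test_that("clustering and path-length normalizations are elementwise", {
  expect_equal(normalize_clustering_map(0.6, 0.2)$values, 3)
  expect_equal(normalize_clustering_map(0, 0.2)$values, 0)
  set.seed(1)
  v <- runif(20)
  expect_equal(normalize_clustering_map(v, 0.13)$values, v / 0.13)
  expect_error(normalize_clustering_map(v, 0), "positive")

  expect_equal(normalize_pathlength_map(2, 1.6)$values, 0.8)
  expect_equal(normalize_pathlength_map(1.6, 1.6)$values, 1)
  l <- seq(3, 1.2, length.out = 10)
  out <- normalize_pathlength_map(l, 1.6)$values
  expect_false(is.unsorted(out))  # monotone inversion
  expect_error(normalize_pathlength_map(c(1, 0), 1.6), "positive")
})

test_that("normalizations preserve voxel ranks", {
  set.seed(2)
  k <- sample(1:50, 25, replace = TRUE)
  expect_equal(rank(normalize_degree_map(k)$values), rank(k))
  c_i <- runif(25)
  expect_equal(rank(normalize_clustering_map(c_i, 0.2)$values), rank(c_i))
  l_i <- runif(25, 1, 3)
  expect_equal(rank(normalize_pathlength_map(l_i, 1.8)$values), rank(-l_i))
})

test_that("in-mask smoothing is exact on constants and preserves the mean", {
  roi <- make_roi(80, "blob", seed = 4)
  v <- runif(80)
  v[c(3, 10)] <- NA
  ok <- !is.na(v)
  sm <- smooth_map(v, roi, 6)
  expect_identical(which(is.na(sm$values)), which(is.na(v)))
  expect_lt(abs(mean(sm$values[ok]) - mean(v[ok])), 1e-10)
  expect_equal(smooth_map(rep(2.5, 80), roi, 6)$values, rep(2.5, 80),
               tolerance = 1e-10)
  expect_identical(smooth_map(v, roi, 0)$values, v)
})

test_that("an impulse smooths into a renormalized Gaussian profile", {
  roi <- make_roi(60, "slab", seed = 1)
  v <- rep(0, 60)
  v[30] <- 1
  fwhm <- 6
  sm <- smooth_map(v, roi, fwhm)
  # oracle: the doubly stochastic scaling d_i K_ij d_j applied to the impulse
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  d_mm <- as.matrix(dist(roi$coords)) * roi$voxel_size_mm
  k <- exp(-d_mm^2 / (2 * sigma^2))
  d <- 1 / sqrt(rowSums(k))
  for (i in 1:2000) {
    r <- d * as.vector(k %*% d)
    if (max(abs(r - 1)) < 1e-14) break
    d <- d / sqrt(r)
  }
  expect_equal(sm$values, unname(d * (k %*% (d * v))[, 1]),
               tolerance = 1e-8)
  # the profile decays with distance from the impulse
  dist30 <- d_mm[30, ]
  ord <- order(dist30)
  expect_gt(sm$values[30], max(sm$values[-30]))
})

test_that("hub extraction selects the top fraction with tie inclusion", {
  vals <- matrix(seq(0.05, 1, by = 0.05), 1)  # 20 voxels
  hm <- hub_map(vals, fraction = 0.15)
  expect_length(hm$hub_voxels, 3)
  expect_setequal(hm$hub_voxels, 18:20)

  # near-unity fraction selects every voxel
  hm_all <- hub_map(vals, fraction = 0.999)
  expect_length(hm_all$hub_voxels, 20)

  # ties at the cutoff are all included and the realized fraction recorded
  vals_tie <- matrix(c(rep(1, 5), rep(0.5, 15)), 1)
  hm_tie <- hub_map(vals_tie, fraction = 0.15)
  expect_length(hm_tie$hub_voxels, 5)
  expect_equal(hm_tie$realized_fraction, 0.25)

  # invariance to strictly monotone transforms
  hm_exp <- hub_map(exp(3 * vals), fraction = 0.15)
  expect_setequal(hm_exp$hub_voxels, hm$hub_voxels)

  # voxels missing in any map are excluded
  two <- rbind(seq(0.05, 1, by = 0.05), seq(0.05, 1, by = 0.05))
  two[2, 20] <- NA
  hm_miss <- hub_map(two, fraction = 0.15)
  expect_false(20 %in% hm_miss$hub_voxels)
})

test_that("a planted shortcut hub is recovered from path-length maps", {
  # graph-level construction: a ring lattice with one subregion wired
  # broadly across the network communicates most efficiently
  set.seed(8)
  n <- 80
  base <- igraph::sample_smallworld(1, n, 3, 0.05)
  hub_vox <- 1:12
  extra <- unlist(lapply(hub_vox, function(h)
    rbind(h, sample(setdiff(1:n, hub_vox), 6))))
  g <- igraph::add_edges(base, extra)
  g <- igraph::simplify(g)
  fg <- voxgraph:::as_fgraph(g)
  li <- nodal_path_length(fg)
  lmap <- normalize_pathlength_map(unname(li), mean(li))
  hm <- hub_map(matrix(lmap$values, 1), fraction = 0.15)
  expect_gt(dice_overlap(hm$hub_voxels, hub_vox), 0.5)
})

test_that("nodal_maps assembles normalized maps with missing voxels", {
  roi <- make_roi(40, "slab", seed = 3)
  ses <- simulate_session(roi, n_timepoints = 80, seed = 2)
  M <- correlation_matrix(preprocess_series(ses$bold, ses$nuisance))
  g <- restrict_to_largest(threshold_graph(M, scan_tmax(M)$T_max))
  maps <- nodal_maps(g, roi, theoretical_null(g$n_nodes, mean(nodal_degree(g))),
                     fwhm_mm = 0)
  expect_named(maps, c("K_norm", "C_norm", "L_norm"))
  expect_equal(max(maps$K_norm$values, na.rm = TRUE), 1)
  expect_setequal(which(is.na(maps$C_norm$values)), g$missing_nodes)
})
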