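roi_small <- make_roi(60, "slab", seed = 1)

test_that("generated signal components are band-limited", {
  # noise off: data is the latent field plus nuisance-free scaling
  ses <- simulate_session(roi_small, noise_sd = 0, nuisance_amplitude = 0,
                          amp_jitter_sd = 0, n_timepoints = 175, seed = 2)
  x <- ses$bold$data
  fs <- 1 / 1.8
  for (i in c(1, 20, 45)) {
    sp <- stats::spec.pgram(x[i, ], plot = FALSE, detrend = TRUE, taper = 0)
    freq_hz <- sp$freq * fs
    outside <- freq_hz < 0.005 | freq_hz > 0.12
    expect_lt(sum(sp$spec[outside]) / sum(sp$spec), 0.05)
  }
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_session(roi_small, seed = 11, n_timepoints = 80)
  b <- simulate_session(roi_small, seed = 11, n_timepoints = 80)
  expect_identical(a$bold$data, b$bold$data)
  expect_identical(a$nuisance$regressors, b$nuisance$regressors)
  c <- simulate_session(roi_small, seed = 12, n_timepoints = 80)
  expect_false(identical(a$bold$data, c$bold$data))
})

test_that("degenerate limit: single latent, no noise gives correlation 1", {
  ses <- simulate_session(roi_small, noise_sd = 0, spatial_scale = Inf,
                          nuisance_amplitude = 0, amp_jitter_sd = 0,
                          n_timepoints = 80, seed = 3)
  m <- cor(t(ses$bold$data))
  expect_true(all(abs(m - 1) < 1e-8))
})

test_that("local coupling raises within-target correlation by delta", {
  roi <- make_roi(200, "slab", seed = 1)
  tgt <- order(rowSums(sweep(roi$coords, 2, colMeans(roi$coords))^2))[1:40]
  eff <- effect_spec("local_coupling", target_voxels = tgt,
                     coupling_delta = 0.15)
  s0 <- simulate_session(roi, effect_spec("none"), seed = 5)
  s1 <- simulate_session(roi, eff, seed = 5)
  pp <- function(s) correlation_matrix(preprocess_series(s$bold, s$nuisance))$values
  m0 <- pp(s0)
  m1 <- pp(s1)
  ut <- upper.tri(m0[tgt, tgt])
  inc <- mean(m1[tgt, tgt][ut]) - mean(m0[tgt, tgt][ut])
  expect_gt(inc, 0.10)
  expect_lt(inc, 0.20)
  # localization: voxels outside the target have the same series
  off <- setdiff(seq_len(200), tgt)
  expect_identical(s0$bold$data[off, ], s1$bold$data[off, ])
})

test_that("impossible coupling raises an explicit error", {
  tgt <- 1:20
  bl <- effect_spec("local_coupling", tgt, 0.6, saturate = FALSE)
  eff <- effect_spec("local_coupling", tgt, 0.8)
  expect_error(
    simulate_session(roi_small, eff, baseline_effect = bl,
                     n_timepoints = 80, seed = 4),
    "above 1")
  expect_error(effect_spec("local_coupling", tgt, 1.2), "\\[0, 1\\)")
  expect_error(effect_spec("none", coupling_delta = 0.1), "requires")
})

test_that("long-range coupling links the target to a distal partner region", {
  roi <- make_roi(150, "slab", seed = 2)
  tgt <- order(rowSums(sweep(roi$coords, 2, colMeans(roi$coords))^2))[1:20]
  eff <- effect_spec("long_range", target_voxels = tgt, coupling_delta = 0.4,
                     n_shortcut_partners = 20L)
  s0 <- simulate_session(roi, effect_spec("none"), seed = 6, n_timepoints = 120)
  s1 <- simulate_session(roi, eff, seed = 6, n_timepoints = 120)
  prt <- s1$truth$partners
  expect_length(prt, 20)
  expect_length(intersect(prt, tgt), 0)
  m0 <- cor(t(s0$bold$data))
  m1 <- cor(t(s1$bold$data))
  expect_gt(mean(m1[tgt, prt]) - mean(m0[tgt, prt]), 0.2)
})

test_that("study simulation is fully crossed and labelled", {
  des <- study_design(seed = 9)
  expect_equal(des$n_subjects * length(des$sessions) * length(des$times), 84)
  small <- study_design(n_subjects = 2, sessions = "sham", seed = 9)
  st <- simulate_study(small,
                       roi_params = list(n_voxels = 30, shape = "slab",
                                         voxel_size_mm = 3),
                       session_params = list(n_timepoints = 60))
  expect_length(st$datasets, 4)
  expect_true(all(vapply(st$datasets, function(d)
    d$truth$effect$kind, character(1)) == "none"))
  # determinism of the whole collection
  st2 <- simulate_study(small,
                        roi_params = list(n_voxels = 30, shape = "slab",
                                          voxel_size_mm = 3),
                        session_params = list(n_timepoints = 60))
  expect_identical(st$datasets[[3]]$bold$data, st2$datasets[[3]]$bold$data)
})

test_that("effects are confined to non-sham post-stimulation cells", {
  expect_error(
    study_design(effects = list("sham.after" = list(kind = "local_coupling",
                                                    delta = 0.1))),
    "sham")
  expect_error(
    study_design(effects = list("anodal.before" = list(kind = "local_coupling",
                                                       delta = 0.1))),
    "no effect")
})

test_that("the QC-failure switch produces an excluded session", {
  ok <- simulate_session(roi_small, seed = 8, n_timepoints = 80)
  bad <- simulate_session(roi_small, seed = 8, n_timepoints = 80,
                          qc_fail = TRUE)
  expect_true(motion_qc(ok$nuisance)$pass)
  expect_false(motion_qc(bad$nuisance)$pass)
})

test_that("sub-seeds stay within 32-bit integer range and are reproducible", {
  s <- vapply(1:500, function(i) seed_for(123L, 5L, i), integer(1))
  expect_true(all(s >= 1 & s <= 2147483646))
  expect_identical(seed_for(7L, 1L, 2L), seed_for(7L, 1L, 2L))
  expect_false(seed_for(7L, 1L, 2L) == seed_for(7L, 2L, 1L))
})
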