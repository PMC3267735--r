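test_that("initial volumes are discarded correctly", {
  x <- matrix(rnorm(10 * 175), 10, 175)
  expect_equal(ncol(discard_initial_volumes(x, 2)), 173)
  expect_identical(discard_initial_volumes(x, 0), x)
  expect_error(discard_initial_volumes(x, 180), "discard")
})

test_that("motion QC applies the rms rule per axis", {
  zeros <- matrix(0, 6, 50)
  res <- motion_qc(zeros)
  expect_true(res$pass)
  expect_equal(unname(res$rms), rep(0, 6))

  bad <- zeros
  bad[2, ] <- 1.2
  expect_false(motion_qc(bad)$pass)

  # closed-form rms of a sinusoid over full periods: amplitude / sqrt(2)
  tt <- seq(0, 4 * pi, length.out = 201)[-201]
  s <- zeros
  s[1, ] <- 0  # keep dims; replace with sine trace of length 200
  s <- matrix(0, 6, 200)
  s[1, ] <- 0.8 * sin(tt)
  res <- motion_qc(s)
  expect_equal(unname(res$rms[1]), 0.8 / sqrt(2), tolerance = 1e-10)
  expect_error(motion_qc(matrix(0, 5, 10)), "6 traces")
})

test_that("nuisance regression produces orthogonal residuals", {
  set.seed(1)
  y <- matrix(rnorm(8 * 100), 8, 100)
  reg <- matrix(rnorm(9 * 100), 9, 100)
  cl <- nuisance_regression(y, reg)
  expect_true(all(abs(rowMeans(cl$data)) < 1e-10))
  for (k in 1:9)
    expect_true(all(abs(cor(t(cl$data), reg[k, ])) < 1e-8))

  # normal-equations oracle
  x <- cbind(1, t(reg))
  beta <- solve(t(x) %*% x, t(x) %*% t(y))
  resid_oracle <- t(t(y) - x %*% beta)
  expect_equal(cl$data, resid_oracle, tolerance = 1e-8)
})

test_that("nuisance regression handles perfect fits and degenerate designs", {
  reg <- matrix(rnorm(9 * 80), 9, 80)
  y <- rbind(reg[9, ], rnorm(80))
  cl <- nuisance_regression(y, reg)
  expect_lt(max(abs(cl$data[1, ])), 1e-10)

  # all-zero regressors collapse to the intercept-only model
  expect_warning(cl0 <- nuisance_regression(y, matrix(0, 9, 80)), "collinear")
  expect_equal(cl0$data, y - rowMeans(y), tolerance = 1e-10)
})

test_that("prewhitening removes AR(1) autocorrelation", {
  set.seed(2)
  white <- matrix(rnorm(3 * 5000), 3, 5000)
  pw <- prewhiten(white, 1)
  ac <- apply(pw$data, 1, function(v) acf(v, plot = FALSE)$acf[2])
  ac0 <- apply(white, 1, function(v) acf(v, plot = FALSE)$acf[2])
  expect_true(all(abs(ac - ac0) < 0.05))

  ar1 <- matrix(as.numeric(arima.sim(list(ar = 0.5), 10000)), 1)
  pw1 <- prewhiten(ar1, 1)
  expect_lt(abs(acf(pw1$data[1, ], plot = FALSE)$acf[2]), 0.03)

  expect_warning(pwc <- prewhiten(rbind(rep(1, 100), rnorm(100)), 1),
                 "constant")
  expect_true(all(pwc$data[1, ] == 0))
})

test_that("vectorized AR(1) prewhitening matches ar.yw", {
  set.seed(3)
  y <- matrix(rnorm(4 * 150), 4, 150)
  pw <- prewhiten(y, 1)
  for (i in 1:4) {
    fit <- stats::ar.yw(y[i, ], aic = FALSE, order.max = 1, demean = TRUE)
    ref <- (y[i, -1] - mean(y[i, ])) - fit$ar[1] * (y[i, -150] - mean(y[i, ]))
    expect_equal(unname(pw$data[i, ]), unname(ref), tolerance = 1e-10)
  }
})

test_that("band-pass keeps the passband and rejects the stopband", {
  tr <- 1.8
  tt <- (0:299) * tr
  inband <- sin(2 * pi * 0.05 * tt)
  stopb <- sin(2 * pi * 0.2 * tt)
  dc <- rep(5, 300)
  y <- rbind(inband, stopb, dc + inband)
  bp <- bandpass(y, 0.01, 0.09, tr_seconds = tr)
  amp <- function(v) sqrt(2 * mean(v^2))
  mid <- 60:240  # avoid filter edge transients
  expect_gt(amp(bp$data[1, mid]), 0.9)
  expect_lt(amp(bp$data[1, mid]), 1.1)
  expect_lt(amp(bp$data[2, mid]), 0.1)
  expect_lt(abs(mean(bp$data[3, ])), 0.05)
  # zero phase: cross-correlation of filtered and raw passband peaks at lag 0
  cc <- ccf(bp$data[1, mid], inband[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(bandpass(y, 0.05, 0.4, tr_seconds = tr), "Nyquist")
})

test_that("matrix filtering equals the reference per-vector filtfilt", {
  set.seed(4)
  x <- matrix(rnorm(6 * 160), 6, 160)
  bf <- signal::butter(2, c(0.01, 0.09) / (1 / (2 * 1.8)), type = "pass")
  mine <- voxgraph:::filtfilt_rows(bf$b, bf$a, x)
  ref <- t(apply(x, 1, function(v) signal::filtfilt(bf$b, bf$a, v)))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("the preprocessing chain is deterministic and records provenance", {
  roi <- make_roi(30, "slab", seed = 1)
  ses <- simulate_session(roi, n_timepoints = 80, seed = 5)
  a <- preprocess_series(ses$bold, ses$nuisance)
  b <- preprocess_series(ses$bold, ses$nuisance)
  expect_identical(a$data, b$data)
  chain <- a$provenance[[length(a$provenance)]]
  expect_equal(chain$order, c("regress", "prewhiten", "bandpass"))
  expect_equal(chain$discarded, 2L)
  # a reordered chain gives different results and different provenance
  c <- preprocess_series(ses$bold, ses$nuisance,
                         order = c("bandpass", "regress", "prewhiten"))
  expect_false(identical(dim(a$data), dim(c$data)) &&
                 isTRUE(all.equal(a$data, c$data)))
})
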