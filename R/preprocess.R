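#' Discard initial volumes of a BOLD series
#'
#' Drops the first `n` volumes (magnetization-equilibrium scans) from a series
#' and, if supplied, the matching columns of its nuisance regressors.
#'
#' @param ts A `bold_series` (or plain voxels x timepoints matrix).
#' @param n Number of leading volumes to drop (default 2).
#' @return Object of the same type with `n` fewer timepoints.
#' @export
discard_initial_volumes <- function(ts, n = 2L) {
  m <- series_matrix(ts)
  if (n < 0) stop("n must be non-negative")
  if (n >= ncol(m)) stop("cannot discard ", n, " of ", ncol(m), " volumes")
  keep <- if (n == 0) seq_len(ncol(m)) else -(seq_len(n))
  set_series_matrix(ts, m[, keep, drop = FALSE])
}

series_matrix <- function(ts) {
  if (inherits(ts, c("bold_series", "clean_series"))) ts$data else as.matrix(ts)
}

set_series_matrix <- function(ts, m) {
  if (inherits(ts, c("bold_series", "clean_series"))) {
    ts$data <- m
    ts
  } else m
}

#' Motion quality control
#'
#' Checks the root-mean-square of each of six rigid-body motion traces
#' (three translations in mm, three rotations in degrees) against limits.
#'
#' @param motion 6 x timepoints matrix (rows: tx, ty, tz, rx, ry, rz) or a
#'   `nuisance_set` (its first six rows are used).
#' @param limit_mm Translation rms limit (default 1 mm).
#' @param limit_deg Rotation rms limit (default 1 degree).
#' @return List with `pass` (logical) and `rms` (named per-axis rms).
#' @export
motion_qc <- function(motion, limit_mm = 1, limit_deg = 1) {
  if (inherits(motion, "nuisance_set")) motion <- motion$regressors[1:6, ]
  motion <- as.matrix(motion)
  if (nrow(motion) != 6) stop("motion must have exactly 6 traces")
  rms <- sqrt(rowMeans(motion^2))
  names(rms) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  limits <- c(rep(limit_mm, 3), rep(limit_deg, 3))
  list(pass = all(rms <= limits), rms = rms)
}

#' Nuisance regression
#'
#' Regresses the nine nuisance signals (six motion parameters, mean WM, mean
#' CSF and the global signal) plus an intercept out of every voxel time
#' series by ordinary least squares. Residuals are exactly orthogonal to the
#' regressors used. Collinear regressor columns are dropped with a warning
#' and recorded in the provenance.
#'
#' @param ts A `bold_series` (or matrix), voxels x timepoints.
#' @param nuis A `nuisance_set` (or 9 x timepoints matrix).
#' @return A `clean_series` with zero-mean residual rows and a provenance
#'   record.
#' @export
nuisance_regression <- function(ts, nuis) {
  y <- series_matrix(ts)
  reg <- if (inherits(nuis, "nuisance_set")) nuis$regressors else as.matrix(nuis)
  if (ncol(y) != ncol(reg))
    stop("time series and nuisance regressors differ in timepoints")
  x <- cbind(intercept = 1, t(reg))
  qx <- qr(x)
  dropped <- character(0)
  if (qx$rank < ncol(x)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(x)[setdiff(seq_len(ncol(x)), keep)]
    warning("dropping collinear nuisance regressors: ",
            paste(dropped, collapse = ", "))
    x <- x[, keep, drop = FALSE]
    qx <- qr(x)
  }
  resid <- t(qr.resid(qx, t(y)))
  prov <- list(steps = "nuisance_regression",
               regressors_used = colnames(x),
               regressors_dropped = dropped)
  new_clean_series(resid, ts, prov)
}

new_clean_series <- function(data, parent, prov_entry) {
  prov <- if (inherits(parent, "clean_series"))
    c(parent$provenance, list(prov_entry)) else list(prov_entry)
  structure(list(data = data,
                 tr_seconds = if (is.list(parent)) parent$tr_seconds else NULL,
                 roi = if (is.list(parent)) parent$roi else NULL,
                 provenance = prov),
            class = "clean_series")
}

#' @export
print.clean_series <- function(x, ...) {
  steps <- vapply(x$provenance, function(p) p$steps, character(1))
  cat("Clean series:", nrow(x$data), "voxels x", ncol(x$data),
      "timepoints | steps:", paste(steps, collapse = " -> "), "\n")
  invisible(x)
}

#' Prewhiten voxel time series
#'
#' Removes temporal autocorrelation per voxel by fitting an autoregressive
#' model of order `ar_order` (Yule-Walker) and residualizing. The first
#' `ar_order` timepoints are dropped so all voxels keep a common length.
#' Constant (zero-variance) voxels are returned as zeros with a warning.
#'
#' @param ts A `clean_series`, `bold_series` or matrix.
#' @param ar_order Autoregressive order (default 1).
#' @return A `clean_series` of the prewhitened residuals.
#' @export
prewhiten <- function(ts, ar_order = 1L) {
  y <- series_matrix(ts)
  n_t <- ncol(y)
  if (n_t <= 10 * ar_order)
    stop("need more than 10 x ar_order timepoints")
  out <- matrix(0, nrow(y), n_t - ar_order)
  sds <- apply(y, 1, stats::sd)
  degenerate <- sds < .Machine$double.eps * 100
  if (ar_order == 1L) {
    # closed-form Yule-Walker for AR(1): phi = lag-1 autocovariance ratio
    xc <- y - rowMeans(y)
    c0 <- rowSums(xc^2)
    c1 <- rowSums(xc[, -1, drop = FALSE] * xc[, -n_t, drop = FALSE])
    phi <- ifelse(c0 > 0, c1 / c0, 0)
    out <- xc[, -1, drop = FALSE] - phi * xc[, -n_t, drop = FALSE]
    out[degenerate, ] <- 0
  } else {
    for (i in seq_len(nrow(y))) {
      if (degenerate[i]) next
      v <- y[i, ]
      fit <- stats::ar.yw(v, aic = FALSE, order.max = ar_order, demean = TRUE)
      res <- v[(ar_order + 1):n_t] - mean(v)
      for (k in seq_len(ar_order))
        res <- res - fit$ar[k] * (v[(ar_order + 1 - k):(n_t - k)] - mean(v))
      out[i, ] <- res
    }
  }
  if (any(degenerate))
    warning("constant voxel series encountered; returned as zeros")
  new_clean_series(out, ts, list(steps = "prewhiten", ar_order = ar_order))
}


# direct-form IIR applied along the rows of a matrix (zero initial state)
iir_rows <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  n_t <- ncol(x)
  y <- matrix(0, nrow(x), n_t)
  nb <- length(b)
  na_ <- length(a)
  for (t in seq_len(n_t)) {
    acc <- b[1] * x[, t]
    if (nb > 1 && t > 1)
      for (k in 2:min(nb, t)) acc <- acc + b[k] * x[, t - k + 1]
    if (na_ > 1 && t > 1)
      for (k in 2:min(na_, t)) acc <- acc - a[k] * y[, t - k + 1]
    y[, t] <- acc
  }
  y
}

# forward-backward (zero-phase) filtering of every row, matching the
# pad-with-zeros forward/reverse scheme of signal::filtfilt
filtfilt_rows <- function(b, a, x) {
  n_t <- ncol(x)
  pad <- 2 * max(length(a), length(b))
  y <- iir_rows(b, a, cbind(x, matrix(0, nrow(x), pad)))
  y <- iir_rows(b, a, y[, rev(seq_len(ncol(y))), drop = FALSE])
  y[, rev(seq_len(ncol(y))), drop = FALSE][, seq_len(n_t), drop = FALSE]
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-lag) Butterworth band-pass filtering of every voxel
#' series, selecting the low-frequency resting-state band (default
#' 0.01-0.09 Hz).
#'
#' @param ts A `clean_series`, `bold_series` or matrix.
#' @param low_hz,high_hz Band edges in Hz.
#' @param tr_seconds Sampling interval; taken from the series if `NULL`.
#' @param order Butterworth design order (default 2, i.e. a 4th-order
#'   band-pass; forward-backward application squares the magnitude response).
#' @return A `clean_series` of zero-mean band-limited rows.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.09, tr_seconds = NULL,
                     order = 2L) {
  y <- series_matrix(ts)
  if (is.null(tr_seconds)) tr_seconds <- ts$tr_seconds
  if (is.null(tr_seconds)) stop("tr_seconds must be supplied")
  nyq <- 1 / (2 * tr_seconds)
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- filtfilt_rows(bf$b, bf$a, y - rowMeans(y))
  new_clean_series(out, ts,
                   list(steps = "bandpass", band_hz = c(low_hz, high_hz),
                        order = order, tr_seconds = tr_seconds))
}

#' Full preprocessing chain for one dataset
#'
#' Applies the standard chain: discard initial volumes, nuisance regression,
#' prewhitening, zero-phase band-pass. The order of the cleaning steps is
#' recorded in the provenance and is configurable, since reordering
#' regression and filtering changes the result.
#'
#' @param bold A `bold_series`.
#' @param nuis A `nuisance_set` matched to `bold`.
#' @param discard Leading volumes to drop (default 2).
#' @param ar_order AR order for prewhitening (default 1; 0 skips).
#' @param band Band edges in Hz (default `c(0.01, 0.09)`).
#' @param order Order of the cleaning steps (any permutation of
#'   `"regress"`, `"prewhiten"`, `"bandpass"`).
#' @return A `clean_series`.
#' @export
preprocess_series <- function(bold, nuis, discard = 2L, ar_order = 1L,
                              band = c(0.01, 0.09),
                              order = c("regress", "prewhiten", "bandpass")) {
  stopifnot(all(order %in% c("regress", "prewhiten", "bandpass")))
  ts <- discard_initial_volumes(bold, discard)
  reg <- nuis$regressors
  if (discard > 0) reg <- reg[, -(seq_len(discard)), drop = FALSE]
  nuis_t <- structure(list(regressors = reg), class = "nuisance_set")
  for (step in order) {
    ts <- switch(step,
      regress = {
        # regressors must track any timepoints dropped by earlier steps
        reg_cur <- nuis_t$regressors
        if (ncol(reg_cur) > ncol(series_matrix(ts)))
          reg_cur <- reg_cur[, (ncol(reg_cur) - ncol(series_matrix(ts)) + 1):ncol(reg_cur),
                             drop = FALSE]
        nuisance_regression(ts, reg_cur)
      },
      prewhiten = if (ar_order > 0) prewhiten(ts, ar_order) else ts,
      bandpass = bandpass(ts, band[1], band[2],
                          tr_seconds = bold$tr_seconds)
    )
  }
  ts$provenance <- c(ts$provenance,
                     list(list(steps = "chain", order = order,
                               discarded = discard)))
  ts
}
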