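#' @importFrom stats rnorm runif sd cor quantile
NULL

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Counter-based fan-out so that per-stage, per-subject and per-replicate
#' random streams are decoupled yet fully determined by one master seed.
#'
#' @param master Master integer seed.
#' @param ... Further integer keys (stage id, subject index, replicate, ...).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
seed_for <- function(master, ...) {
  keys <- c(as.double(master), vapply(list(...), as.double, double(1)))
  x <- 0
  for (k in keys) x <- (x * 69069 + k + 1) %% 2147483647
  as.integer(x %% 2147483646) + 1L
}

#' Specify a plantable connectivity effect
#'
#' Describes ground-truth network alterations injected by the generator:
#' `"local_coupling"` mixes one shared band-limited latent into a target
#' subregion, raising expected pairwise correlation there by about
#' `coupling_delta` (the synthetic analogue of a local-connectedness increase);
#' `"long_range"` gives each target voxel a latent shared with distal partner
#' voxels, creating shortcut edges that reduce path length.
#'
#' @param kind `"none"`, `"local_coupling"` or `"long_range"`.
#' @param target_voxels Integer indices (into the ROI voxel list) receiving
#'   the effect.
#' @param coupling_delta Correlation-scale effect size in `[0, 1)`.
#' @param n_shortcut_partners Size of the compact distal partner region with
#'   which every target voxel shares a shortcut latent (long-range kind
#'   only).
#' @param baseline_rho Optional correlation in `[0, 1]` linking per-subject
#'   effect size to the subject's baseline coupling (used by
#'   [simulate_study()] to plant baseline dependence).
#' @param saturate If `TRUE`, a requested `coupling_delta` that would push
#'   model correlations past a synchrony ceiling (mean target correlation
#'   0.92) is capped at the ceiling instead of raising an error; used for
#'   study simulation, where per-subject baselines vary.
#' @param decoupling For local coupling: fraction of the injected latent that
#'   is a new independent source rather than an amplification of the
#'   region's own coherent signal. 0 purely strengthens existing shared
#'   structure (surround correlations preserved); 1 adds a fully new source
#'   (surround correlations shed as the target synchronizes internally).
#'   Intermediate values trade added connections against shed ones, so the
#'   target's degree can stay balanced while its local clustering rises.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(kind = c("none", "local_coupling", "long_range"),
                        target_voxels = integer(0), coupling_delta = 0,
                        n_shortcut_partners = 3L, baseline_rho = NULL,
                        decoupling = 0, saturate = FALSE) {
  kind <- match.arg(kind)
  if (coupling_delta < 0 || coupling_delta >= 1)
    stop("coupling_delta must lie in [0, 1)")
  if (kind == "none" && coupling_delta != 0)
    stop("kind = 'none' requires coupling_delta = 0")
  if (kind != "none" && !length(target_voxels))
    stop("an active effect needs target_voxels")
  if (decoupling < 0 || decoupling > 1)
    stop("decoupling must lie in [0, 1]")
  structure(list(kind = kind,
                 target_voxels = as.integer(target_voxels),
                 coupling_delta = coupling_delta,
                 n_shortcut_partners = as.integer(n_shortcut_partners),
                 baseline_rho = baseline_rho,
                 decoupling = decoupling,
                 saturate = isTRUE(saturate)),
            class = "effect_spec")
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("Effect:", x$kind)
  if (x$kind != "none")
    cat(" | delta =", x$coupling_delta, "| targets =", length(x$target_voxels))
  cat("\n")
  invisible(x)
}

#' Define a crossed stimulation study design
#'
#' A fully crossed subjects x sessions x times resting-state design. Sham
#' cells and all pre-stimulation cells carry no planted effect; effects are
#' attached to (session, time) cells by name, e.g. `"cathodal.after"`.
#'
#' @param n_subjects Number of subjects (default 14).
#' @param sessions Stimulation sessions (default anodal, cathodal, sham).
#' @param times Measurement times per session (default before, after).
#' @param effects Named list of effect templates (see [simulate_study()]),
#'   names of the form `"<session>.<time>"`. Only non-sham `"after"` cells
#'   may carry an active effect.
#' @param subject_baseline Optional list `list(delta_range = c(lo, hi))`
#'   giving per-subject baseline local-coupling heterogeneity on the target
#'   region (applied identically in every cell of a subject).
#' @param seed Master seed for the study.
#' @return A `study_design` object.
#' @export
study_design <- function(n_subjects = 14L,
                         sessions = c("anodal", "cathodal", "sham"),
                         times = c("before", "after"),
                         effects = list(),
                         subject_baseline = NULL,
                         seed = 1L) {
  cells <- as.vector(outer(sessions, times, paste, sep = "."))
  for (nm in names(effects)) {
    if (!nm %in% cells) stop("effect cell '", nm, "' not in design")
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (parts[1] == "sham" || parts[2] == times[1])
      stop("sham and pre-stimulation cells must carry no effect: ", nm)
  }
  structure(list(n_subjects = as.integer(n_subjects), sessions = sessions,
                 times = times, effects = effects,
                 subject_baseline = subject_baseline, seed = as.integer(seed)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", x$n_subjects, "subjects x",
      length(x$sessions), "sessions x", length(x$times), "times =",
      x$n_subjects * length(x$sessions) * length(x$times), "datasets\n")
  if (length(x$effects))
    cat("  effect cells:", paste(names(x$effects), collapse = ", "), "\n")
  invisible(x)
}

# sum of unit-variance sinusoids with random frequencies in [f_lo, f_hi]
band_limited_latent <- function(n_t, tr, n_freqs = 6L,
                                f_lo = 0.01, f_hi = 0.09) {
  t_sec <- (seq_len(n_t) - 1) * tr
  f <- runif(n_freqs, f_lo, f_hi)
  ph <- runif(n_freqs, 0, 2 * pi)
  z <- rowSums(vapply(seq_len(n_freqs),
                      function(k) sin(2 * pi * f[k] * t_sec + ph[k]),
                      double(n_t)))
  z * sqrt(2 / n_freqs)
}

# AR(1) noise with unit marginal variance
ar1_noise <- function(n, n_t, phi = 0.3) {
  eps <- matrix(rnorm(n * n_t), n, n_t)
  out <- t(apply(eps, 1, function(e) stats::filter(e, phi, method = "recursive")))
  out * sqrt(1 - phi^2)
}

# smooth random-walk motion trace scaled to a target rms
motion_trace <- function(n_t, rms_target) {
  w <- cumsum(rnorm(n_t, 0, 1))
  w <- as.numeric(stats::filter(w, rep(1 / 5, 5), sides = 2))
  w[is.na(w)] <- 0
  r <- sqrt(mean(w^2))
  if (r < .Machine$double.eps) return(rep(0, n_t))
  w * rms_target / r
}

#' Simulate one resting-state session for an ROI
#'
#' Generates a voxels x timepoints BOLD-like series as a mixture of spatially
#' correlated band-limited latent signals (0.01-0.09 Hz sinusoid sums, with
#' exponential spatial decay of shared variance), AR(1) voxel noise, and nine
#' nuisance components (six motion traces, WM, CSF and global signals) that
#' are also returned as regressors. Connectivity effects are planted by
#' analytically calibrated latent mixing so that the expected correlation
#' increase equals the requested `coupling_delta`.
#'
#' @param roi An `roi_mask`.
#' @param effect An `effect_spec` (default none).
#' @param n_timepoints Number of volumes (default 175).
#' @param tr_seconds Sampling interval in seconds (default 1.8).
#' @param noise_sd White/AR(1) noise amplitude relative to unit-variance
#'   shared signal (default 1).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param n_freqs Sinusoids per latent signal.
#' @param spatial_scale Exponential decay length of shared variance, in voxel
#'   units (default 2; `Inf` collapses the field to a single latent signal).
#' @param nuisance_amplitude Scale of nuisance contamination mixed into the
#'   data (0 disables contamination; the regressors are still returned).
#' @param motion_rms Typical rms of the motion traces (mm / degrees).
#' @param qc_fail If `TRUE`, one translation trace is scaled to 1.5 mm rms to
#'   exercise the motion-exclusion rule.
#' @param baseline_effect Optional second `effect_spec` applied before
#'   `effect` (per-subject baseline coupling in study simulations).
#' @param n_latents Number of latent band-limited signals (anchored at
#'   voxels spread over the ROI and orthonormalized within the session;
#'   capped by the ROI size and the series length).
#' @param amp_jitter_sd Log-scale standard deviation of per-session,
#'   per-voxel signal amplitude jitter, emulating scan-to-scan SNR
#'   variation (0 disables).
#' @param hub_region Optional list `list(voxels, strength)` (or a list of
#'   such lists): stable, strongly coupled subregions built into the base
#'   architecture (the ROI's dominant hub, per-subject baseline coupling),
#'   present identically in every session of a subject. `strength` is the
#'   pre-normalization weight of the shared regional latent (default 1).
#' @return A list with elements `bold` (a `bold_series`), `nuisance` (a
#'   `nuisance_set`) and `truth` (planted-effect ground truth).
#' @export
simulate_session <- function(roi, effect = effect_spec("none"),
                             n_timepoints = 175L, tr_seconds = 1.8,
                             noise_sd = 1, seed = 1L, n_freqs = 16L,
                             spatial_scale = 2, nuisance_amplitude = 1,
                             motion_rms = 0.25, qc_fail = FALSE,
                             baseline_effect = NULL, n_latents = 40L,
                             amp_jitter_sd = 0.3, hub_region = NULL) {
  stopifnot(inherits(roi, "roi_mask"))
  if (n_timepoints < 50) stop("n_timepoints must be at least 50")
  if (length(effect$target_voxels) &&
      (min(effect$target_voxels) < 1 || max(effect$target_voxels) > roi$n_voxels))
    stop("effect target_voxels outside the ROI")
  n <- roi$n_voxels
  n_t <- as.integer(n_timepoints)

  n_latents <- min(n, n_latents, n_t - 12L)
  anchors <- unique(round(seq(1, n, length.out = n_latents)))
  n_latents <- length(anchors)
  coupled_list <- if (is.null(hub_region)) list()
    else if (!is.null(hub_region$voxels)) list(hub_region)
    else hub_region
  n_z <- n_latents + length(coupled_list)
  with_seed(seed, {
    # --- shared band-limited field with exponential spatial decay ---------
    # Latents sit at anchor voxels spread over the ROI; each is a sum of
    # band-limited sinusoids, and the latent basis is orthonormalized within
    # the session so the field's correlation structure is set by the mixing
    # weights rather than by finite-sample overlap of the sinusoids. This
    # gives the session-to-session stability of connectivity seen in
    # test-retest resting-state data.
    z <- t(vapply(seq_len(n_z), function(i)
      band_limited_latent(n_t, tr_seconds, n_freqs), double(n_t)))
    qz <- qr(cbind(1, t(z)))
    z <- t(qr.Q(qz)[, 2:(n_z + 1L), drop = FALSE]) * sqrt(n_t)
    if (is.infinite(spatial_scale)) {
      w <- matrix(1 / sqrt(n_latents), n, n_latents)
    } else {
      ac <- roi$coords[anchors, , drop = FALSE]
      d2 <- outer(rowSums(roi$coords^2), rep(1, n_latents)) -
        2 * roi$coords %*% t(ac) +
        outer(rep(1, n), rowSums(ac^2))
      w <- exp(-sqrt(pmax(d2, 0)) / spatial_scale)
    }
    for (reg in coupled_list) {
      # architectural coupling: one extra shared latent loaded only on the
      # region's voxels, identical in structure every session (used for the
      # stable dominant hub and for per-subject baseline coupling)
      wh <- rep(0, n)
      wh[reg$voxels] <- reg$strength %||% 1
      w <- cbind(w, wh)
    }
    w <- w / sqrt(rowSums(w^2))
    field <- w %*% z

    # model correlation matrix of signal+noise (unit-variance voxels)
    # per-session voxel signal-amplitude jitter (scan-to-scan SNR variation
    # from repositioning, field inhomogeneity and coil sensitivity); the
    # gain field is spatially smooth, like its physical sources
    amp <- if (amp_jitter_sd > 0) {
      gain_field <- as.vector(w[, seq_len(n_latents), drop = FALSE] %*%
                              rnorm(n_latents))
      exp(amp_jitter_sd * gain_field)
    } else rep(1, n)
    sdv <- sqrt(amp^2 + noise_sd^2)
    r_model <- (outer(amp, amp) * (w %*% t(w))) / outer(sdv, sdv)
    diag(r_model) <- 1

    noise <- if (noise_sd > 0) ar1_noise(n, n_t) else matrix(0, n, n_t)
    x <- (amp * field + noise_sd * noise) / sdv

    # --- nuisance components ---------------------------------------------
    t_sec <- (seq_len(n_t) - 1) * tr_seconds
    mot <- t(vapply(seq_len(6), function(k)
      motion_trace(n_t, runif(1, 0.4, 1) * motion_rms), double(n_t)))
    if (qc_fail) mot[1, ] <- motion_trace(n_t, 1.5)
    drift <- 0.6 * sin(2 * pi * 0.004 * t_sec + runif(1, 0, 2 * pi)) +
      0.4 * (t_sec - mean(t_sec)) / max(t_sec)
    wm <- 0.7 * band_limited_latent(n_t, tr_seconds, n_freqs) + 0.4 * drift
    csf <- 0.7 * band_limited_latent(n_t, tr_seconds, n_freqs) + 0.4 * drift
    # the global signal tracks the actual common mode of the generated data
    # (as when averaging over all brain voxels) plus extra-ROI background
    x_common <- colMeans(x)
    x_common <- x_common / max(stats::sd(x_common), .Machine$double.eps)
    glob <- 0.55 * x_common +
      0.45 * band_limited_latent(n_t, tr_seconds, n_freqs) + 0.6 * drift
    if (nuisance_amplitude > 0) {
      load_m <- matrix(rnorm(n * 6, 0, 0.08), n, 6)
      x <- x + nuisance_amplitude * (
        0.35 * outer(rep(1, n), glob) +
        load_m %*% mot +
        0.15 * outer(rnorm(n), wm) +
        0.15 * outer(rnorm(n), csf) +
        0.30 * outer(rep(1, n), drift))
    }

    # --- planted effects (drawn last so the base field is seed-stable) ----
    truth <- list(effect = effect, beta2 = NA_real_, partners = NULL,
                  baseline_beta2 = NA_real_)
    # Local coupling amplifies the target region's own coherent latent
    # signal u (the normalized mean field over the target).  This raises
    # within-target correlations by the calibrated delta while largely
    # preserving target-to-outside correlations (u itself correlates with
    # nearby outside voxels), mimicking a strengthening of existing local
    # connections rather than the appearance of a new independent source.
    # Long-range coupling is the same mechanism applied to the union of the
    # target and a compact distal partner region, so that shortcut
    # correlations arise between the two while degrees stay balanced.
    lr_partners <- NULL
    if (effect$kind == "long_range") {
      st <- effect$target_voxels
      ctr <- colMeans(roi$coords[st, , drop = FALSE])
      d_ctr <- sqrt(rowSums(sweep(roi$coords, 2, ctr)^2))
      pool <- setdiff(order(d_ctr, decreasing = TRUE),
                      c(st, if (!is.null(hub_region)) hub_region$voxels))
      lr_partners <- pool[seq_len(min(effect$n_shortcut_partners,
                                      length(pool)))]
    }
    eff_targets <- unique(c(
      if (!is.null(baseline_effect)) baseline_effect$target_voxels,
      if (effect$kind == "local_coupling") effect$target_voxels,
      if (effect$kind == "long_range") c(effect$target_voxels, lr_partners)))
    if (length(eff_targets)) {
      wbar <- colMeans(w[eff_targets, , drop = FALSE])
      v_e <- sum(wbar^2)
      u_sig <- as.vector(wbar %*% z) / sqrt(v_e)
      # model covariances of u with every voxel (unit-variance scale)
      c_u <- amp * as.vector(w %*% wbar) / (sqrt(v_e) * sdv)
    }
    apply_local <- function(x, s, delta, decoupling = 0, saturate = FALSE) {
      # injected latent: mixture of the region's own coherent signal u and
      # a fresh independent source, per the decoupling fraction
      alpha <- sqrt(1 - decoupling^2)
      u_mix <- alpha * u_sig +
        decoupling * band_limited_latent(n_t, tr_seconds, n_freqs)
      c_mix <- alpha * c_u
      sbar <- mean(r_model[s, s][upper.tri(r_model[s, s], diag = FALSE)])
      ut <- upper.tri(diag(length(s)))
      # mixing x_i' = (sqrt(1-b) x_i + sqrt(b) u_mix) / norm_i, with norm_i
      # restoring unit variance (u_mix is correlated with the target voxels)
      mean_corr <- function(b) {
        g <- sqrt(b * (1 - b))
        nrm <- sqrt(1 + 2 * g * c_mix[s])
        cv <- (1 - b) * r_model[s, s] + b + g * outer(c_mix[s], c_mix[s], `+`)
        cr <- cv / outer(nrm, nrm)
        mean(cr[ut])
      }
      gain <- function(b) mean_corr(b) - sbar - delta
      if (gain(0.999) < 0) {
        if (!saturate)
          stop("coupling_delta pushes model correlations above 1")
        # biological ceiling: cap the rise so mean target correlation
        # stays at or below 0.92
        if (sbar >= 0.92) {
          b <- 0
        } else if (mean_corr(0.999) <= 0.92) {
          b <- 0.999
        } else {
          b <- stats::uniroot(function(b) mean_corr(b) - 0.92,
                              c(0, 0.999), tol = 1e-10)$root
        }
      } else {
        b <- stats::uniroot(gain, c(0, 0.999), tol = 1e-10)$root
      }
      g <- sqrt(b * (1 - b))
      nrm <- sqrt(1 + 2 * g * c_mix[s])
      x[s, ] <- (sqrt(1 - b) * x[s, , drop = FALSE] +
                 sqrt(b) * matrix(u_mix, length(s), n_t, byrow = TRUE)) / nrm
      # exact covariance update for any subsequent effect
      r_ss <- ((1 - b) * r_model[s, s] + b +
               g * outer(c_mix[s], c_mix[s], `+`)) / outer(nrm, nrm)
      r_so <- (sqrt(1 - b) * r_model[s, -s, drop = FALSE] +
               sqrt(b) * matrix(c_mix[-s], length(s), n - length(s),
                                byrow = TRUE)) / nrm
      r_model[s, s] <<- r_ss
      r_model[s, -s] <<- r_so
      r_model[-s, s] <<- t(r_so)
      diag(r_model) <<- 1
      c_u[s] <<- (sqrt(1 - b) * c_u[s] + sqrt(b) * alpha) / nrm
      list(x = x, beta2 = b)
    }
    if (!is.null(baseline_effect) && baseline_effect$kind == "local_coupling" &&
        baseline_effect$coupling_delta > 0) {
      res <- apply_local(x, baseline_effect$target_voxels,
                         baseline_effect$coupling_delta,
                         saturate = baseline_effect$saturate %||% FALSE)
      x <- res$x
      truth$baseline_beta2 <- res$beta2
    }
    if (effect$kind == "local_coupling") {
      res <- apply_local(x, effect$target_voxels, effect$coupling_delta,
                         decoupling = effect$decoupling %||% 0,
                         saturate = effect$saturate %||% FALSE)
      x <- res$x
      truth$beta2 <- res$beta2
    } else if (effect$kind == "long_range") {
      res <- apply_local(x, c(effect$target_voxels, lr_partners),
                         effect$coupling_delta,
                         decoupling = effect$decoupling %||% 0,
                         saturate = effect$saturate %||% FALSE)
      x <- res$x
      truth$beta2 <- res$beta2
      truth$partners <- lr_partners
    }

    data <- 1000 + 30 * x
    bold <- structure(list(data = data, tr_seconds = tr_seconds, roi = roi),
                      class = "bold_series")
    reg <- rbind(mot, wm = wm, csf = csf, global = glob)
    rownames(reg) <- c(paste0("motion", 1:6), "wm", "csf", "global")
    nuis <- structure(list(regressors = reg), class = "nuisance_set")
    list(bold = bold, nuisance = nuis, truth = truth)
  })
}

#' @export
print.bold_series <- function(x, ...) {
  cat("BOLD series:", nrow(x$data), "voxels x", ncol(x$data),
      "volumes, TR =", x$tr_seconds, "s\n")
  invisible(x)
}

#' @export
print.nuisance_set <- function(x, ...) {
  cat("Nuisance set:", nrow(x$regressors), "regressors x",
      ncol(x$regressors), "timepoints\n")
  invisible(x)
}

# voxels nearest the ROI centroid (the shared target-selection rule)
central_voxels <- function(roi, n_target) {
  ctr <- colMeans(roi$coords)
  d2 <- rowSums(sweep(roi$coords, 2, ctr)^2)
  order(d2)[seq_len(n_target)]
}

#' Simulate a full multi-subject stimulation study
#'
#' Generates one (BOLD, nuisance) pair per design cell per subject. Each
#' subject gets a fresh ROI (subject-specific seed) and, optionally, a random
#' baseline coupling level on the central target region that is shared across
#' all of that subject's cells. Effect templates in the design are
#' instantiated per subject; a template with `baseline_rho` plants a
#' correlation of that size between per-subject effect amplitude and baseline
#' coupling.
#'
#' Effect templates are lists with fields `kind`, `delta`, `n_target`
#' (voxel count of the central target region), and optionally
#' `n_shortcut_partners`, `baseline_rho`, `effect_cv`.
#'
#' @param design A `study_design`.
#' @param roi_params List of arguments for [make_roi()] (defaults: 470-voxel
#'   slab on a 3 mm lattice).
#' @param session_params List of arguments for [simulate_session()]
#'   (timepoints, TR, noise, ...).
#' @param hub List `list(n_voxels, strength)` describing the stable dominant
#'   hub region built into every session (`NULL` disables it). The hub sits
#'   off-centre along the ROI's longest axis, clear of the central target.
#' @return A `study_data` object: list of dataset records (`subject`,
#'   `session`, `time`, `bold`, `nuisance`, `truth`) plus per-subject ROIs,
#'   target voxel sets and ground-truth labels.
#' @export
simulate_study <- function(design,
                           roi_params = list(n_voxels = 470L, shape = "slab",
                                             voxel_size_mm = 3),
                           session_params = list(),
                           hub = list(n_voxels = 30L, strength = 1)) {
  stopifnot(inherits(design, "study_design"))
  master <- design$seed
  ns <- design$n_subjects

  rois <- lapply(seq_len(ns), function(s)
    do.call(make_roi, c(roi_params, list(seed = seed_for(master, 1L, s)))))

  n_target_default <- max(vapply(design$effects, function(e)
    as.integer(e$n_target %||% 40L), integer(1)), 40L)
  targets <- lapply(rois, central_voxels, n_target = n_target_default)

  # the stable dominant hub sits off-centre along the ROI's longest axis,
  # clear of the central target region
  hubs <- if (is.null(hub)) vector("list", ns) else lapply(seq_len(ns),
    function(s) {
      roi <- rois[[s]]
      ext <- apply(roi$coords, 2, function(v) diff(range(v)))
      ax <- which.max(ext)
      ctr <- colMeans(roi$coords)
      ctr[ax] <- ctr[ax] + 0.35 * ext[ax]
      d2 <- rowSums(sweep(roi$coords, 2, ctr)^2)
      cand <- setdiff(order(d2), targets[[s]])
      list(voxels = cand[seq_len(min(hub$n_voxels, length(cand)))],
           strength = hub$strength %||% 1)
    })

  # per-subject baseline coupling (identical in every cell of the subject);
  # either latent-mixing ("delta_range", correlation scale) or architectural
  # ("strength_range", a per-subject weight column in the mixing matrix)
  bl <- design$subject_baseline
  bl_mode <- if (!is.null(bl$strength_range)) "architectural" else "mixing"
  b_s <- if (!is.null(bl)) {
    rng <- if (bl_mode == "architectural") bl$strength_range else bl$delta_range
    with_seed(seed_for(master, 2L), runif(ns, rng[1], rng[2]))
  } else rep(0, ns)
  z_s <- if (ns > 1 && stats::sd(b_s) > 0)
    (b_s - mean(b_s)) / stats::sd(b_s) else rep(0, ns)

  # per-subject effect amplitudes, optionally coupled to baseline
  amp <- list()
  for (nm in names(design$effects)) {
    tpl <- design$effects[[nm]]
    rho <- tpl$baseline_rho %||% 0
    cv <- tpl$effect_cv %||% (if (rho > 0) 0.4 else 0)
    eps <- with_seed(seed_for(master, 3L, which(names(design$effects) == nm)),
                     rnorm(ns))
    mix <- rho * z_s + sqrt(max(0, 1 - rho^2)) * eps
    delta_s <- tpl$delta * pmax(0.05, 1 + cv * mix)
    amp[[nm]] <- pmin(delta_s, 0.8)
  }

  datasets <- list()
  idx <- 0L
  for (s in seq_len(ns)) {
    baseline_eff <- if (b_s[s] > 0 && bl_mode == "mixing")
      effect_spec("local_coupling", target_voxels = targets[[s]],
                  coupling_delta = b_s[s], saturate = TRUE) else NULL
    regions <- c(if (!is.null(hubs[[s]])) list(hubs[[s]]),
                 if (b_s[s] > 0 && bl_mode == "architectural")
                   list(list(voxels = targets[[s]], strength = b_s[s])))
    for (sess in design$sessions) {
      for (tm in design$times) {
        idx <- idx + 1L
        cell <- paste(sess, tm, sep = ".")
        tpl <- design$effects[[cell]]
        eff <- if (is.null(tpl)) effect_spec("none") else
          effect_spec(tpl$kind, target_voxels = targets[[s]],
                      coupling_delta = amp[[cell]][s],
                      n_shortcut_partners = as.integer(tpl$n_shortcut_partners %||% 3L),
                      decoupling = tpl$decoupling %||% 0,
                      saturate = TRUE)
        args <- c(list(roi = rois[[s]], effect = eff,
                       seed = seed_for(master, 4L, s,
                                       match(sess, design$sessions),
                                       match(tm, design$times)),
                       baseline_effect = baseline_eff,
                       hub_region = if (length(regions)) regions else NULL),
                  session_params)
        out <- do.call(simulate_session, args)
        datasets[[idx]] <- list(subject = s, session = sess, time = tm,
                                bold = out$bold, nuisance = out$nuisance,
                                truth = out$truth)
      }
    }
  }
  structure(list(datasets = datasets, design = design, rois = rois,
                 targets = targets, hubs = hubs, baseline_coupling = b_s,
                 effect_amplitudes = amp),
            class = "study_data")
}

#' @export
print.study_data <- function(x, ...) {
  cat("Synthetic study:", length(x$datasets), "datasets (",
      x$design$n_subjects, "subjects )\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
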