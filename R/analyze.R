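#' Per-dataset maps and global metrics for a whole study
#'
#' Runs the dataset-level half of the pipeline on a simulated (or otherwise
#' assembled) study: preprocessing, synchronization matrices, the percolation
#' threshold scan, the common group threshold, largest-component graphs,
#' null normalization and smoothed nodal maps.
#'
#' @param study A `study_data` object (datasets with `bold` and `nuisance`).
#' @param config A `run_config`; only the `preprocess`, `netbuild`, `nulls`
#'   and `maps` sections are used.
#' @return A list: `meta` (design table), `roi`, `t_maxes`, `t_common`,
#'   `graphs`, `null_summaries`, `maps` (per dataset, named metric maps),
#'   `values` (per metric, datasets x voxels matrices) and `global`
#'   (per-dataset `global_metrics`).
#' @export
study_maps <- function(study, config = default_config()) {
  roi <- study$rois[[1]]
  nd <- length(study$datasets)
  clean <- lapply(study$datasets, function(d)
    preprocess_series(d$bold, d$nuisance,
                      discard = config$preprocess$discard,
                      ar_order = config$preprocess$ar_order,
                      band = config$preprocess$band,
                      order = config$preprocess$order))
  mats <- lapply(clean, correlation_matrix)
  scans <- lapply(mats, scan_tmax, t0 = config$netbuild$t0,
                  step = config$netbuild$step,
                  criterion = config$netbuild$criterion)
  t_maxes <- vapply(scans, function(s) s$T_max, double(1))
  t_common <- group_common_threshold(t_maxes)

  graphs <- vector("list", nd)
  nullsums <- vector("list", nd)
  maps <- vector("list", nd)
  glob <- vector("list", nd)
  for (i in seq_len(nd)) {
    g <- restrict_to_largest(threshold_graph(mats[[i]], t_common))
    graphs[[i]] <- g
    nullsums[[i]] <- if (config$nulls$method == "theoretical") {
      theoretical_null(g$n_nodes, mean(nodal_degree(g)))
    } else {
      null_ensemble(g, n_replicates = config$nulls$n_replicates,
                    seed = seed_for(config$seed, 5L, i),
                    swap_factor = config$nulls$swap_factor)
    }
    maps[[i]] <- nodal_maps(g, roi, nullsums[[i]],
                            fwhm_mm = config$maps$fwhm_mm)
    glob[[i]] <- global_metrics(g, nullsums[[i]])
  }
  meta <- data.frame(
    subject = vapply(study$datasets, `[[`, integer(1), "subject"),
    session = vapply(study$datasets, `[[`, character(1), "session"),
    time = vapply(study$datasets, `[[`, character(1), "time"))
  values <- lapply(c(K_norm = "K_norm", C_norm = "C_norm", L_norm = "L_norm"),
                   function(m) do.call(rbind, lapply(maps, function(x)
                     x[[m]]$values)))
  list(meta = meta, roi = roi, t_maxes = t_maxes, t_common = t_common,
       graphs = graphs, null_summaries = nullsums, maps = maps,
       values = values, global = glob)
}

#' Planted-effect recovery experiment
#'
#' Simulates a before/after study for one stimulation session with a planted
#' connectivity effect, runs the full dataset-level pipeline, applies the
#' after-minus-before paired contrast with Monte-Carlo cluster correction to
#' each metric map, and scores recovery of the planted target (Dice overlap
#' of the best surviving cluster with the target voxels).
#'
#' @param kind `"local_coupling"` (clustering-coefficient effect),
#'   `"long_range"` (path-length effect) or `"none"` (specificity run).
#' @param n_subjects Number of subjects (default 14).
#' @param roi_n ROI size in voxels.
#' @param n_target Target-region size in voxels.
#' @param delta Planted correlation-scale effect size (default 0.15 for
#'   local coupling, 0.45 for the long-range shortcut effect).
#' @param n_timepoints Volumes per dataset.
#' @param n_permutations Permutations for cluster correction.
#' @param cluster_forming_p Uncorrected cluster-forming threshold for the
#'   recovery contrasts (default 0.01, the stricter forming threshold
#'   recommended for smoothed-map cluster inference).
#' @param seed Master seed.
#' @param baseline_range Per-subject baseline coupling range on the target
#'   region (the target is a pre-existing functional module; the planted
#'   effect strengthens it further). `NULL` disables baseline coupling.
#' @param n_shortcut_partners Distal partner-region size for long-range
#'   effects.
#' @param decoupling Decoupling fraction of the planted effect (default 0.7
#'   local, 0.45 long-range); see [effect_spec()].
#' @param noise_sd Session noise level.
#' @param config_overrides Named list merged into [default_config()].
#' @return List with per-metric cluster tables, Dice overlap of the best
#'   surviving cluster per metric, `t_common` and the target voxel set.
#' @export
effect_recovery_study <- function(kind = "local_coupling", n_subjects = 14L,
                                  roi_n = 300L, n_target = 40L, delta = NULL,
                                  n_timepoints = 175L, n_permutations = 1000L,
                                  cluster_forming_p = 0.01,
                                  seed = 1L, baseline_range = c(0.08, 0.18),
                                  n_shortcut_partners = 60L, decoupling = NULL,
                                  noise_sd = 0.45,
                                  config_overrides = list()) {
  # effect-size defaults per kind: a 0.15 correlation increase for the
  # cathodal-like local effect; a stronger 0.45 shared-latent coupling for
  # the anodal-like shortcut effect (cross-region correlations start near 0
  # and must clear the common threshold to form edges)
  delta <- delta %||% if (kind == "long_range") 0.45 else 0.15
  decoupling <- decoupling %||% if (kind == "long_range") 0.45 else 0.7
  session_name <- "cathodal"
  effects <- if (kind == "none") list() else
    stats::setNames(list(list(kind = kind, delta = delta,
                              n_target = n_target,
                              n_shortcut_partners = n_shortcut_partners,
                              decoupling = decoupling)),
                    paste0(session_name, ".after"))
  design <- study_design(n_subjects = n_subjects, sessions = session_name,
                         times = c("before", "after"), effects = effects,
                         subject_baseline = if (is.null(baseline_range)) NULL
                           else list(delta_range = baseline_range),
                         seed = seed)
  cfg <- default_config(seed = seed,
                        roi = list(n_voxels = roi_n, shape = "slab",
                                   voxel_size_mm = 3),
                        session = list(n_timepoints = n_timepoints,
                                       tr_seconds = 1.8, noise_sd = noise_sd),
                        nulls = list(method = "theoretical"))
  for (nm in names(config_overrides)) {
    if (is.list(config_overrides[[nm]]) && is.list(cfg[[nm]])) {
      for (sub in names(config_overrides[[nm]]))
        cfg[[nm]][[sub]] <- config_overrides[[nm]][[sub]]
    } else cfg[[nm]] <- config_overrides[[nm]]
  }
  study <- simulate_study(design, roi_params = cfg$roi,
                          session_params = cfg$session)
  sm <- study_maps(study, cfg)
  target <- study$targets[[1]][seq_len(n_target)]
  # for long-range effects the planted system is target + partner region
  planted <- target
  if (kind == "long_range") {
    aff <- Filter(function(d) d$truth$effect$kind == "long_range",
                  study$datasets)
    if (length(aff)) planted <- union(target, aff[[1]]$truth$partners)
  }

  out <- list(t_common = sm$t_common, target = target, planted = planted)
  for (metric in c("K_norm", "C_norm", "L_norm")) {
    pm <- posthoc_paired_map(sm$values[[metric]], sm$meta,
                             c(session_name, "after"),
                             c(session_name, "before"), sm$roi)
    cc <- cluster_correct(pm, sm$roi,
                          adjacency = cfg$stats$adjacency,
                          cluster_forming_p = cluster_forming_p,
                          n_permutations = n_permutations,
                          seed = seed_for(seed, 9L,
                                          match(metric, c("K_norm", "C_norm", "L_norm"))))
    sig <- significant_clusters(cc, cfg$stats$alpha)
    out[[metric]] <- list(
      clusters = cc$clusters,
      n_significant = length(sig),
      dice = if (length(sig))
        max(vapply(sig, dice_overlap, double(1), planted)) else 0)
  }
  out
}

#' Baseline-dependence experiment
#'
#' Simulates a before/after stimulation study in which each subject's effect
#' amplitude is coupled, with planted correlation `rho`, to the subject's
#' measured baseline network metric: the before sessions are simulated and
#' analysed first, the mean normalized clustering of the target region is
#' extracted as the baseline metric, and per-subject effect amplitudes are
#' then drawn with correlation `rho` to that metric before the after
#' sessions are generated. [baseline_dependence()] finally regresses the
#' within-target after-minus-before change on the baseline value across
#' subjects. With `rho = 0` the slope test provides a type-I calibration.
#'
#' @param rho Planted correlation between per-subject effect size and the
#'   measured baseline metric (0 to 1).
#' @param n_subjects Number of subjects (default 14).
#' @param roi_n ROI size in voxels (default 200).
#' @param n_target Target-region size (default 30).
#' @param n_timepoints Volumes per dataset (default 175).
#' @param delta Mean planted effect size (default 0.15).
#' @param effect_cv Coefficient of variation of per-subject effect
#'   amplitudes (default 1; a wide amplitude spread so that the planted
#'   coupling dominates measurement noise).
#' @param baseline_range Per-subject architectural coupling-strength range
#'   for the target (default 0.3-0.9).
#' @param seed Master seed.
#' @return List with `slope`, `r_squared`, `p` and `n` from
#'   [baseline_dependence()] on the ground-truth target region.
#' @export
baseline_dependence_study <- function(rho, n_subjects = 14L, roi_n = 200L,
                                      n_target = 30L, n_timepoints = 175L,
                                      delta = 0.15, effect_cv = 1,
                                      baseline_range = c(0.3, 0.9),
                                      seed = 1L) {
  cfg <- default_config(seed = seed,
                        roi = list(n_voxels = roi_n, shape = "slab",
                                   voxel_size_mm = 3),
                        session = list(n_timepoints = n_timepoints,
                                       tr_seconds = 1.8, noise_sd = 0.3,
                                       amp_jitter_sd = 0.05),
                        nulls = list(method = "theoretical"))
  roi <- do.call(make_roi, c(cfg$roi, list(seed = seed_for(seed, 1L))))
  target <- central_voxels(roi, n_target)
  ext <- apply(roi$coords, 2, function(v) diff(range(v)))
  ax <- which.max(ext)
  ctr <- colMeans(roi$coords)
  ctr[ax] <- ctr[ax] + 0.35 * ext[ax]
  hub_vox <- setdiff(order(rowSums(sweep(roi$coords, 2, ctr)^2)), target)
  hub <- list(voxels = hub_vox[1:30], strength = 1)
  b_s <- with_seed(seed_for(seed, 2L),
                   runif(n_subjects, baseline_range[1], baseline_range[2]))

  sim_one <- function(s, tm, eff) {
    regions <- list(hub, list(voxels = target, strength = b_s[s]))
    do.call(simulate_session,
            c(list(roi = roi, effect = eff,
                   seed = seed_for(seed, 4L, s, tm),
                   hub_region = regions),
              cfg$session))
  }
  mats_of <- function(sessions) lapply(sessions, function(d)
    correlation_matrix(preprocess_series(d$bold, d$nuisance)))
  tmax_of <- function(mats) vapply(mats, function(m) scan_tmax(m)$T_max,
                                   double(1))
  maps_at <- function(mats, tc) t(vapply(mats, function(m) {
    g <- restrict_to_largest(threshold_graph(m, tc))
    ns <- theoretical_null(g$n_nodes, mean(nodal_degree(g)))
    nodal_maps(g, roi, ns, fwhm_mm = cfg$maps$fwhm_mm)$C_norm$values
  }, double(roi$n_voxels)))

  before <- lapply(seq_len(n_subjects), function(s) sim_one(s, 1L, effect_spec("none")))
  mats_b <- mats_of(before)
  tmax_b <- tmax_of(mats_b)
  # baseline metric for the coupling, measured at the before-group threshold
  x <- rowMeans(maps_at(mats_b, group_common_threshold(tmax_b))[, target,
                                                               drop = FALSE])

  # couple per-subject effect amplitude to the measured baseline metric
  z <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else rep(0, n_subjects)
  eps <- with_seed(seed_for(seed, 3L), rnorm(n_subjects))
  mix <- rho * z + sqrt(max(0, 1 - rho^2)) * eps
  delta_s <- pmin(delta * pmax(0.05, 1 + effect_cv * mix), 0.8)

  after <- lapply(seq_len(n_subjects), function(s)
    sim_one(s, 2L, effect_spec("local_coupling", target_voxels = target,
                               coupling_delta = delta_s[s],
                               decoupling = 0.7, saturate = TRUE)))
  mats_a <- mats_of(after)
  # final maps for the regression share one common threshold, as in the
  # full pipeline
  tc <- group_common_threshold(c(tmax_b, tmax_of(mats_a)))
  baseline_dependence(target, maps_at(mats_b, tc), maps_at(mats_a, tc))
}

#' Map-level generator with baseline-coupled effects
#'
#' Draws per-subject baseline and after metric maps in which the effect
#' amplitude added over a target region carries a planted correlation `rho`
#' with the subject's measured baseline level. This is the parameter-recovery
#' harness for [baseline_dependence()]: with small map noise the regression's
#' R-squared estimates `rho^2` directly; with `rho = 0` its slope test is a
#' calibrated null. (The full BOLD-level analogue, with all measurement
#' stages in between, is [baseline_dependence_study()].)
#'
#' @param rho Planted correlation between effect amplitude and measured
#'   baseline (0 to 1).
#' @param n_subjects Number of subjects (default 14).
#' @param n_voxels Map length (default 100).
#' @param n_target Target-region size (default 30; the first voxels).
#' @param baseline_sd Between-subject standard deviation of baseline level.
#' @param noise_sd Voxelwise map noise standard deviation.
#' @param effect_mean,effect_sd Mean and spread of the per-subject effect
#'   amplitude.
#' @param seed Integer seed.
#' @return List with `before` and `after` (subjects x voxels matrices),
#'   `target` voxel indices and the true per-subject amplitudes.
#' @export
simulate_coupled_maps <- function(rho, n_subjects = 14L, n_voxels = 100L,
                                  n_target = 30L, baseline_sd = 0.5,
                                  noise_sd = 0.05, effect_mean = 0.3,
                                  effect_sd = 0.15, seed = 1L) {
  with_seed(seed, {
    target <- seq_len(n_target)
    pattern <- runif(n_voxels, 0.8, 1.2)
    u <- rnorm(n_subjects, 0, baseline_sd)
    before <- outer(rep(1, n_subjects), pattern) + u +
      matrix(rnorm(n_subjects * n_voxels, 0, noise_sd), n_subjects)
    x_meas <- rowMeans(before[, target, drop = FALSE])
    z <- (x_meas - mean(x_meas)) / stats::sd(x_meas)
    eff <- effect_mean + effect_sd *
      (rho * z + sqrt(max(0, 1 - rho^2)) * rnorm(n_subjects))
    after <- outer(rep(1, n_subjects), pattern) + u +
      matrix(rnorm(n_subjects * n_voxels, 0, noise_sd), n_subjects)
    after[, target] <- after[, target, drop = FALSE] + eff
    list(before = before, after = after, target = target,
         effect_amplitudes = eff, baseline_levels = u)
  })
}
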