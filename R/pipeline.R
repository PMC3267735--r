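#' Default end-to-end run configuration
#'
#' Returns the full nested parameter list for [run_pipeline()], populated
#' with the reference study conditions: 14 subjects x 3 sessions x 2 times,
#' 470-voxel ROI on a 3 mm lattice, 175 volumes at TR 1.8 s, 0.01-0.09 Hz
#' band, threshold scan from 0.1 in steps of 0.002 with a 95% giant-component
#' criterion, 1000-replicate rewired null ensembles, 6 mm FWHM smoothing and
#' 5000-permutation cluster correction. Any element can be overridden via
#' `...` (named sublists are merged).
#'
#' @param seed Master seed.
#' @param ... Named sublist overrides, e.g.
#'   `study = list(n_subjects = 6)`.
#' @return A `run_config` (nested named list).
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    study = list(
      n_subjects = 14L,
      sessions = c("anodal", "cathodal", "sham"),
      times = c("before", "after"),
      effects = list(),
      subject_baseline = NULL
    ),
    roi = list(n_voxels = 470L, shape = "slab", voxel_size_mm = 3),
    session = list(n_timepoints = 175L, tr_seconds = 1.8, noise_sd = 1),
    preprocess = list(discard = 2L, ar_order = 1L, band = c(0.01, 0.09),
                      order = c("regress", "prewhiten", "bandpass")),
    netbuild = list(t0 = 0.1, step = 0.002, criterion = 0.95),
    nulls = list(method = "rewire", n_replicates = 1000L, swap_factor = 10),
    maps = list(fwhm_mm = 6, hub_fraction = 0.15),
    stats = list(adjacency = 26L, cluster_forming_p = 0.05,
                 n_permutations = 5000L, alpha = 0.05,
                 gatekeeping = TRUE, global_thresholds = NULL)
  )
  override <- list(...)
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(cfg[[nm]])) {
      for (sub in names(override[[nm]])) {
        val <- override[[nm]][[sub]]
        if (!is.null(val)) cfg[[nm]][[sub]] <- val
      }
    } else cfg[[nm]] <- override[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param path YAML file path.
#' @return For `read_config`, a `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(seed = cfg$seed %||% 1L)
  for (nm in names(cfg)) {
    if (is.list(cfg[[nm]]) && is.list(base[[nm]])) {
      for (sub in names(cfg[[nm]])) {
        val <- cfg[[nm]][[sub]]
        if (!is.null(val)) base[[nm]][[sub]] <- val
      }
    } else base[[nm]] <- cfg[[nm]]
  }
  base
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# small FNV-1a hash of the config serialization, for provenance
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        null = "null")
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Orchestrates simulate -> preprocess -> netbuild -> metrics/nulls -> maps
#' -> stats from one configuration, with all randomness fanned out from the
#' single master seed. Emits a machine-readable report; identical
#' configuration and seed give byte-identical reports.
#'
#' The stats stage runs only when the design supports it (at least two
#' sessions, two times and three subjects); with gatekeeping on (default),
#' post-hoc paired contrasts for a metric are computed only when its
#' interaction map has a surviving corrected cluster.
#'
#' @param config A `run_config` from [default_config()] or [read_config()].
#' @param out_dir Optional output directory; when given, `report.json`,
#'   cluster tables (CSV) and the group-mean maps are written there.
#' @return The report, an invisible named list.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  t_start <- Sys.time()
  design <- study_design(n_subjects = config$study$n_subjects,
                         sessions = config$study$sessions,
                         times = config$study$times,
                         effects = config$study$effects,
                         subject_baseline = config$study$subject_baseline,
                         seed = config$seed)
  study <- simulate_study(design, roi_params = config$roi,
                          session_params = config$session)
  roi <- study$rois[[1]]
  nd <- length(study$datasets)

  # --- motion QC + dataset-level pipeline --------------------------------
  qc <- vapply(study$datasets, function(d)
    motion_qc(d$nuisance)$pass, logical(1))
  sm <- study_maps(study, config)
  t_maxes <- sm$t_maxes
  t_common <- sm$t_common
  maps <- sm$maps
  glob <- sm$global
  meta <- sm$meta

  global_tbl <- do.call(rbind, lapply(seq_len(nd), function(i)
    data.frame(meta[i, ], threshold = t_common,
               K = glob[[i]]$K, C = glob[[i]]$C, L = glob[[i]]$L,
               gamma = glob[[i]]$gamma, lambda = glob[[i]]$lambda,
               sigma = glob[[i]]$sigma)))

  # --- global paired tests ----------------------------------------------
  global_tests <- NULL
  if (length(config$study$times) == 2 && config$study$n_subjects >= 3) {
    long <- do.call(rbind, lapply(c("K", "gamma", "lambda", "sigma"),
      function(mname) {
        d <- data.frame(meta, threshold = t_common,
                        value = vapply(glob, `[[`, double(1),
                                       switch(mname, K = "K", gamma = "gamma",
                                              lambda = "lambda", sigma = "sigma")),
                        metric = mname)
        d
      }))
    global_tests <- do.call(rbind, lapply(split(long, long$metric),
      function(d) {
        res <- global_metric_tests(d, times = config$study$times)
        res$metric <- d$metric[1]
        res
      }))
    rownames(global_tests) <- NULL
  }

  # --- nodal statistics --------------------------------------------------
  can_stats <- length(config$study$sessions) >= 2 &&
    length(config$study$times) == 2 && config$study$n_subjects >= 3
  stats_out <- NULL
  if (can_stats) {
    stats_out <- list()
    before_lab <- config$study$times[1]
    after_lab <- config$study$times[2]
    for (metric in c("K_norm", "C_norm", "L_norm")) {
      vals <- do.call(rbind, lapply(maps, function(m) m[[metric]]$values))
      imap <- interaction_map(vals, meta, roi)
      icor <- cluster_correct(imap, roi, values = vals, design = meta,
                              adjacency = config$stats$adjacency,
                              cluster_forming_p = config$stats$cluster_forming_p,
                              n_permutations = config$stats$n_permutations,
                              seed = seed_for(config$seed, 6L,
                                              match(metric, c("K_norm", "C_norm", "L_norm"))))
      sig <- significant_clusters(icor, config$stats$alpha)
      entry <- list(interaction_clusters = icor$clusters,
                    interaction_significant = length(sig) > 0)
      run_posthoc <- !config$stats$gatekeeping || length(sig) > 0
      if (run_posthoc) {
        ph <- list()
        for (sess in setdiff(config$study$sessions, "sham")) {
          pm <- posthoc_paired_map(vals, meta,
                                   c(sess, after_lab), c(sess, before_lab), roi)
          pc <- cluster_correct(pm, roi,
                                adjacency = config$stats$adjacency,
                                cluster_forming_p = config$stats$cluster_forming_p,
                                n_permutations = config$stats$n_permutations,
                                seed = seed_for(config$seed, 8L,
                                                match(metric, c("K_norm", "C_norm", "L_norm")),
                                                match(sess, config$study$sessions)))
          ph[[paste0(sess, "_after_minus_before")]] <- pc$clusters
          sigc <- significant_clusters(pc, config$stats$alpha)
          if (length(sigc)) {
            ib <- which(meta$session == sess & meta$time == before_lab)
            ia <- which(meta$session == sess & meta$time == after_lab)
            ib <- ib[order(meta$subject[ib])]
            ia <- ia[order(meta$subject[ia])]
            bd <- baseline_dependence(sigc[[1]],
                                      vals[ib, , drop = FALSE],
                                      vals[ia, , drop = FALSE])
            ph[[paste0(sess, "_baseline_dependence")]] <- bd
          }
        }
        entry$posthoc <- ph
      }
      stats_out[[metric]] <- entry
    }
  }

  # --- hub mapping from baseline path-length maps ------------------------
  hub <- NULL
  if (nd >= 2) {
    before_idx <- which(meta$time == config$study$times[1])
    lmaps <- lapply(before_idx, function(i) maps[[i]]$L_norm)
    hub <- hub_map(lmaps, fraction = config$maps$hub_fraction)
  }

  report <- list(
    config_hash = config_hash(config),
    n_datasets = nd,
    qc_pass = qc,
    t_max = t_maxes,
    t_common = t_common,
    global_metrics = global_tbl,
    global_tests = global_tests,
    nodal_stats = stats_out,
    hub_voxels = if (!is.null(hub)) hub$hub_voxels else NULL,
    hub_realized_fraction = if (!is.null(hub)) hub$realized_fraction else NULL,
    elapsed_seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rep_out <- report
    rep_out$elapsed_seconds <- NULL  # keep report files byte-stable
    jsonlite::write_json(rep_out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns", pretty = TRUE)
    if (!is.null(stats_out)) {
      for (metric in names(stats_out)) {
        utils::write.csv(stats_out[[metric]]$interaction_clusters,
                         file.path(out_dir, paste0("clusters_", metric, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  invisible(report)
}
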