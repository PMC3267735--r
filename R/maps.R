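new_metric_map <- function(values, metric, roi, smoothing = NULL) {
  structure(list(values = values, metric = metric, roi = roi,
                 smoothing_fwhm_mm = smoothing,
                 missing = which(is.na(values))),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("Metric map [%s]: %d voxels (%d missing), range [%.3f, %.3f]%s\n",
              x$metric, length(x$values), sum(is.na(x$values)),
              min(v), max(v),
              if (!is.null(x$smoothing_fwhm_mm))
                sprintf(", smoothed %g mm FWHM", x$smoothing_fwhm_mm) else ""))
  invisible(x)
}

# expand nodal values (named by voxel ordinal) to a full-ROI vector with NA
# at voxels outside the largest component
expand_to_roi <- function(values, n_voxels) {
  out <- rep(NA_real_, n_voxels)
  out[as.integer(names(values))] <- values
  out
}

#' Normalized degree map
#'
#' Scales a nodal degree map to `[0, 1]` by dividing by the map's own
#' maximum, making maps comparable across subjects.
#'
#' @param k_values Named nodal degrees (from [nodal_degree()]) or a plain
#'   numeric vector.
#' @param roi The `roi_mask` the map lives on (optional).
#' @return A `metric_map` with metric `"K_norm"`.
#' @export
normalize_degree_map <- function(k_values, roi = NULL) {
  v <- map_input_vector(k_values, roi)
  mx <- max(v, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("degree map maximum must be positive")
  new_metric_map(v / mx, "K_norm", roi)
}

#' Normalized clustering map
#'
#' Elementwise `C_i / C_rand` against the null-ensemble clustering.
#'
#' @param c_values Named nodal clustering values or plain vector.
#' @param C_rand Null clustering scalar (> 0).
#' @param roi Optional `roi_mask`.
#' @return A `metric_map` with metric `"C_norm"`.
#' @export
normalize_clustering_map <- function(c_values, C_rand, roi = NULL) {
  if (C_rand <= 0) stop("C_rand must be positive")
  v <- map_input_vector(c_values, roi)
  new_metric_map(v / C_rand, "C_norm", roi)
}

#' Normalized path-length map
#'
#' Elementwise `L_rand / L_i`. The inversion makes better-integrated voxels
#' (lower `L_i`) take larger values.
#'
#' @param l_values Named nodal path lengths or plain vector (all > 0).
#' @param L_rand Null path-length scalar.
#' @param roi Optional `roi_mask`.
#' @return A `metric_map` with metric `"L_norm"`.
#' @export
normalize_pathlength_map <- function(l_values, L_rand, roi = NULL) {
  v <- map_input_vector(l_values, roi)
  if (any(v <= 0, na.rm = TRUE)) stop("all L_i must be positive")
  new_metric_map(L_rand / v, "L_norm", roi)
}

map_input_vector <- function(values, roi) {
  if (inherits(values, "metric_map")) return(values$values)
  v <- as.numeric(values)
  if (!is.null(names(values)) && !is.null(roi))
    v <- expand_to_roi(stats::setNames(v, names(values)), roi$n_voxels)
  v
}

#' Gaussian smoothing within a mask
#'
#' Mask-restricted Gaussian smoothing of a metric map: each voxel's value is
#' replaced by a weighted average of in-mask, non-missing voxels with weights
#' `exp(-d^2 / (2 sigma^2))`, `sigma = fwhm / (2 sqrt(2 ln 2))` in mm,
#' renormalized to sum to one. Renormalization preserves constant maps
#' exactly; `fwhm = 0` is the identity.
#'
#' @param map A `metric_map` (or numeric vector).
#' @param roi The `roi_mask` (taken from the map if present).
#' @param fwhm_mm Kernel full width at half maximum in mm (default 6).
#' @return A smoothed `metric_map`; missing voxels stay missing.
#' @export
smooth_map <- function(map, roi = NULL, fwhm_mm = 6) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (inherits(map, "metric_map")) {
    v <- map$values
    roi <- roi %||% map$roi
    metric <- map$metric
  } else {
    v <- as.numeric(map)
    metric <- "values"
  }
  if (is.null(roi)) stop("an roi_mask is required for smoothing")
  if (fwhm_mm == 0)
    return(new_metric_map(v, metric, roi, smoothing = 0))
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d_mm <- roi_distance_voxels(roi) * roi$voxel_size_mm
  ok <- !is.na(v)
  k <- exp(-d_mm[ok, ok, drop = FALSE]^2 / (2 * sigma^2))
  # symmetric Sinkhorn scaling: find d with diag(d) K diag(d) doubly
  # stochastic, so smoothing leaves both constant maps and the in-mask mean
  # exactly unchanged
  d <- 1 / sqrt(rowSums(k))
  for (i in 1:500) {
    r <- d * as.vector(k %*% d)
    if (max(abs(r - 1)) < 1e-13) break
    d <- d / sqrt(r)
  }
  out <- rep(NA_real_, length(v))
  out[ok] <- d * as.vector(k %*% (d * v[ok]))
  new_metric_map(out, metric, roi, smoothing = fwhm_mm)
}

#' Hub extraction from averaged path-length maps
#'
#' Averages a collection of normalized path-length (`L_rand / L_i`) maps
#' voxelwise and selects the top fraction of voxels (default 15%) as hubs --
#' the voxels that communicate most efficiently with the rest of the ROI.
#' The hub count is the ceiling of `fraction * N_valid`; ties at the cutoff
#' are all included and the realized fraction is recorded.
#'
#' @param maps List of `metric_map` objects sharing one ROI (or a matrix,
#'   maps x voxels).
#' @param fraction Top fraction to select, in (0, 1) (default 0.15).
#' @return A `hub_map`: `hub_voxels`, requested and realized `fraction`, the
#'   averaged `source` map.
#' @export
hub_map <- function(maps, fraction = 0.15) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  if (is.list(maps) && inherits(maps[[1]], "metric_map")) {
    roi <- maps[[1]]$roi
    vals <- do.call(rbind, lapply(maps, function(m) m$values))
  } else {
    roi <- NULL
    vals <- as.matrix(maps)
  }
  valid <- colSums(is.na(vals)) == 0
  avg <- rep(NA_real_, ncol(vals))
  avg[valid] <- colMeans(vals[, valid, drop = FALSE])
  n_valid <- sum(valid)
  n_hub <- ceiling(fraction * n_valid)
  vv <- avg[valid]
  cutoff <- sort(vv, decreasing = TRUE)[n_hub]
  hubs <- which(valid)[vv >= cutoff]
  structure(list(hub_voxels = hubs, fraction = fraction,
                 realized_fraction = length(hubs) / n_valid,
                 n_valid = n_valid, source = avg, roi = roi),
            class = "hub_map")
}

#' @export
print.hub_map <- function(x, ...) {
  cat(sprintf("Hub map: %d hub voxels of %d valid (requested %.0f%%, realized %.1f%%)\n",
              length(x$hub_voxels), x$n_valid, 100 * x$fraction,
              100 * x$realized_fraction))
  invisible(x)
}

#' All three normalized nodal maps for one dataset
#'
#' Convenience wrapper: computes nodal degree, clustering and path length on
#' the largest-component graph, applies the standard normalizations
#' (`K / max`, `C_i / C_rand`, `L_rand / L_i`), places values at their ROI
#' voxels (missing elsewhere) and optionally smooths.
#'
#' @param G_largest A connected `functional_graph` from
#'   [restrict_to_largest()] whose `node_ids` index the ROI.
#' @param roi The `roi_mask`.
#' @param null_summary A null summary supplying `C_rand` and `L_rand`.
#' @param fwhm_mm Smoothing FWHM in mm (0 disables; default 6).
#' @return Named list of `metric_map`s: `K_norm`, `C_norm`, `L_norm`.
#' @export
nodal_maps <- function(G_largest, roi, null_summary, fwhm_mm = 6) {
  k <- expand_to_roi(nodal_degree(G_largest), roi$n_voxels)
  ci <- expand_to_roi(nodal_clustering(G_largest), roi$n_voxels)
  li <- expand_to_roi(nodal_path_length(G_largest), roi$n_voxels)
  maps <- list(
    K_norm = normalize_degree_map(k, roi),
    C_norm = normalize_clustering_map(ci, null_summary$C_rand, roi),
    L_norm = normalize_pathlength_map(li, null_summary$L_rand, roi)
  )
  if (fwhm_mm > 0) maps <- lapply(maps, smooth_map, roi = roi,
                                  fwhm_mm = fwhm_mm)
  maps
}

#' Write a metric map as CSV
#'
#' @param map A `metric_map`.
#' @param path Output path (columns `voxel_id`, `value`).
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(data.frame(voxel_id = seq_along(map$values),
                              value = map$values),
                   path, row.names = FALSE)
  invisible(path)
}
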