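#' Render an ROI (optionally with per-voxel values) as a 3-D array
#'
#' @param roi An `roi_mask`.
#' @param values Optional per-voxel values; default renders the binary mask.
#' @param background Value outside the mask (default 0; `NA` is useful for
#'   metric maps).
#' @return A 3-D numeric array spanning the mask's bounding box.
#' @export
roi_to_array <- function(roi, values = NULL, background = 0) {
  dims <- apply(roi$coords, 2, max) + 1L
  arr <- array(background, dim = dims)
  v <- if (is.null(values)) rep(1, roi$n_voxels) else values
  arr[roi$coords + 1L] <- v
  arr
}

#' Write an ROI mask as NIfTI
#'
#' @param roi An `roi_mask`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @export
write_roi_nifti <- function(roi, path) {
  img <- RNifti::asNifti(roi_to_array(roi))
  RNifti::pixdim(img) <- rep(roi$voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a BOLD series as 4-D NIfTI
#'
#' @param bold A `bold_series` (its `roi` supplies the geometry).
#' @param path Output path.
#' @export
write_series_nifti <- function(bold, path) {
  roi <- bold$roi
  dims <- c(apply(roi$coords, 2, max) + 1L, ncol(bold$data))
  arr <- array(0, dim = dims)
  idx <- cbind(roi$coords[rep(seq_len(roi$n_voxels), ncol(bold$data)), ] + 1L,
               rep(seq_len(ncol(bold$data)), each = roi$n_voxels))
  arr[idx] <- as.vector(bold$data)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(roi$voxel_size_mm, 3), bold$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary ROI mask from NIfTI
#'
#' @param path NIfTI file; voxels with value > 0 enter the mask.
#' @return An `roi_mask` (voxel order: x fastest, then y, then z).
#' @export
read_roi_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  idx <- which(as.array(img) > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 3], idx[, 2], idx[, 1]), , drop = FALSE]
  coords <- idx - 1L
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  storage.mode(coords) <- "integer"
  vs <- RNifti::pixdim(img)[1]
  structure(list(coords = coords, voxel_size_mm = vs,
                 n_voxels = nrow(coords)),
            class = "roi_mask")
}

#' Read ROI voxel time series from a 4-D NIfTI
#'
#' @param path 4-D NIfTI file.
#' @param roi An `roi_mask` on the same grid.
#' @return A `bold_series` (voxels x timepoints).
#' @export
read_bold_nifti <- function(path, roi) {
  img <- as.array(RNifti::readNifti(path))
  n_t <- dim(img)[4]
  data <- vapply(seq_len(n_t), function(t)
    img[cbind(roi$coords + 1L, t)], double(roi$n_voxels))
  tr <- RNifti::pixdim(RNifti::readNifti(path))
  tr <- if (length(tr) >= 4) tr[4] else NA_real_
  structure(list(data = data, tr_seconds = tr, roi = roi),
            class = "bold_series")
}

#' Write a metric map as NIfTI aligned to its ROI grid
#'
#' @param map A `metric_map` (missing voxels written as 0).
#' @param path Output path.
#' @export
write_map_nifti <- function(map, path) {
  v <- map$values
  v[is.na(v)] <- 0
  img <- RNifti::asNifti(roi_to_array(map$roi, v))
  RNifti::pixdim(img) <- rep(map$roi$voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read motion parameters from whitespace-delimited text
#'
#' Expects six columns per timepoint (the MCFLIRT `.par` dialect).
#'
#' @param path Text file.
#' @return A 6 x timepoints matrix.
#' @export
read_motion_par <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6) stop("motion parameter file must have 6 columns")
  t(m)
}

#' Write ground-truth labels of a synthetic study as JSON
#'
#' @param study A `study_data` object.
#' @param path Output JSON path.
#' @export
write_study_truth <- function(study, path) {
  labels <- lapply(study$datasets, function(d)
    list(subject = d$subject, session = d$session, time = d$time,
         effect_kind = d$truth$effect$kind,
         coupling_delta = d$truth$effect$coupling_delta))
  jsonlite::write_json(
    list(datasets = labels,
         targets = study$targets,
         baseline_coupling = study$baseline_coupling),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
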