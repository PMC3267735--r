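#' Construct a lattice ROI mask
#'
#' Creates a connected set of voxels on a regular 3-D lattice that serves as
#' the node universe for voxel-wise connectivity graphs. Two geometries are
#' available: a `"slab"` (a thin rectangular sheet two voxels deep, roughly the
#' shape of a re-sliced cortical ribbon label) and a `"blob"` (a compact,
#' quasi-spherical cluster grown around a centre point).
#'
#' @param n_voxels Number of voxels in the mask (>= 8).
#' @param shape `"slab"` or `"blob"`.
#' @param voxel_size_mm Isotropic voxel edge length in millimetres (default 3,
#'   the grid of a typical EPI acquisition).
#' @param seed Integer seed; construction is deterministic given the seed.
#' @param max_extent Maximum lattice extent per axis for the slab geometry.
#' @return An object of class `roi_mask` with fields `coords` (an
#'   `n_voxels` x 3 integer matrix of 0-based lattice indices),
#'   `voxel_size_mm` and `n_voxels`.
#' @examples
#' roi <- make_roi(64, shape = "blob", seed = 1)
#' roi
#' @export
make_roi <- function(n_voxels, shape = c("slab", "blob"), voxel_size_mm = 3,
                     seed = 1L, max_extent = 64L) {
  shape <- match.arg(shape)
  if (n_voxels < 8) stop("n_voxels must be at least 8")
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")

  coords <- switch(shape,
    slab = {
      depth <- 2L
      nx <- ceiling(sqrt(n_voxels / depth))
      ny <- ceiling(n_voxels / (depth * nx))
      if (nx > max_extent || ny > max_extent)
        stop("n_voxels exceeds slab capacity for max_extent = ", max_extent)
      # raster fill: consecutive voxels are face neighbours, so any prefix of
      # the enumeration is connected
      grid <- expand.grid(x = seq_len(nx) - 1L, y = seq_len(ny) - 1L,
                          z = seq_len(depth) - 1L)
      grid <- grid[order(grid$z, grid$y, grid$x), ]
      as.matrix(grid[seq_len(n_voxels), , drop = FALSE])
    },
    blob = {
      # n voxels closest (Euclidean) to the dual-lattice point (.5,.5,.5);
      # ties broken lexicographically.  A Euclidean ball on the lattice is
      # face-connected, and n = 8 yields the 2x2x2 cube.
      r <- ceiling((3 * n_voxels / (4 * pi))^(1 / 3)) + 2L
      ax <- seq.int(-r, r + 1L)
      grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
      d2 <- rowSums((grid - 0.5)^2)
      ord <- order(d2, grid[, 1], grid[, 2], grid[, 3])
      sel <- grid[ord[seq_len(n_voxels)], , drop = FALSE]
      sel - matrix(apply(sel, 2, min), n_voxels, 3, byrow = TRUE)
    }
  )
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  storage.mode(coords) <- "integer"
  roi <- structure(
    list(coords = coords, voxel_size_mm = voxel_size_mm,
         n_voxels = nrow(coords)),
    class = "roi_mask"
  )
  if (anyDuplicated(voxel_key(roi$coords)) > 0)
    stop("internal error: duplicate voxels in mask")
  if (!roi_is_connected(roi))
    stop("internal error: generated mask is not face-connected")
  roi
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("ROI mask:", x$n_voxels, "voxels,",
      x$voxel_size_mm, "mm isotropic lattice\n")
  ext <- apply(x$coords, 2, function(v) diff(range(v)) + 1L)
  cat("  extent (voxels): ", paste(ext, collapse = " x "), "\n", sep = "")
  invisible(x)
}

# unique integer key per lattice coordinate (coords must be >= 0, < 2^10)
voxel_key <- function(coords) {
  coords[, 1] + 1024 * coords[, 2] + 1024^2 * coords[, 3]
}

# offsets for 6/18/26-connectivity neighbourhoods
lattice_offsets <- function(connectivity = 6L) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nrm <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6"  = nrm == 1,
                 "18" = nrm >= 1 & rowSums(off != 0) <= 2,
                 "26" = nrm >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  off[keep, , drop = FALSE]
}

#' Voxel adjacency within an ROI mask
#'
#' @param roi An `roi_mask`.
#' @param connectivity Lattice neighbourhood: 6 (faces), 18 (faces+edges) or
#'   26 (faces+edges+corners).
#' @return A list with one integer vector per voxel giving the indices of its
#'   in-mask neighbours.
#' @export
roi_adjacency <- function(roi, connectivity = 6L) {
  coords <- roi$coords
  keys <- voxel_key(coords)
  off <- lattice_offsets(connectivity)
  n <- nrow(coords)
  nb <- vector("list", n)
  for (k in seq_len(nrow(off))) {
    shifted <- sweep(coords, 2, off[k, ], "+")
    ok <- rowSums(shifted >= 0) == 3
    idx <- rep(NA_integer_, n)
    idx[ok] <- match(voxel_key(shifted[ok, , drop = FALSE]), keys)
    hit <- which(!is.na(idx))
    for (i in hit) nb[[i]] <- c(nb[[i]], idx[i])
  }
  lapply(nb, function(v) if (is.null(v)) integer(0) else sort(v))
}

roi_is_connected <- function(roi, connectivity = 6L) {
  nb <- roi_adjacency(roi, connectivity)
  n <- roi$n_voxels
  if (n == 1) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]
    queue <- queue[-1L]
    for (j in nb[[cur]]) {
      if (!seen[j]) {
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  all(seen)
}

# Euclidean distance matrix between voxel centres, in voxel units
roi_distance_voxels <- function(roi) {
  as.matrix(stats::dist(roi$coords))
}

#' Connected components of a voxel set under lattice adjacency
#'
#' Groups a subset of ROI voxels into maximal connected clusters under the
#' configured lattice neighbourhood; used for cluster-forming in the group
#' statistics.
#'
#' @param voxels Integer indices into the ROI's voxel list.
#' @param roi An `roi_mask`.
#' @param connectivity 6, 18 or 26 (default 26, the usual cluster-forming
#'   neighbourhood in volumetric fMRI statistics).
#' @return A list of integer vectors, one per cluster, ordered by decreasing
#'   size (ties by smallest contained voxel index).
#' @export
lattice_clusters <- function(voxels, roi, connectivity = 26L) {
  voxels <- sort(unique(as.integer(voxels)))
  if (!length(voxels)) return(list())
  coords <- roi$coords[voxels, , drop = FALSE]
  keys <- voxel_key(coords)
  off <- lattice_offsets(connectivity)
  n <- length(voxels)
  # union-find over the subset
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(off))) {
    shifted <- sweep(coords, 2, off[k, ], "+")
    ok <- rowSums(shifted >= 0) == 3
    idx <- rep(NA_integer_, n)
    idx[ok] <- match(voxel_key(shifted[ok, , drop = FALSE]), keys)
    for (i in which(!is.na(idx))) {
      ri <- find(i); rj <- find(idx[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comps <- split(voxels, root)
  names(comps) <- NULL
  sizes <- lengths(comps)
  mins <- vapply(comps, min, integer(1))
  comps[order(-sizes, mins)]
}
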