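#' @importFrom stats pt pf lm na.omit
NULL

# vectorized two-tailed paired t on a subjects x voxels difference matrix
paired_t_cols <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2, m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  t[s == 0 & m == 0] <- 0
  p <- 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
  p[s == 0 & m == 0] <- 1
  list(t = t, p = p, df = n - 1)
}

#' Paired t-tests on global metrics across thresholds
#'
#' Compares a global network metric before vs after stimulation, separately
#' per session and per threshold, with two-tailed paired t-tests (no
#' multiplicity correction at this stage).
#'
#' @param tbl Data frame with columns `subject`, `session`, `time`,
#'   `threshold`, `value`; exactly one row per subject per cell per
#'   threshold.
#' @param times Length-2 character vector naming the (before, after) levels
#'   (default `c("before", "after")`).
#' @return Data frame with one row per (session, threshold): `t`, `df`, `p`,
#'   `mean_diff`. Zero-variance non-zero differences yield `p = NaN` with a
#'   warning.
#' @export
global_metric_tests <- function(tbl, times = c("before", "after")) {
  stopifnot(all(c("subject", "session", "time", "threshold", "value")
                %in% names(tbl)))
  out <- list()
  for (sess in unique(tbl$session)) {
    for (th in sort(unique(tbl$threshold))) {
      sub <- tbl[tbl$session == sess & tbl$threshold == th, ]
      b <- sub[sub$time == times[1], ]
      a <- sub[sub$time == times[2], ]
      b <- b[order(b$subject), ]
      a <- a[order(a$subject), ]
      if (!identical(b$subject, a$subject))
        stop("unpaired before/after data for session ", sess)
      d <- a$value - b$value
      n <- length(d)
      if (stats::sd(d) < 1e-12 * max(abs(d), 1)) {
        if (all(abs(d) < 1e-12)) {
          t <- 0; p <- 1
        } else {
          t <- NaN; p <- NaN
          warning("zero-variance non-zero differences (session ", sess,
                  ", T = ", th, "); p undefined")
        }
      } else {
        t <- mean(d) / (stats::sd(d) / sqrt(n))
        p <- 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(
        session = sess, threshold = th, t = t, df = n - 1, p = p,
        mean_diff = mean(d))
    }
  }
  do.call(rbind, out)
}

new_stat_map <- function(stat, p, kind, df, contrast, roi = NULL) {
  structure(list(stat = stat, p = p, kind = kind, df = df,
                 contrast = contrast, roi = roi),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  ok <- !is.na(x$stat)
  cat(sprintf("Stat map [%s, %s]: %d voxels, peak %s = %.2f\n",
              x$kind, x$contrast, sum(ok), x$kind, max(abs(x$stat[ok]))))
  invisible(x)
}

# per-voxel two-way repeated-measures interaction F (vectorized over voxels)
rm_anova_interaction_F <- function(Y, subject, session, time) {
  subject <- factor(subject); session <- factor(session); time <- factor(time)
  A <- nlevels(session); B <- nlevels(time); n <- nlevels(subject)
  if (nrow(Y) != A * B * n) stop("design must be fully crossed")
  gm <- colMeans(Y)
  mean_by <- function(f) {
    m <- rowsum(Y, f) / as.vector(table(f))
    m[as.integer(f), , drop = FALSE]
  }
  y_ab <- mean_by(interaction(session, time, drop = TRUE))
  y_a <- mean_by(session)
  y_b <- mean_by(time)
  y_s <- mean_by(subject)
  y_as <- mean_by(interaction(session, subject, drop = TRUE))
  y_bs <- mean_by(interaction(time, subject, drop = TRUE))
  g <- matrix(gm, nrow(Y), ncol(Y), byrow = TRUE)
  int_cell <- y_ab - y_a - y_b + g
  # each (a,b) cell is replicated n times across rows, so the column sum of
  # squares equals n * sum over cells, i.e. SS_interaction directly
  ss_ab <- colSums(int_cell^2)
  resid <- Y - y_ab - y_as - y_bs + y_a + y_b + y_s - g
  ss_abs <- colSums(resid^2)
  df1 <- (A - 1) * (B - 1)
  df2 <- df1 * (n - 1)
  F <- (ss_ab / df1) / (ss_abs / df2)
  list(F = F, df1 = df1, df2 = df2)
}

#' Voxelwise repeated-measures interaction map
#'
#' Two-way within-subject ANOVA (stimulation x time, subject as blocking
#' factor) at every voxel; returns the interaction F map with uncorrected p
#' from the F distribution with `((A-1)(B-1), (A-1)(B-1)(n-1))` degrees of
#' freedom. Voxels missing in any dataset are marked missing.
#'
#' @param values Datasets x voxels matrix of map values (e.g. stacked
#'   `metric_map` values).
#' @param design Data frame with columns `subject`, `session`, `time`, one
#'   row per row of `values`.
#' @param roi Optional `roi_mask` carried on the result.
#' @return A `stat_map` of kind `"F"`.
#' @export
interaction_map <- function(values, design, roi = NULL) {
  values <- as.matrix(values)
  ok <- colSums(is.na(values)) == 0
  res <- rm_anova_interaction_F(values[, ok, drop = FALSE],
                                design$subject, design$session, design$time)
  F <- p <- rep(NA_real_, ncol(values))
  F[ok] <- res$F
  p[ok] <- stats::pf(res$F, res$df1, res$df2, lower.tail = FALSE)
  new_stat_map(F, p, "F", c(res$df1, res$df2), "stimulation:time", roi)
}

#' Voxelwise post-hoc paired t map
#'
#' Paired t-test at every voxel for a stated contrast of two design cells,
#' e.g. after-cathodal minus before-cathodal, or after-anodal minus
#' after-sham.
#'
#' @param values Datasets x voxels matrix.
#' @param design Data frame with `subject`, `session`, `time` rows matching
#'   `values`.
#' @param cell_a,cell_b Length-2 character vectors `c(session, time)`; the
#'   contrast is `cell_a - cell_b`, paired within subject.
#' @param roi Optional `roi_mask`.
#' @return A `stat_map` of kind `"t"`, with the per-subject difference
#'   matrix attached as attribute `"diff"` (used for sign-flip permutation).
#' @export
posthoc_paired_map <- function(values, design, cell_a, cell_b, roi = NULL) {
  values <- as.matrix(values)
  ia <- which(design$session == cell_a[1] & design$time == cell_a[2])
  ib <- which(design$session == cell_b[1] & design$time == cell_b[2])
  ia <- ia[order(design$subject[ia])]
  ib <- ib[order(design$subject[ib])]
  if (!identical(design$subject[ia], design$subject[ib]) || !length(ia))
    stop("cells are not paired within subjects")
  D <- values[ia, , drop = FALSE] - values[ib, , drop = FALSE]
  ok <- colSums(is.na(D)) == 0
  t <- p <- rep(NA_real_, ncol(values))
  res <- paired_t_cols(D[, ok, drop = FALSE])
  t[ok] <- res$t
  p[ok] <- res$p
  sm <- new_stat_map(t, p, "t", res$df,
                     paste(paste(cell_a, collapse = "_"), "-",
                           paste(cell_b, collapse = "_")), roi)
  attr(sm, "diff") <- D
  sm
}

# all in-mask adjacency edges among ROI voxels (precomputed once)
roi_edges <- function(roi, connectivity = 26L) {
  nb <- roi_adjacency(roi, connectivity)
  from <- rep(seq_along(nb), lengths(nb))
  to <- unlist(nb, use.names = FALSE)
  keep <- from < to
  cbind(from[keep], to[keep])
}

# sizes of connected clusters of a logical supra-threshold vector, given the
# precomputed edge matrix; returns list(sizes, membership)
supra_clusters <- function(supra, edges) {
  idx <- which(supra)
  if (!length(idx)) return(list(sizes = integer(0), membership = NULL))
  pos <- integer(length(supra))
  pos[idx] <- seq_along(idx)
  keep <- supra[edges[, 1]] & supra[edges[, 2]]
  e1 <- pos[edges[keep, 1]]
  e2 <- pos[edges[keep, 2]]
  n <- length(idx)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(e1)) for (k in seq_along(e1)) {
    r1 <- find(e1[k]); r2 <- find(e2[k])
    if (r1 != r2) parent[r1] <- r2
  }
  root <- vapply(seq_len(n), find, integer(1))
  list(sizes = as.integer(table(root)),
       membership = split(idx, root))
}

#' Monte-Carlo cluster correction of a statistic map
#'
#' Thresholds a voxelwise statistic map at an uncorrected cluster-forming p,
#' groups supra-threshold voxels into clusters under lattice adjacency, and
#' corrects cluster extent by permutation: sign-flipping of per-subject
#' difference maps for paired t maps, within-subject permutation of session
#' labels for interaction F maps. The corrected p of an observed cluster is
#' `(1 + #[perm max size >= observed size]) / (1 + n_permutations)`.
#'
#' @param stat_map A `stat_map` from [posthoc_paired_map()] (kind `"t"`,
#'   which carries its difference matrix) or [interaction_map()].
#' @param roi The `roi_mask` defining lattice adjacency.
#' @param values,design Required for F maps: the dataset x voxel matrix and
#'   design table used to build the map.
#' @param adjacency 6, 18 or 26 (default 26).
#' @param cluster_forming_p Uncorrected forming threshold (default 0.05).
#' @param n_permutations Number of random permutations (default 5000; < 100
#'   triggers a warning). For sign-flipping with 12 or fewer subjects,
#'   `exhaustive = TRUE` enumerates all sign patterns instead.
#' @param seed Integer seed for the permutation draw.
#' @param exhaustive Enumerate all `2^n` sign flips (t maps, n <= 20).
#' @return A `cluster_result`: data frame of clusters (size in voxels and
#'   mm^3, peak statistic and voxel, corrected p) plus the permutation null
#'   of maximum cluster size.
#' @export
cluster_correct <- function(stat_map, roi, values = NULL, design = NULL,
                            adjacency = 26L, cluster_forming_p = 0.05,
                            n_permutations = 5000L, seed = 1L,
                            exhaustive = FALSE) {
  if (!exhaustive && n_permutations < 100)
    warning("fewer than 100 permutations gives unstable corrected p-values")
  edges <- roi_edges(roi, adjacency)
  obs_supra <- !is.na(stat_map$p) & stat_map$p < cluster_forming_p
  obs <- supra_clusters(obs_supra, edges)

  # statistic recomputation under permutation
  if (stat_map$kind == "t") {
    D <- attr(stat_map, "diff")
    if (is.null(D)) stop("t map carries no difference matrix")
    ok <- colSums(is.na(D)) == 0
    n <- nrow(D)
    tcrit <- stats::qt(1 - cluster_forming_p / 2, n - 1)
    signs <- if (exhaustive) {
      if (n > 20) stop("exhaustive enumeration limited to 20 subjects")
      as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    } else {
      with_seed(seed, matrix(sample(c(-1, 1), n_permutations * n,
                                    replace = TRUE), ncol = n))
    }
    Dok <- D[, ok, drop = FALSE]
    msq <- colMeans(Dok^2)
    M <- (signs %*% Dok) / n              # perms x voxels of mean
    # sd of flipped differences from fixed second moment
    max_sizes <- vapply(seq_len(nrow(signs)), function(r) {
      m <- M[r, ]
      v <- (msq - m^2) * n / (n - 1)
      t <- m / sqrt(v / n)
      supra <- rep(FALSE, length(obs_supra))
      supra[ok] <- abs(t) > tcrit & v > 0
      s <- supra_clusters(supra, edges)$sizes
      if (length(s)) max(s) else 0L
    }, integer(1))
    n_eff <- nrow(signs)
  } else {
    if (is.null(values) || is.null(design))
      stop("F-map correction needs values and design")
    values <- as.matrix(values)
    ok <- colSums(is.na(values)) == 0
    Yok <- values[, ok, drop = FALSE]
    subj <- factor(design$subject)
    sessions <- as.character(design$session)
    df1 <- stat_map$df[1]; df2 <- stat_map$df[2]
    fcrit <- stats::qf(1 - cluster_forming_p, df1, df2)
    subj_levels <- levels(subj)
    perm_seeds <- vapply(seq_len(n_permutations), function(r)
      seed_for(seed, 11L, r), integer(1))
    max_sizes <- vapply(seq_len(n_permutations), function(r) {
      perm_sessions <- sessions
      with_seed(perm_seeds[r], {
        for (s in subj_levels) {
          rows <- which(design$subject == s)
          ulab <- unique(sessions[rows])
          relab <- stats::setNames(sample(ulab), ulab)
          perm_sessions[rows] <- relab[sessions[rows]]
        }
      })
      res <- rm_anova_interaction_F(Yok, design$subject, perm_sessions,
                                    design$time)
      supra <- rep(FALSE, length(obs_supra))
      supra[ok] <- res$F > fcrit
      s <- supra_clusters(supra, edges)$sizes
      if (length(s)) max(s) else 0L
    }, integer(1))
    n_eff <- n_permutations
  }

  vox_mm3 <- roi$voxel_size_mm^3
  clusters <- if (length(obs$sizes)) {
    do.call(rbind, lapply(seq_along(obs$membership), function(i) {
      vox <- obs$membership[[i]]
      peak <- vox[which.max(abs(stat_map$stat[vox]))]
      data.frame(cluster_id = i, n_voxels = length(vox),
                 mm3 = length(vox) * vox_mm3,
                 peak_stat = stat_map$stat[peak], peak_voxel = peak,
                 p_corrected = if (exhaustive)
                   mean(max_sizes >= length(vox))
                 else
                   (1 + sum(max_sizes >= length(vox))) / (1 + n_eff))
    }))
  } else {
    data.frame(cluster_id = integer(0), n_voxels = integer(0),
               mm3 = numeric(0), peak_stat = numeric(0),
               peak_voxel = integer(0), p_corrected = numeric(0))
  }
  clusters <- clusters[order(clusters$p_corrected, -clusters$n_voxels), ,
                       drop = FALSE]
  structure(list(clusters = clusters,
                 cluster_voxels = obs$membership,
                 n_permutations = n_eff,
                 cluster_forming_p = cluster_forming_p,
                 adjacency = adjacency,
                 max_size_null = max_sizes),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Cluster correction:", nrow(x$clusters), "cluster(s),",
      x$n_permutations, "permutations\n")
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Surviving clusters at a corrected alpha
#'
#' @param x A `cluster_result`.
#' @param alpha Corrected significance level (default 0.05).
#' @return List of voxel-index vectors of the surviving clusters.
#' @export
significant_clusters <- function(x, alpha = 0.05) {
  keep <- which(x$clusters$p_corrected < alpha)
  x$cluster_voxels[x$clusters$cluster_id[keep]]
}

#' Baseline dependence of a stimulation effect
#'
#' For each subject, averages the after-minus-before effect over a cluster's
#' voxels and regresses it on the subject's baseline (before) value averaged
#' over the same cluster, by ordinary least squares.
#'
#' @param cluster_voxels Integer voxel indices of the effect cluster.
#' @param before,after Subjects x voxels matrices of map values for the
#'   before and after condition (rows aligned by subject).
#' @return List with `slope`, `intercept`, `r_squared`, `p` (two-tailed, for
#'   the slope) and `n`.
#' @export
baseline_dependence <- function(cluster_voxels, before, after) {
  before <- as.matrix(before)
  after <- as.matrix(after)
  if (nrow(before) < 3) stop("need at least 3 subjects")
  x <- rowMeans(before[, cluster_voxels, drop = FALSE], na.rm = TRUE)
  y <- rowMeans(after[, cluster_voxels, drop = FALSE] -
                before[, cluster_voxels, drop = FALSE], na.rm = TRUE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       n = length(x))
}

#' Dice overlap of two voxel sets
#'
#' @param a,b Integer voxel index vectors.
#' @return `2|a intersect b| / (|a| + |b|)`.
#' @export
dice_overlap <- function(a, b) {
  if (!length(a) && !length(b)) return(NA_real_)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}
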