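#' Linear-threshold binary mask
#'
#' @param image numeric array (any dimensionality).
#' @param fraction_of_max threshold as a fraction of the image maximum
#'   (default 0.5).
#' @param k_sigma alternative: threshold at `mean + k_sigma * sd` (overrides
#'   `fraction_of_max` when given).
#' @return logical array of the same shape, with a `threshold` attribute.
#' @export
linear_threshold_mask <- function(image, fraction_of_max = 0.5, k_sigma = NULL) {
  thr <- if (!is.null(k_sigma)) mean(image) + k_sigma * stats::sd(image)
         else fraction_of_max * max(image)
  m <- image >= thr
  attr(m, "threshold") <- thr
  m
}

#' Pearson correlation between two channels
#'
#' @param A,B numeric arrays of identical shape.
#' @param roi_mask optional logical array restricting the computation.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson_coloc <- function(A, B, roi_mask = NULL) {
  if (!identical(dim(A) %||% length(A), dim(B) %||% length(B)))
    stopf("A and B must have identical shape")
  a <- as.vector(A); b <- as.vector(B)
  if (!is.null(roi_mask)) {
    sel <- as.vector(roi_mask)
    if (!any(sel)) stopf("empty ROI")
    a <- a[sel]; b <- b[sel]
  }
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stopf("PCC undefined: zero variance in a channel")
  stats::cor(a, b)
}

#' Manders overlap coefficients
#'
#' Intensity-weighted overlap: `M1` is the fraction of channel-A signal lying
#' inside the channel-B mask, `M2` the fraction of channel-B signal inside
#' the channel-A mask. A voxel-count variant (`weighted = FALSE`) counts mask
#' voxels instead of intensities.
#'
#' @param A,B numeric arrays of identical shape.
#' @param maskA,maskB logical arrays (typically from
#'   [linear_threshold_mask()]).
#' @param weighted intensity-weighted (default) or voxel-count variant.
#' @return list with `M1`, `M2`.
#' @export
manders_coloc <- function(A, B, maskA, maskB, weighted = TRUE) {
  if (!identical(dim(A) %||% length(A), dim(B) %||% length(B)))
    stopf("A and B must have identical shape")
  if (weighted) {
    list(M1 = sum(A[maskB]) / sum(A), M2 = sum(B[maskA]) / sum(B))
  } else {
    list(M1 = sum(maskA & maskB) / sum(maskA),
         M2 = sum(maskA & maskB) / sum(maskB))
  }
}

#' Detect 3D intensity clusters
#'
#' Connected components (26-connected by default) of voxels above a
#' threshold, size-filtered. Labeling is deterministic: components are
#' numbered by their smallest column-major voxel index.
#'
#' @param volume 3D `(z, y, x)` numeric array.
#' @param threshold intensity threshold (absolute), or `"auto"` for half the
#'   volume maximum.
#' @param min_size_voxels minimum cluster size.
#' @param connectivity 6 or 26.
#' @param voxel_um voxel sizes `c(dz, dy, dx)` for physical centroids.
#' @return object of class `cluster_set`: data.frame with one row per
#'   cluster (id, n_voxels, centroid_z/y/x_um, integrated_intensity) and the
#'   label volume in `attr(, "labels")`.
#' @export
detect_clusters_3d <- function(volume, threshold = "auto",
                               min_size_voxels = 5L, connectivity = 26L,
                               voxel_um = c(1, 1, 1)) {
  if (identical(threshold, "auto")) threshold <- max(volume) / 2
  mask <- volume >= threshold
  lab <- label_components_3d(mask, connectivity)
  k <- max(lab)
  rows <- list()
  keep_id <- 0L
  relab <- array(0L, dim(lab))
  for (i in seq_len(k)) {
    sel <- lab == i
    n <- sum(sel)
    if (n < min_size_voxels) next
    keep_id <- keep_id + 1L
    ijk <- which(sel, arr.ind = TRUE)
    w <- volume[sel]
    rows[[keep_id]] <- data.frame(
      id = keep_id, n_voxels = n,
      centroid_z_um = sum((ijk[, 1] - 1) * w) / sum(w) * voxel_um[1],
      centroid_y_um = sum((ijk[, 2] - 1) * w) / sum(w) * voxel_um[2],
      centroid_x_um = sum((ijk[, 3] - 1) * w) / sum(w) * voxel_um[3],
      integrated_intensity = sum(w))
    relab[sel] <- keep_id
  }
  df <- if (keep_id > 0) do.call(rbind, rows) else
    data.frame(id = integer(0), n_voxels = integer(0),
               centroid_z_um = numeric(0), centroid_y_um = numeric(0),
               centroid_x_um = numeric(0), integrated_intensity = numeric(0))
  attr(df, "labels") <- relab
  attr(df, "threshold") <- threshold
  class(df) <- c("cluster_set", "data.frame")
  df
}

#' Distance of a cluster from the interface via the APC channel
#'
#' Line scan from the cluster centroid along the inward interface normal,
#' back toward the APC: the interface position is taken where the APC
#' fluorescence rises through half its maximum along the scan; the returned
#' distance is the centroid depth relative to that crossing.
#'
#' @param centroid_um cluster centroid `c(z, y, x)` in micrometers.
#' @param apc_vol 3D APC-channel volume.
#' @param frame an `interface_frame` (its normal points into the T cell).
#' @param voxel_um voxel sizes.
#' @param step_um scan step; default half the smallest voxel size.
#' @return distance in micrometers (positive = into the T cell).
#' @export
cluster_interface_distance <- function(centroid_um, apc_vol, frame, voxel_um,
                                       step_um = NULL) {
  step_um <- step_um %||% (min(voxel_um) / 2)
  dm <- dim(apc_vol)
  extent <- sum(dm * voxel_um)
  # scan the full line through the centroid along the depth axis, ordered from
  # deep inside the T cell (tau < 0 lies beyond the centroid on the APC side)
  tau <- seq(-extent, extent, by = step_um)
  pts <- matrix(rep(centroid_um, each = length(tau)), ncol = 3) -
    tau %o% frame$normal
  idx <- cbind(round(pts[, 1] / voxel_um[1]) + 1,
               round(pts[, 2] / voxel_um[2]) + 1,
               round(pts[, 3] / voxel_um[3]) + 1)
  ok <- idx[, 1] >= 1 & idx[, 1] <= dm[1] & idx[, 2] >= 1 & idx[, 2] <= dm[2] &
        idx[, 3] >= 1 & idx[, 3] <= dm[3]
  tau <- tau[ok]
  v <- apc_vol[idx[ok, , drop = FALSE]]
  if (length(v) < 3) stopf("scan leaves the volume immediately")
  vmax <- max(v)
  half <- vmax / 2
  if (vmax <= 0 || all(v >= half) || all(v < half) || v[1] >= half)
    stopf("no half-max crossing of the APC channel along the scan")
  i <- which(v >= half)[1]
  frac <- (half - v[i - 1]) / (v[i] - v[i - 1])
  tau[i - 1] + frac * (tau[i] - tau[i - 1])
}

#' Correlation between actin depth and deepest cluster depth
#'
#' Pearson correlation over paired per-cell measurements with a two-sided
#' p-value from the t transform `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y paired per-cell values (e.g. actin half-max depths and deepest
#'   cluster distances).
#' @return list with `r`, `p`, `n`.
#' @export
depth_correlation <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stopf("x and y lengths differ")
  if (n < 3) stopf("p-value undefined for n < 3")
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}
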