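# Synthetic two-channel volumes with controlled correlation / overlap, and
# planted 3D cluster fields with a known interface plane.

add_gaussian_blob <- function(vol, center_vox, sigma_vox, amplitude) {
  dm <- dim(vol)
  r <- ceiling(4 * sigma_vox)
  zr <- max(1, round(center_vox[1]) - r[1]):min(dm[1], round(center_vox[1]) + r[1])
  yr <- max(1, round(center_vox[2]) - r[2]):min(dm[2], round(center_vox[2]) + r[2])
  xr <- max(1, round(center_vox[3]) - r[3]):min(dm[3], round(center_vox[3]) + r[3])
  gz <- exp(-0.5 * ((zr - center_vox[1]) / sigma_vox[1])^2)
  gy <- exp(-0.5 * ((yr - center_vox[2]) / sigma_vox[2])^2)
  gx <- exp(-0.5 * ((xr - center_vox[3]) / sigma_vox[3])^2)
  vol[zr, yr, xr] <- vol[zr, yr, xr] +
    amplitude * outer(outer(gz, gy), gx)
  vol
}

#' Generate a two-channel volume with controlled colocalization
#'
#' Two modes. `"correlation"`: channel B is built as
#' `rho * A + sqrt(1 - rho^2) * noise` (after standardization), so the
#' expected pixelwise Pearson correlation equals `rho`. `"cluster_overlap"`:
#' channel A is a solid reference region (e.g. the F-actin mask) and channel
#' B a field of point clusters of which a fraction `overlap_fraction` is
#' planted inside the A region, controlling the Manders coefficient of B in
#' the A mask.
#'
#' @param rho target Pearson correlation (correlation mode).
#' @param overlap_fraction fraction of B clusters inside the A mask
#'   (cluster-overlap mode).
#' @param n_clusters number of clusters (cluster-overlap mode).
#' @param shape volume dimensions `c(nz, ny, nx)`; defaults: `c(40, 50, 50)`
#'   (1e5 voxels) for correlation, `c(24, 64, 64)` for cluster overlap.
#' @param mode `"correlation"` or `"cluster_overlap"`.
#' @param seed integer seed.
#' @return list with `A`, `B` (3D arrays) and `truth`.
#' @export
gen_coloc_volume <- function(rho = 0.6, overlap_fraction = 0.34,
                             n_clusters = 200L, shape = NULL,
                             mode = c("correlation", "cluster_overlap"),
                             seed = 0) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (mode == "correlation") {
    if (abs(rho) > 1) stopf("rho in [-1, 1]")
    shape <- shape %||% c(40, 50, 50)
    n <- prod(shape)
    a <- stats::rnorm(n)
    b <- rho * a + sqrt(1 - rho^2) * stats::rnorm(n)
    A <- array(5 + a, shape)
    B <- array(5 + b, shape)
    list(A = A, B = B,
         truth = list(mode = mode, rho = rho, n_voxels = n, seed = seed))
  } else {
    shape <- shape %||% c(24, 64, 64)
    n_in <- round(overlap_fraction * n_clusters)
    n_out <- n_clusters - n_in
    # channel A: solid slab over the lower-x half of the volume
    x_split <- floor(shape[3] / 2)
    A <- array(0, shape)
    A[, , seq_len(x_split)] <- 1
    A <- gaussian_smooth(A, 0.7)
    sigma <- c(0.8, 0.8, 0.8)
    margin <- 5
    B <- array(0, shape)
    draw_centers <- function(m, x_lo, x_hi) {
      cbind(stats::runif(m, margin, shape[1] - margin),
            stats::runif(m, margin, shape[2] - margin),
            stats::runif(m, x_lo, x_hi))
    }
    cin <- draw_centers(n_in, margin, x_split - margin)
    cout <- draw_centers(n_out, x_split + margin, shape[3] - margin)
    centers <- rbind(cin, cout)
    amp <- 1 + 0.2 * stats::runif(n_clusters, -1, 1)
    for (i in seq_len(n_clusters)) {
      B <- add_gaussian_blob(B, centers[i, ], sigma, amp[i])
    }
    list(A = A, B = B,
         truth = list(mode = mode, overlap_fraction = n_in / n_clusters,
                      n_clusters = n_clusters, centers_vox = centers,
                      inside = rep(c(TRUE, FALSE), c(n_in, n_out)),
                      seed = seed))
  }
}

#' Generate a 3D cluster field with a known interface plane
#'
#' Plants Gaussian blobs at specified depths from a synthetic interface
#' plane, together with an APC channel whose intensity falls through
#' half-maximum exactly at the interface. The APC occupies low x, the T cell
#' high x; the interface normal is `+x`.
#'
#' @param depth_list_um cluster depths into the T cell (um); one blob each.
#' @param sigma_um blob sd (um, isotropic).
#' @param volume_shape `c(nz, ny, nx)`.
#' @param voxel_um voxel sizes `c(dz, dy, dx)`.
#' @param interface_x_um physical x of the interface plane; default 30% into
#'   the volume.
#' @param edge_sigma_um softness of the APC edge.
#' @param seed integer seed (controls in-plane blob placement).
#' @return list with `volume` (cluster channel), `apc` (APC channel),
#'   `frame` (an `interface_frame`), `truth` (planted centers and depths).
#' @export
gen_cluster_field <- function(depth_list_um, sigma_um = 0.4,
                              volume_shape = c(24, 48, 48),
                              voxel_um = c(0.4, 0.4, 0.4),
                              interface_x_um = NULL, edge_sigma_um = 0.2,
                              seed = 0) {
  set.seed(seed)
  dm <- volume_shape
  x0 <- interface_x_um %||% (0.3 * (dm[3] - 1) * voxel_um[3])
  n <- length(depth_list_um)
  vol <- array(0, dm)
  centers <- NULL
  if (n > 0) {
    # spread blobs in-plane on a jittered grid so separations stay large
    gz <- stats::runif(n, 0.3, 0.7) * (dm[1] - 1) * voxel_um[1]
    gy <- (seq_len(n) - 0.5) / n * (dm[2] - 1) * voxel_um[2]
    gy <- gy + stats::runif(n, -0.2, 0.2) * (dm[2] - 1) * voxel_um[2] / n
    centers <- cbind(z_um = gz, y_um = gy, x_um = x0 + depth_list_um)
    for (i in seq_len(n)) {
      vol <- add_gaussian_blob(vol, centers[i, ] / voxel_um + 1,
                               rep(sigma_um, 3) / voxel_um, 1)
    }
  }
  xx <- (seq_len(dm[3]) - 1) * voxel_um[3]
  apc_profile <- stats::pnorm((x0 - xx) / edge_sigma_um)
  apc <- array(rep(apc_profile, each = dm[1] * dm[2]), dm)
  frame <- make_interface_frame(
    point = c((dm[1] - 1) / 2 * voxel_um[1], (dm[2] - 1) / 2 * voxel_um[2], x0),
    normal = c(0, 0, 1),
    diameter_um = (dm[2] - 1) * voxel_um[2])
  list(volume = vol, apc = apc, frame = frame,
       truth = list(centers_um = centers, depths_um = depth_list_um,
                    interface_x_um = x0, sigma_um = sigma_um, seed = seed))
}
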