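#' Time-resolved multi-channel image stack
#'
#' Container for 4D fluorescence data of a cell conjugate. Each channel is an
#' array indexed `(t, z, y, x)`; physical voxel sizes and the frame interval
#' live alongside. Voxel `[i, j, k]` (1-based) is centered at
#' `((i-1)*dz, (j-1)*dy, (k-1)*dx)` micrometers.
#'
#' @param channels named list of 4D numeric arrays `(t, z, y, x)`, all with
#'   identical dimensions and non-negative intensities.
#' @param voxel_um numeric `c(dz, dy, dx)` in micrometers, all positive.
#' @param dt_s frame interval in seconds.
#' @return object of class `image_stack4d`.
#' @export
image_stack4d <- function(channels, voxel_um, dt_s = 20) {
  if (is.null(names(channels)) || any(names(channels) == ""))
    stopf("channels must be a named list")
  dm <- dim(channels[[1]])
  if (length(dm) != 4) stopf("channel arrays must be 4D (t, z, y, x)")
  for (ch in channels) {
    if (!identical(dim(ch), dm)) stopf("all channels must share dimensions")
    if (any(ch < 0, na.rm = TRUE)) stopf("intensities must be >= 0")
  }
  if (length(voxel_um) != 3 || any(voxel_um <= 0))
    stopf("voxel_um must be positive (dz, dy, dx)")
  structure(list(channels = channels, voxel_um = as.numeric(voxel_um),
                 dt_s = dt_s, dim = dm),
            class = "image_stack4d")
}

#' @export
print.image_stack4d <- function(x, ...) {
  cat(sprintf(
    "<image_stack4d> %d frame(s) x %d z x %d y x %d x, channels: %s\n  voxel %g x %g x %g um (dz,dy,dx), dt = %g s\n",
    x$dim[1], x$dim[2], x$dim[3], x$dim[4],
    paste(names(x$channels), collapse = ", "),
    x$voxel_um[1], x$voxel_um[2], x$voxel_um[3], x$dt_s))
  invisible(x)
}

#' Extract one timepoint of one channel as a (z, y, x) volume
#' @param stack an [image_stack4d].
#' @param channel channel name.
#' @param t frame index (1-based).
#' @return 3D numeric array.
#' @export
get_volume <- function(stack, channel, t = 1) {
  ch <- stack$channels[[channel]]
  if (is.null(ch)) stopf("no channel '%s' (have: %s)", channel,
                         paste(names(stack$channels), collapse = ", "))
  if (t < 1 || t > stack$dim[1]) stopf("frame %d out of range 1..%d", t, stack$dim[1])
  array(ch[t, , , ], stack$dim[2:4])
}

#' Segment the T cell and APC from a whole-cell channel
#'
#' Global threshold (Otsu by default) followed by 26-connected component
#' labeling; the two largest components are kept and assigned to T cell and
#' APC. Fully deterministic given the input volume.
#'
#' @param stack an [image_stack4d].
#' @param channel whole-cell channel name.
#' @param t frame index.
#' @param assign `"brighter"` (default; the brighter component is the T cell,
#'   matching a sensor-transduced T cell vs an unlabeled or counterstained
#'   APC) or `"smaller"`.
#' @param threshold optional fixed intensity threshold; default Otsu.
#' @param min_voxels components smaller than this are ignored.
#' @return object of class `cell_couple_scene` with logical `tcell_mask`,
#'   `apc_mask` (disjoint), `voxel_um`, `t`.
#' @export
segment_cells <- function(stack, channel = "cell", t = 1,
                          assign = c("brighter", "smaller"),
                          threshold = NULL, min_voxels = 30L) {
  assign <- match.arg(assign)
  vol <- get_volume(stack, channel, t)
  thr <- threshold %||% otsu_threshold(vol)
  mask <- vol >= thr
  lab <- label_components_3d(mask, 26L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  if (length(keep) < 2) stopf("no conjugate: found %d cell-sized component(s)",
                              length(keep))
  ord <- keep[order(sizes[keep], decreasing = TRUE)][1:2]
  m1 <- lab == ord[1]; m2 <- lab == ord[2]
  b1 <- mean(vol[m1]); b2 <- mean(vol[m2])
  tcell_first <- if (assign == "brighter") b1 >= b2 else sizes[ord[1]] <= sizes[ord[2]]
  scene <- list(
    tcell_mask = if (tcell_first) m1 else m2,
    apc_mask = if (tcell_first) m2 else m1,
    voxel_um = stack$voxel_um, t = t, threshold = thr
  )
  class(scene) <- "cell_couple_scene"
  scene
}

#' @export
print.cell_couple_scene <- function(x, ...) {
  cat(sprintf("<cell_couple_scene> T cell %d voxels, APC %d voxels (frame %d)\n",
              sum(x$tcell_mask), sum(x$apc_mask), x$t))
  invisible(x)
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit <- function(v) v / sqrt(sum(v^2))

#' Construct an interface coordinate frame directly
#'
#' Builds the interface-anchored frame used by all depth/radial measurements
#' without segmentation, e.g. for synthetic volumes with a known interface
#' plane. Coordinates are `(z, y, x)` micrometers.
#'
#' @param point a point on the interface plane.
#' @param normal plane normal, pointing into the T cell (unit-normalized here).
#' @param diameter_um interface diameter D.
#' @param center in-plane interface center; defaults to `point`.
#' @param e1 optional in-plane diameter axis; defaults to an arbitrary
#'   in-plane unit vector.
#' @return object of class `interface_frame`.
#' @export
make_interface_frame <- function(point, normal, diameter_um,
                                 center = point, e1 = NULL) {
  n <- unit(normal)
  if (is.null(e1)) {
    probe <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- unit(probe - sum(probe * n) * n)
  } else {
    e1 <- unit(e1 - sum(e1 * n) * n)
  }
  structure(list(p0 = point, normal = n, e1 = e1, e2 = unit(vec_cross(n, e1)),
                 center = center, endpoints = NULL, D_um = diameter_um),
            class = "interface_frame")
}

#' @export
print.interface_frame <- function(x, ...) {
  cat(sprintf("<interface_frame> D = %.2f um, normal (%.2f, %.2f, %.2f) [z,y,x]\n",
              x$D_um, x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Build the interface frame from a segmented cell couple
#'
#' Contact voxels are T cell boundary voxels within `gap_voxels` (Chebyshev)
#' of the APC mask. A least-squares plane is fitted through them; the normal
#' is oriented so the T cell centroid has positive depth. The interface
#' diameter D is the largest in-plane extent of the contact voxels; the
#' middle 50% of D is the center region, the outer 25% on each side the
#' periphery.
#'
#' @param scene a `cell_couple_scene`.
#' @param voxel_um voxel sizes; defaults to the scene's.
#' @param gap_um physical contact tolerance in micrometers (converted to
#'   per-axis voxel radii, at least one voxel per axis). The default 1 um
#'   absorbs the resolution-limited inter-membrane seam of fluorescence data
#'   (the 20 nm criterion is an EM-scale notion handled by
#'   [tight_contact_length()]).
#' @return an `interface_frame`.
#' @export
build_interface_frame <- function(scene, voxel_um = NULL, gap_um = 1.0) {
  voxel_um <- voxel_um %||% scene$voxel_um
  tb <- mask_boundary(scene$tcell_mask)
  tc_ijk <- which(scene$tcell_mask, arr.ind = TRUE)
  tc_centroid <- c(mean((tc_ijk[, 1] - 1) * voxel_um[1]),
                   mean((tc_ijk[, 2] - 1) * voxel_um[2]),
                   mean((tc_ijk[, 3] - 1) * voxel_um[3]))
  ap_ijk <- which(scene$apc_mask, arr.ind = TRUE)
  ap_centroid <- c(mean((ap_ijk[, 1] - 1) * voxel_um[1]),
                   mean((ap_ijk[, 2] - 1) * voxel_um[2]),
                   mean((ap_ijk[, 3] - 1) * voxel_um[3]))
  # apposed membranes face each other across the seam: bridge the gap
  # tolerance along the dominant cell-cell axis; a one-voxel Chebyshev
  # dilation covers tilted or touching configurations
  axis <- which.max(abs(tc_centroid - ap_centroid) / voxel_um)
  r_axis <- max(1L, round(gap_um / voxel_um[axis]))
  r_vec <- integer(3); r_vec[axis] <- r_axis
  near_apc <- dilate_mask(scene$apc_mask, r_vec) |
    dilate_mask(scene$apc_mask, 1L)
  contact <- tb & near_apc
  n_contact <- sum(contact)
  if (n_contact == 0) stopf("no interface: no T cell boundary voxel within %g um of the APC",
                            gap_um)
  ijk <- which(contact, arr.ind = TRUE)
  P <- cbind((ijk[, 1] - 1) * voxel_um[1], (ijk[, 2] - 1) * voxel_um[2],
             (ijk[, 3] - 1) * voxel_um[3])
  p0 <- colMeans(P)
  if (n_contact >= 3) {
    sv <- svd(sweep(P, 2, p0))
    normal <- sv$v[, 3]
    # inlier refinement: drop boundary voxels curving away from the contact
    # plane (beyond ~0.6 normal voxel pitches of the median plane offset)
    pitch_n <- sum(abs(normal) * voxel_um)
    d0 <- sweep(P, 2, p0) %*% normal
    keep <- abs(d0 - stats::median(d0)) <= 0.6 * pitch_n
    if (sum(keep) >= 3 && sum(keep) < n_contact) {
      P <- P[keep, , drop = FALSE]
      p0 <- colMeans(P)
      sv <- svd(sweep(P, 2, p0))
      normal <- sv$v[, 3]
    }
  } else {
    normal <- tc_centroid - p0
  }
  if (sum((tc_centroid - p0) * normal) < 0) normal <- -normal
  normal <- unit(normal)
  # contact voxels are T cell boundary voxel *centers*; the membrane lies half
  # a voxel further toward the APC, so shift the plane accordingly
  p0 <- p0 - 0.5 * sum(abs(normal) * voxel_um) * normal

  # in-plane projection; farthest pair over the convex hull
  probe <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a1 <- unit(probe - sum(probe * normal) * normal)
  a2 <- unit(vec_cross(normal, a1))
  S <- cbind((P - rep(p0, each = nrow(P))) %*% a1,
             (P - rep(p0, each = nrow(P))) %*% a2)
  idx_pair <- farthest_pair(S)
  ep <- P[idx_pair, , drop = FALSE]
  D <- sqrt(sum((ep[1, ] - ep[2, ])^2))
  center <- (ep[1, ] + ep[2, ]) / 2
  e1 <- if (D > 0) unit(ep[2, ] - ep[1, ] - sum((ep[2, ] - ep[1, ]) * normal) * normal) else a1
  structure(list(p0 = p0, normal = normal, e1 = e1,
                 e2 = unit(vec_cross(normal, e1)), center = center,
                 endpoints = ep, D_um = D, n_contact = n_contact),
            class = "interface_frame")
}

farthest_pair <- function(S) {
  n <- nrow(S)
  if (n == 1) return(c(1L, 1L))
  cand <- seq_len(n)
  if (n > 8) {
    h <- unique(grDevices::chull(S[, 1], S[, 2]))
    if (length(h) >= 2) cand <- h
  }
  best <- c(cand[1], cand[1]); bd <- -1
  for (i in seq_along(cand)) {
    d2 <- (S[cand, 1] - S[cand[i], 1])^2 + (S[cand, 2] - S[cand[i], 2])^2
    j <- which.max(d2)
    if (d2[j] > bd) { bd <- d2[j]; best <- c(cand[i], cand[j]) }
  }
  best
}

#' Interface-frame coordinates of points
#'
#' @param frame an `interface_frame`.
#' @param Q n x 3 matrix of `(z, y, x)` coordinates in micrometers.
#' @return list with `delta` (um into the T cell from the interface plane),
#'   `u`, `v` (in-plane coordinates relative to the interface center, `u`
#'   along the diameter axis), `r` (in-plane radial distance) and `rho`
#'   (`r / (D/2)`, 0 = center, 1 = interface edge).
#' @export
frame_coords <- function(frame, Q) {
  Q <- matrix(Q, ncol = 3)
  d0 <- sweep(Q, 2, frame$p0)
  dc <- sweep(Q, 2, frame$center)
  u <- as.vector(dc %*% frame$e1)
  v <- as.vector(dc %*% frame$e2)
  r <- sqrt(u^2 + v^2)
  list(delta = as.vector(d0 %*% frame$normal), u = u, v = v, r = r,
       rho = if (frame$D_um > 0) r / (frame$D_um / 2) else r * Inf)
}

# (z,y,x) um coordinates of all voxels of a volume with given dims
volume_coord_matrix <- function(dimv, voxel_um) {
  ijk <- arrayInd(seq_len(prod(dimv)), dimv)
  cbind((ijk[, 1] - 1) * voxel_um[1], (ijk[, 2] - 1) * voxel_um[2],
        (ijk[, 3] - 1) * voxel_um[3])
}

#' Extract midplane contours of both cells
#'
#' Takes the midplane z-slice of each mask, lightly smooths it and traces the
#' 0.5 level set (marching squares via [grDevices::contourLines()]). Interface
#' endpoints are marked where the two outlines diverge beyond the gap
#' tolerance.
#'
#' @param scene a `cell_couple_scene`.
#' @param z_mid midplane z index; default the rounded mid z of the T cell mask.
#' @param voxel_um voxel sizes; defaults to the scene's.
#' @param gap_um_tol divergence tolerance in micrometers; default 3 in-plane
#'   pixels here (the masks are separated by a resolution-limited seam).
#' @return list with `tcell` and `apc` [contour2d] objects (x = image x axis,
#'   y = image y axis, micrometers).
#' @export
extract_midplane_contours <- function(scene, z_mid = NULL, voxel_um = NULL,
                                      gap_um_tol = NULL) {
  voxel_um <- voxel_um %||% scene$voxel_um
  if (!any(scene$tcell_mask) || !any(scene$apc_mask)) stopf("empty mask")
  if (is.null(z_mid)) {
    zr <- range(which(apply(scene$tcell_mask, 1, any)))
    z_mid <- round(mean(zr))
  }
  tc <- scene$tcell_mask[z_mid, , ] + 0
  ap <- scene$apc_mask[z_mid, , ] + 0
  contours_from_masks(tc, ap, pixel_um = voxel_um[2:3],
                      gap_um_tol = gap_um_tol %||% (3 * max(voxel_um[2:3])),
                      blur_px = 0.8)
}

#' Trace paired cell outlines from 2D midplane images
#'
#' Workhorse behind [extract_midplane_contours()], also usable on rendered
#' occupancy images (see [render_contour_mask()]). Binary inputs are smoothed
#' with a small Gaussian before contouring; graded (anti-aliased or
#' fluorescence) inputs are contoured directly at half their maximum.
#'
#' @param tc_img,apc_img matrices (rows = y, cols = x), logical or numeric.
#' @param pixel_um pixel size, scalar or `c(dy, dx)`.
#' @param origin_um `c(x0, y0)` of pixel `[1,1]` center; default taken from an
#'   `origin_um` attribute or `c(0, 0)`.
#' @param gap_um_tol interface divergence tolerance; default half a pixel
#'   (outlines extracted from the same image coincide along the interface to
#'   sub-pixel precision, so the tolerance only absorbs extraction noise; use
#'   a larger value when the masks are separated by a visible seam).
#' @param blur_px Gaussian sigma (pixels) applied to binary inputs.
#' @return list with `tcell` and `apc` [contour2d] objects, interface
#'   endpoints marked on both.
#' @export
contours_from_masks <- function(tc_img, apc_img, pixel_um = 0.4,
                                origin_um = NULL, gap_um_tol = NULL,
                                blur_px = 0.8) {
  if (length(pixel_um) == 1) pixel_um <- c(pixel_um, pixel_um)
  # floor of 0.1 um: apposed membranes sit within ~50 nm of each other, so
  # sub-pixel tolerances below that would fragment the interface at EM scale
  tol <- gap_um_tol %||% max(0.5 * max(pixel_um), 0.1)
  o_t <- attr(tc_img, "origin_um") %||% origin_um %||% c(0, 0)
  o_a <- attr(apc_img, "origin_um") %||% origin_um %||% c(0, 0)
  tc_xy <- trace_outline(tc_img, pixel_um, o_t, blur_px)
  ap_xy <- trace_outline(apc_img, pixel_um, o_a, blur_px)
  tc_flag <- pts_polyline_dist(tc_xy, ap_xy) < tol
  ap_flag <- pts_polyline_dist(ap_xy, tc_xy) < tol
  list(tcell = mark_interface(tc_xy, tc_flag),
       apc = mark_interface(ap_xy, ap_flag))
}

trace_outline <- function(img, pixel_um, origin_um, blur_px) {
  m <- img + 0
  if (!any(m > 0)) stopf("empty mask")
  binary <- all(m %in% c(0, 1))
  if (binary && blur_px > 0) m <- gaussian_smooth(m, blur_px)
  lev <- max(m) / 2
  yy <- origin_um[2] + (seq_len(nrow(m)) - 1) * pixel_um[1]
  xx <- origin_um[1] + (seq_len(ncol(m)) - 1) * pixel_um[2]
  cl <- grDevices::contourLines(yy, xx, m, levels = lev)
  if (length(cl) == 0) stopf("no outline at level %g", lev)
  lens <- vapply(cl, function(l) polyline_length(cbind(l$y, l$x)), 0)
  l <- cl[[which.max(lens)]]
  xy <- cbind(l$y, l$x)  # back to (x_um, y_um)
  if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  xy
}

# minimum distance from each point to a polyline (closed by default)
pts_polyline_dist <- function(P, Q, closed = TRUE) {
  n <- nrow(Q)
  if (closed) {
    A <- Q
    B <- Q[c(2:n, 1), , drop = FALSE]
  } else {
    A <- Q[-n, , drop = FALSE]
    B <- Q[-1, , drop = FALSE]
  }
  AB <- B - A
  len2 <- rowSums(AB^2)
  len2[len2 == 0] <- 1e-300
  out <- numeric(nrow(P))
  for (i in seq_len(nrow(P))) {
    ap1 <- P[i, 1] - A[, 1]; ap2 <- P[i, 2] - A[, 2]
    tt <- pmin(1, pmax(0, (ap1 * AB[, 1] + ap2 * AB[, 2]) / len2))
    dx <- ap1 - tt * AB[, 1]; dy <- ap2 - tt * AB[, 2]
    out[i] <- sqrt(min(dx * dx + dy * dy))
  }
  out
}

# rotate a closed-vertex cycle so the longest TRUE run starts at vertex 1
mark_interface <- function(xy, flag) {
  n <- length(flag)
  if (!any(flag)) return(contour2d(xy, closed = TRUE, interface_idx = NULL))
  if (all(flag)) return(contour2d(xy, closed = TRUE, interface_idx = c(1L, n)))
  f2 <- c(flag, flag)
  r <- rle(f2)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & starts <= n)
  li <- ok[which.max(r$lengths[ok])]
  a <- starts[li]; len <- min(r$lengths[li], n)
  ord <- ((a - 1 + 0:(n - 1)) %% n) + 1
  contour2d(xy[ord, , drop = FALSE], closed = TRUE,
            interface_idx = c(1L, as.integer(len)))
}
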