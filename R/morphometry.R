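#' Interface arc length, diameter and undulation ratio
#'
#' The interface length L is the polyline arc length of the membrane between
#' the marked interface endpoints; the diameter D is the straight (chord)
#' distance between them. Their ratio quantifies interface undulation; the
#' isotropic extrapolation `ratio^2` estimates the fold-increase in contact
#' membrane area.
#'
#' @param tc_contour a [contour2d] with `interface_idx` set.
#' @return object of class `interface_morphometry` with fields `L_um`, `D_um`,
#'   `ratio`, `area_fold`.
#' @export
interface_length_diameter <- function(tc_contour) {
  idx <- tc_contour$interface_idx
  if (is.null(idx)) stopf("contour has no interface endpoints marked")
  xy <- tc_contour$xy[idx[1]:idx[2], , drop = FALSE]
  if (nrow(xy) < 2) stopf("interface segment needs >= 2 vertices")
  D <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  if (D == 0) stopf("interface endpoints coincide")
  L <- polyline_length(xy)
  structure(list(L_um = L, D_um = D, ratio = L / D, area_fold = (L / D)^2),
            class = "interface_morphometry")
}

#' @export
print.interface_morphometry <- function(x, ...) {
  cat(sprintf("<interface_morphometry> L = %.3f um, D = %.3f um, L/D = %.3f (area fold %.2f)\n",
              x$L_um, x$D_um, x$ratio, x$area_fold))
  invisible(x)
}

#' Length of tight membrane contact (< 20 nm gap)
#'
#' Sums the T cell interface arc whose nearest-point distance to the APC
#' membrane is below `gap_nm` (a gap spannable by TCR/MHC pairs). Per-vertex
#' distances; partial segments at threshold crossings are linearly
#' interpolated.
#'
#' @param tc_contour,apc_contour [contour2d] objects; if interface endpoints
#'   are marked, only those segments are used.
#' @param gap_nm gap threshold in nanometers.
#' @return tight-contact length in micrometers.
#' @export
tight_contact_length <- function(tc_contour, apc_contour, gap_nm = 20) {
  tx <- contour_interface_xy(tc_contour)
  ax <- contour_interface_xy(apc_contour)
  open_seg <- !is.null(apc_contour$interface_idx)
  d <- pts_polyline_dist(tx, ax, closed = !open_seg)
  gap <- gap_nm / 1000
  seg <- sqrt(rowSums(diff(tx)^2))
  d1 <- d[-length(d)]; d2 <- d[-1]
  both_in <- d1 < gap & d2 < gap
  cross <- xor(d1 < gap, d2 < gap)
  frac <- ifelse(cross, (gap - pmin(d1, d2)) / abs(d2 - d1), 0)
  sum(seg[both_in]) + sum(seg[cross] * frac[cross])
}

contour_interface_xy <- function(contour) {
  if (!is.null(contour$interface_idx)) {
    contour$xy[contour$interface_idx[1]:contour$interface_idx[2], , drop = FALSE]
  } else contour$xy
}

#' Extrapolate an interface length ratio to an area fold-increase
#'
#' Isotropic extrapolation of a 1D undulation measured in a single z-plane to
#' the 2D contact surface: the area fold is the square of the length ratio.
#'
#' @param ratio interface length / diameter ratio.
#' @return `ratio^2`.
#' @export
area_fold_from_length_ratio <- function(ratio) ratio^2

#' Depth-intensity profile away from the interface
#'
#' Box-scan analog: mean intensity in successive slabs
#' `[i*step, (i+1)*step)` of depth into the T cell, restricted in-plane to
#' the full interface, its center (middle 50% of the diameter) or its
#' periphery (outer 25% on each side).
#'
#' @param vol 3D `(z, y, x)` volume.
#' @param frame an `interface_frame`.
#' @param region `"full"`, `"center"` or `"periphery"`.
#' @param step_um slab thickness (default 0.5, the live-imaging box step;
#'   use 0.25 for STED-scale data).
#' @param voxel_um voxel sizes `c(dz, dy, dx)`.
#' @param mode `"relative_max"` (profile divided by its maximum) or
#'   `"pct_above_bg"` (`100 * (mean/bg - 1)`; requires `bg`).
#' @param bg cellular background level (required for `"pct_above_bg"`).
#' @param max_depth_um deepest slab edge.
#' @param mask optional logical volume (e.g. the T cell mask) intersected
#'   with the region.
#' @return object of class `depth_profile`: `depth_um` (bin centers),
#'   `value`, `raw_mean`, `n_voxels` per bin, plus the settings used.
#' @export
depth_profile <- function(vol, frame, region = c("full", "center", "periphery"),
                          step_um = 0.5, voxel_um, mode = c("relative_max",
                          "pct_above_bg"), bg = NULL, max_depth_um = 6,
                          mask = NULL) {
  region <- match.arg(region)
  mode <- match.arg(mode)
  if (mode == "pct_above_bg" && (is.null(bg) || bg <= 0))
    stopf("pct_above_bg mode needs a positive bg")
  dm <- dim(vol)
  co <- frame_coords(frame, volume_coord_matrix(dm, voxel_um))
  sel <- co$delta >= 0 & co$delta < max_depth_um & co$rho <= 1
  sel <- sel & switch(region, full = TRUE, center = co$rho <= 0.5,
                      periphery = co$rho > 0.5)
  if (!is.null(mask)) sel <- sel & as.vector(mask)
  if (!any(sel)) stopf("no voxels in region '%s'", region)
  bin <- floor(co$delta[sel] / step_um)
  vals <- as.vector(vol)[sel]
  n_bins <- max(bin) + 1
  raw <- vapply(0:(n_bins - 1), function(b) mean(vals[bin == b]), 0)
  n_vox <- vapply(0:(n_bins - 1), function(b) sum(bin == b), 0L)
  value <- switch(mode,
                  relative_max = raw / max(raw),
                  pct_above_bg = 100 * (raw / bg - 1))
  structure(list(depth_um = (0:(n_bins - 1) + 0.5) * step_um, value = value,
                 raw_mean = raw, n_voxels = n_vox, mode = mode,
                 region = region, step_um = step_um, bg = bg),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> region %s, %d bins of %.2f um (%s)\n",
              x$region, length(x$value), x$step_um, x$mode))
  print(round(stats::setNames(x$value, sprintf("%.2f", x$depth_um)), 3))
  invisible(x)
}

#' @export
plot.depth_profile <- function(x, ...) {
  graphics::plot(x$depth_um, x$value, type = "b", xlab = "depth into T cell (um)",
                 ylab = if (x$mode == "relative_max") "intensity (rel. max)"
                        else "% above background", ...)
  invisible(x)
}

#' Depth at which a profile falls to half its maximum
#'
#' First depth past the profile peak at which the value drops below half the
#' maximum, linearly interpolated between bins.
#'
#' @param profile a `depth_profile` (or anything with `depth_um` and `value`).
#' @return depth in micrometers.
#' @export
half_max_depth <- function(profile) {
  x <- first_falling_crossing(profile$depth_um, profile$value,
                              max(profile$value) / 2)
  if (is.na(x)) stopf("half-maximum not reached within the profiled depth")
  x
}

#' Measure an elongated structure by FWHM line scans
#'
#' Two line scans through the intensity peak of a structure: perpendicular to
#' the interface (depth, image y axis; the interface is assumed horizontal)
#' and parallel to it (width, x axis). The full width at half maximum of the
#' background-subtracted profile is taken with linear interpolation between
#' samples. Structures whose peak is below `qualify_fold * bg` are rejected
#' (returns `NULL`).
#'
#' @param image2d matrix (rows = y, cols = x).
#' @param structure_seed approximate `c(x_um, y_um)` position of the
#'   structure.
#' @param bg cellular background intensity.
#' @param qualify_fold qualification threshold on peak/background (default
#'   1.35, i.e. 135% of background).
#' @param pixel_um pixel size, scalar or `c(dy, dx)`.
#' @param search_um half-width of the window in which the peak is located
#'   around the seed.
#' @return object of class `structure_measure` with `depth_um`, `width_um`,
#'   `ratio`, `peak`, `integrated_intensity`, `area_um2`,
#'   `intensity_area_ratio`; or `NULL` if the structure does not qualify.
#' @export
measure_structure_fwhm <- function(image2d, structure_seed, bg,
                                   qualify_fold = 1.35, pixel_um = 0.025,
                                   search_um = 0.5) {
  if (length(pixel_um) == 1) pixel_um <- c(pixel_um, pixel_um)
  ny <- nrow(image2d); nx <- ncol(image2d)
  sx <- 1 + structure_seed[1] / pixel_um[2]
  sy <- 1 + structure_seed[2] / pixel_um[1]
  wy <- max(1, ceiling(search_um / pixel_um[1]))
  wx <- max(1, ceiling(search_um / pixel_um[2]))
  ys <- max(1, round(sy) - wy):min(ny, round(sy) + wy)
  xs <- max(1, round(sx) - wx):min(nx, round(sx) + wx)
  win <- image2d[ys, xs, drop = FALSE]
  pk <- which(win == max(win), arr.ind = TRUE)[1, ]
  py <- ys[pk[1]]; px <- xs[pk[2]]
  peak <- image2d[py, px]
  if (peak < qualify_fold * bg) return(NULL)

  prof_y <- image2d[, px] - bg
  prof_x <- image2d[py, ] - bg
  depth <- profile_fwhm((seq_len(ny) - 1) * pixel_um[1], prof_y, py)
  width <- profile_fwhm((seq_len(nx) - 1) * pixel_um[2], prof_x, px)

  # half-max footprint: pixels above bg + (peak-bg)/2 connected to the peak
  half_level <- bg + (peak - bg) / 2
  above <- image2d >= half_level
  lab <- label_components_3d(array(above, c(1, ny, nx)), 26L)
  fp <- lab[1, , ] == lab[1, py, px]
  area <- sum(fp) * pixel_um[1] * pixel_um[2]
  integ <- sum(image2d[fp] - bg)
  structure(list(depth_um = depth, width_um = width, ratio = depth / width,
                 peak = peak, peak_xy_um = c((px - 1) * pixel_um[2],
                                             (py - 1) * pixel_um[1]),
                 integrated_intensity = integ, area_um2 = area,
                 intensity_area_ratio = mean(image2d[fp] - bg) / area),
            class = "structure_measure")
}

#' @export
print.structure_measure <- function(x, ...) {
  cat(sprintf("<structure_measure> depth %.3f um, width %.3f um, depth/width %.2f\n",
              x$depth_um, x$width_um, x$ratio))
  invisible(x)
}

# FWHM of a background-subtracted profile around sample index `peak_i`,
# linear interpolation at the half-max crossings on both flanks.
profile_fwhm <- function(x, y, peak_i) {
  half <- y[peak_i] / 2
  left <- NA_real_
  for (i in peak_i:2) {
    if (y[i - 1] < half) {
      left <- x[i] + (half - y[i]) / (y[i - 1] - y[i]) * (x[i - 1] - x[i])
      break
    }
  }
  right <- NA_real_
  if (peak_i < length(y)) {
    for (i in peak_i:(length(y) - 1)) {
      if (y[i + 1] < half) {
        right <- x[i] + (half - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) stopf("unbounded structure: profile does not drop below half-maximum inside the scan window")
  right - left
}

#' Stage a cell couple as early or late
#'
#' Fluorescence rule: early iff a distinct uropod is present OR the T cell
#' elongation (interface-to-posterior length over widest extent parallel to
#' the interface) exceeds 1.25. EM rule: early iff at least two of {uropod,
#' elongation > 1.25, nucleus-to-interface distance > 1 um} hold.
#'
#' @param uropod_present logical.
#' @param elongation T cell length/diameter ratio (> 0).
#' @param nucleus_distance_um nucleus-to-interface distance (EM rule only).
#' @param rule `"fluorescence"` or `"em"`.
#' @param elongation_cut,nucleus_cut_um staging thresholds.
#' @return object of class `stage_call` with `stage` (`"early"`/`"late"`) and
#'   the criteria flags consulted.
#' @export
stage_call <- function(uropod_present, elongation, nucleus_distance_um = NULL,
                       rule = c("fluorescence", "em"),
                       elongation_cut = 1.25, nucleus_cut_um = 1.0) {
  rule <- match.arg(rule)
  if (elongation <= 0) stopf("elongation must be > 0")
  flags <- c(uropod = isTRUE(uropod_present),
             elongation = elongation > elongation_cut)
  if (rule == "em") {
    if (is.null(nucleus_distance_um)) stopf("EM rule needs nucleus_distance_um")
    flags["nucleus"] <- nucleus_distance_um > nucleus_cut_um
    stage <- if (sum(flags) >= 2) "early" else "late"
  } else {
    stage <- if (any(flags)) "early" else "late"
  }
  structure(list(stage = stage, flags = flags, rule = rule,
                 elongation = elongation,
                 nucleus_distance_um = nucleus_distance_um),
            class = "stage_call")
}

#' @export
print.stage_call <- function(x, ...) {
  cat(sprintf("<stage_call> %s (%s rule; %s)\n", x$stage, x$rule,
              paste(names(x$flags)[x$flags], collapse = "+")))
  invisible(x)
}
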