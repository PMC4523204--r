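#' 2D membrane contour
#'
#' Ordered polyline of membrane vertices in micrometers, as traced from EM
#' micrographs or extracted from fluorescence midplanes. The interface segment
#' (the stretch apposed to the partner cell) is marked by the indices of its
#' first and last vertex.
#'
#' @param xy two-column numeric matrix (x_um, y_um) of ordered vertices.
#' @param closed logical; closed contours need at least 3 vertices.
#' @param interface_idx integer vector `c(first, last)` vertex index of the
#'   interface segment, or `NULL` if unmarked.
#' @return object of class `contour2d`.
#' @export
contour2d <- function(xy, closed = TRUE, interface_idx = NULL) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2) stopf("xy must have two columns (x_um, y_um)")
  if (closed && nrow(xy) < 3) stopf("closed contour needs >= 3 vertices")
  seg <- sqrt(rowSums(diff(xy)^2))
  if (any(seg == 0)) {
    keep <- c(TRUE, seg > 0)
    xy <- xy[keep, , drop = FALSE]
  }
  if (!is.null(interface_idx)) interface_idx <- as.integer(interface_idx)
  structure(list(xy = xy, closed = closed, interface_idx = interface_idx),
            class = "contour2d")
}

#' @export
print.contour2d <- function(x, ...) {
  cat(sprintf("<contour2d> %d vertices%s%s\n", nrow(x$xy),
              if (x$closed) ", closed" else ", open",
              if (!is.null(x$interface_idx))
                sprintf(", interface vertices %d..%d",
                        x$interface_idx[1], x$interface_idx[2]) else ""))
  invisible(x)
}

# arc/chord ratio of y = A*sin(m*pi*x/D) sampled at the emission density;
# solved by uniroot so that what the morphometry op measures on the emitted
# polyline is the requested ratio.
sine_ratio <- function(A, D, m, n_points) {
  x <- seq(0, D, length.out = n_points)
  y <- A * sin(m * pi * x / D)
  polyline_length(cbind(x, y)) / D
}

#' Preset geometries for contour generation
#'
#' Emulation presets for the four measured conditions: EM micrographs of early
#' (1-2 min) and late (2-5 min) conjugates, and CFSE live midplanes at 20 s and
#' 3 min after tight coupling. Ratios are the population means reported for
#' each condition; undulation frequency ranges reflect the imaging resolution
#' (EM resolves many fine undulations, the 100x live images only coarse ones).
#' Tight-contact fractions are chosen so that absolute tight-contact length is
#' comparable early and late while total interface length shrinks.
#'
#' @return named list of preset parameter lists.
#' @export
contour_presets <- function() {
  list(
    em_early   = list(ratio = 2.10, diameter_um = 8, cycles = 8:13,
                      tight_fraction = 0.43, tight_nm = 12, loose_nm = 45),
    em_late    = list(ratio = 1.50, diameter_um = 8, cycles = 6:10,
                      tight_fraction = 0.60, tight_nm = 12, loose_nm = 45),
    live_early = list(ratio = 1.35, diameter_um = 8, cycles = 2:3,
                      tight_fraction = 0.5, tight_nm = 12, loose_nm = 45),
    live_late  = list(ratio = 1.05, diameter_um = 8, cycles = 2:3,
                      tight_fraction = 0.5, tight_nm = 12, loose_nm = 45)
  )
}

#' Generate a paired T cell / APC midplane contour with known undulation
#'
#' Builds two apposed closed polylines sharing an undulating interface
#' segment. The undulation is a single-frequency sinusoid whose amplitude is
#' solved numerically so the arc-length/chord ratio of the emitted polyline
#' equals `ratio`. The inter-membrane gap along the interface follows a
#' piecewise profile in which a target fraction of the T cell arc lies closer
#' than 20 nm to the APC membrane (tight contact).
#'
#' @param ratio target arc/chord ratio (>= 1).
#' @param diameter_um straight interface diameter (chord), micrometers.
#' @param gap_profile list with `tight_fraction` (fraction of arc in tight
#'   contact), `tight_nm`, `loose_nm` (gap widths inside/outside tight
#'   stretches).
#' @param seed integer seed; controls undulation frequency, phase sign and the
#'   placement of tight-contact stretches.
#' @param preset optional name from [contour_presets()]; overrides `ratio`,
#'   `diameter_um` and `gap_profile`.
#' @param n_cycles number of sine half-periods across the interface; default
#'   drawn from the preset range.
#' @param shape `"sinusoid"` (default) or `"semicircle"` (interface bows as a
#'   half circle, ratio fixed at pi/2; `ratio` is ignored).
#' @param n_points vertices along the interface segment.
#' @return list with `tcell` and `apc` [contour2d] objects and `truth`
#'   (requested ratio, realized arc, tight fraction and length, seed).
#' @export
gen_interface_contours <- function(ratio = 2.1, diameter_um = 8,
                                   gap_profile = list(tight_fraction = 0.5,
                                                      tight_nm = 12,
                                                      loose_nm = 45),
                                   seed = 0, preset = NULL, n_cycles = NULL,
                                   shape = c("sinusoid", "semicircle"),
                                   n_points = 1601) {
  shape <- match.arg(shape)
  cycles_range <- 6:12
  if (!is.null(preset)) {
    p <- contour_presets()[[preset]]
    if (is.null(p)) stopf("unknown preset '%s'", preset)
    ratio <- p$ratio; diameter_um <- p$diameter_um; cycles_range <- p$cycles
    gap_profile <- list(tight_fraction = p$tight_fraction,
                        tight_nm = p$tight_nm, loose_nm = p$loose_nm)
  }
  if (ratio < 1) stopf("ratio must be >= 1, got %g", ratio)
  D <- diameter_um
  rng <- local({ set.seed(seed); list(m = if (is.null(n_cycles))
      sample(cycles_range, 1) else n_cycles,
    flip = sample(c(-1, 1), 1), u = runif(8)) })
  x <- seq(0, D, length.out = n_points)

  if (shape == "semicircle") {
    th <- seq(pi, 0, length.out = n_points)
    # bows toward the APC side (-y)
    iface <- cbind(D / 2 + D / 2 * cos(th), -D / 2 * sin(th))
  } else if (ratio == 1) {
    iface <- cbind(x, rep(0, n_points))
  } else {
    m <- rng$m
    a_max <- D
    if (sine_ratio(a_max, D, m, n_points) < ratio)
      stopf("ratio %g unreachable at max amplitude for %d half-cycles", ratio, m)
    A <- uniroot(function(a) sine_ratio(a, D, m, n_points) - ratio,
                 c(0, a_max), tol = 1e-10)$root
    iface <- cbind(x, rng$flip * A * sin(m * pi * x / D))
  }

  # gap profile along interface arc length: contiguous tight stretches
  seg <- sqrt(rowSums(diff(iface)^2))
  s <- c(0, cumsum(seg))
  L <- s[n_points]
  f_tight <- gap_profile$tight_fraction %||% 0.5
  tight <- rep(FALSE, n_points)
  if (f_tight > 0) {
    # one tight window per quarter of the arc, jittered within its slot
    n_win <- 4L
    len <- f_tight / n_win
    slot <- (seq_len(n_win) - 1) / n_win
    starts <- slot + (1 / n_win - len) * rng$u[seq_len(n_win)]
    for (w in seq_len(n_win)) {
      tight <- tight | (s / L >= starts[w] & s / L < starts[w] + len)
    }
  }
  gap_um <- ifelse(tight, gap_profile$tight_nm %||% 12,
                   gap_profile$loose_nm %||% 45) / 1000

  # vertex normals pointing toward the APC (-y side for a flat interface)
  tang <- rbind(iface[2, ] - iface[1, ],
                iface[3:n_points, ] - iface[1:(n_points - 2), ],
                iface[n_points, ] - iface[n_points - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  nrm <- cbind(tang[, 2], -tang[, 1])
  apc_iface <- iface + gap_um * nrm

  back_t <- {
    th <- seq(0, pi, length.out = 257)[2:256]
    cbind(D / 2 + D / 2 * cos(th), D / 2 * sin(th))
  }
  back_a <- {
    th <- seq(0, pi, length.out = 257)[2:256]
    cbind(D / 2 + D / 2 * cos(th), -D / 2 * sin(th) - mean(gap_um))
  }
  # back_t runs right-to-left (th 0..pi), closing the polygon after iface
  tc <- contour2d(rbind(iface, back_t), closed = TRUE,
                  interface_idx = c(1L, n_points))
  ap <- contour2d(rbind(apc_iface, back_a), closed = TRUE,
                  interface_idx = c(1L, n_points))

  tight_um <- sum(seg[tight[-n_points] & tight[-1]])
  list(tcell = tc, apc = ap,
       truth = list(ratio = if (shape == "semicircle") pi / 2 else ratio,
                    diameter_um = D, arc_um = L,
                    tight_fraction = tight_um / L, tight_um = tight_um,
                    gap_tight_nm = gap_profile$tight_nm %||% 12,
                    gap_loose_nm = gap_profile$loose_nm %||% 45,
                    shape = shape, seed = seed))
}

# --- rasterization ----------------------------------------------------------

# Even-odd scanline test: for each (px, py) row/col grid, fraction of
# supersampled points inside the closed polygon.
polygon_coverage <- function(xy, x_centers, y_centers, supersample = 3L) {
  n <- nrow(xy)
  x1 <- xy[, 1]; y1 <- xy[, 2]
  x2 <- xy[c(2:n, 1), 1]; y2 <- xy[c(2:n, 1), 2]
  sub <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  dxc <- if (length(x_centers) > 1) diff(x_centers)[1] else 1
  dyc <- if (length(y_centers) > 1) diff(y_centers)[1] else 1
  cov <- matrix(0, length(y_centers), length(x_centers))
  xs_grid <- as.vector(outer(x_centers, sub * dxc, `+`))
  ord <- order(xs_grid)
  for (sy in sub) {
    for (iy in seq_along(y_centers)) {
      yv <- y_centers[iy] + sy * dyc
      sel <- (y1 <= yv) != (y2 <= yv)
      if (!any(sel)) next
      xc <- x1[sel] + (yv - y1[sel]) / (y2[sel] - y1[sel]) * (x2[sel] - x1[sel])
      cnt <- findInterval(xs_grid, sort(xc))
      inside <- (cnt %% 2) == 1
      cov[iy, ] <- cov[iy, ] + rowMeans(matrix(inside, length(x_centers)))
    }
  }
  cov / supersample
}

#' Rasterize a closed contour into a pixel occupancy image
#'
#' Anti-aliased rendering: each pixel value is the approximate fraction of the
#' pixel covered by the contour's interior (supersampled), so the 0.5 level
#' set of the image tracks the true membrane with sub-pixel accuracy. Used to
#' emulate fluorescence midplane images (CFSE mode: 0.4 um pixels).
#'
#' @param contour a [contour2d] (closed).
#' @param pixel_um pixel size in micrometers.
#' @param bbox optional `c(xmin, xmax, ymin, ymax)` in micrometers; default is
#'   the contour bounding box padded by 1 um.
#' @param supersample subsamples per axis per pixel.
#' @return numeric matrix (rows = y, cols = x) in `[0, 1]` with attributes
#'   `pixel_um` and `origin_um` (`c(x0, y0)` of pixel `[1,1]` center).
#' @export
render_contour_mask <- function(contour, pixel_um = 0.4, bbox = NULL,
                                supersample = 3L) {
  if (!inherits(contour, "contour2d") || !contour$closed)
    stopf("need a closed contour2d")
  xy <- contour$xy
  if (is.null(bbox)) {
    bbox <- c(min(xy[, 1]) - 1, max(xy[, 1]) + 1,
              min(xy[, 2]) - 1, max(xy[, 2]) + 1)
  }
  x_centers <- seq(bbox[1], bbox[2], by = pixel_um)
  y_centers <- seq(bbox[3], bbox[4], by = pixel_um)
  img <- polygon_coverage(xy, x_centers, y_centers, supersample)
  attr(img, "pixel_um") <- pixel_um
  attr(img, "origin_um") <- c(x_centers[1], y_centers[1])
  img
}
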