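#' Specification of a synthetic cell-couple scene
#'
#' Describes one T cell:APC conjugate movie with a known accumulation
#' pattern. Defaults emulate the live-imaging setup: 21 z-planes spaced
#' 1 um, 0.5 um in-plane pixels, 20 s frames, sensor accumulation 80% above
#' the cytoplasmic background (fold 1.8).
#'
#' @param pattern one of `"central"`, `"invagination"`, `"diffuse"`,
#'   `"lamellum"`, `"peripheral"`, `"asymmetric"`, `"none"`; may be a vector
#'   (one label per frame) to emulate pattern transitions.
#' @param fold_over_background sensor accumulation level (1.8 = 80% above
#'   background; 1 = no accumulation).
#' @param depth_um extension of the accumulation into the T cell; pattern-
#'   specific default (lamellum 3, invagination 2.5, central/peripheral 0.8,
#'   diffuse cortex thickness 0.5, asymmetric 1.2).
#' @param coverage fraction of the interface diameter covered; pattern-
#'   specific default.
#' @param interface_radius_um radius of the contact disc (D = 2r).
#' @param voxel_um voxel sizes `c(dz, dy, dx)`.
#' @param n_timepoints frames.
#' @param dt_s frame interval (s).
#' @param noise_sd additive Gaussian noise sd (sensor cytoplasm = 1).
#' @param pre_frames leading frames before conjugate formation (cells
#'   separated; truth label "none").
#' @param seed integer seed.
#' @return validated list of class `scene_spec`.
#' @export
scene_spec <- function(pattern = "lamellum", fold_over_background = 1.8,
                       depth_um = NULL, coverage = NULL,
                       interface_radius_um = 3.5,
                       voxel_um = c(1, 0.5, 0.5), n_timepoints = 1L,
                       dt_s = 20, noise_sd = 0.05, pre_frames = 0L,
                       seed = 0) {
  known <- c("central", "invagination", "diffuse", "lamellum", "peripheral",
             "asymmetric", "none")
  if (!all(pattern %in% known))
    stopf("unknown pattern(s): %s", paste(setdiff(pattern, known), collapse = ", "))
  defaults <- list(
    central      = list(depth_um = 0.8, coverage = 0.5),
    invagination = list(depth_um = 2.5, coverage = 0.28),
    diffuse      = list(depth_um = 0.5, coverage = 1.0),
    lamellum     = list(depth_um = 3.0, coverage = 1.0),
    peripheral   = list(depth_um = 0.8, coverage = 0.5),
    asymmetric   = list(depth_um = 1.2, coverage = 0.35),
    none         = list(depth_um = 0,   coverage = 0))
  # resolve template geometry per frame label (explicit values override all)
  depth_by_label <- vapply(pattern, function(p)
    depth_um %||% defaults[[p]]$depth_um, 0)
  cov_by_label <- vapply(pattern, function(p)
    coverage %||% defaults[[p]]$coverage, 0)
  depth_um <- depth_um %||% depth_by_label[[1]]
  coverage <- coverage %||% cov_by_label[[1]]
  if (any(cov_by_label < 0) || any(cov_by_label > 1)) stopf("coverage in [0, 1]")
  if (fold_over_background < 1) stopf("fold_over_background >= 1")
  if (any(voxel_um <= 0) || interface_radius_um <= 0 || dt_s <= 0)
    stopf("all sizes must be positive")
  spec <- list(pattern = pattern, fold_over_background = fold_over_background,
               depth_um = depth_um, coverage = coverage,
               depth_by_label = unname(depth_by_label),
               cov_by_label = unname(cov_by_label),
               interface_radius_um = interface_radius_um,
               voxel_um = voxel_um, n_timepoints = as.integer(n_timepoints),
               dt_s = dt_s, noise_sd = noise_sd,
               pre_frames = as.integer(pre_frames), seed = seed)
  class(spec) <- "scene_spec"
  spec
}

#' Render a synthetic T cell:APC conjugate movie with ground truth
#'
#' Two apposed truncated spheres (T cell radius 5 um at high x, APC radius
#' 5.5 um at low x) sharing a flat contact disc, separated by a thin
#' resolution-limited seam. The whole-cell channel carries both cells (T
#' brighter); the sensor channel carries a uniform T cell cytoplasm plus a
#' pattern template at `fold_over_background`:
#' central disc on the middle 50% of the interface; narrow deep central
#' finger (invagination); thin cortical shell (diffuse); slab spanning the
#' full interface (lamellum); annulus over the outer 25% of the diameter on
#' each side (peripheral); one-sided off-center patch (asymmetric). Light
#' Gaussian blur emulates the PSF, additive Gaussian noise the camera.
#'
#' @param spec a [scene_spec].
#' @return list with `stack` (an [image_stack4d] with channels `cell`,
#'   `sensor`) and `truth` (per-frame labels, interface geometry, template
#'   parameters).
#' @export
gen_cell_couple_stack <- function(spec) {
  if (!inherits(spec, "scene_spec")) spec <- do.call(scene_spec, spec)
  vx <- spec$voxel_um
  R_t <- 5; R_a <- 5.5
  R_if <- spec$interface_radius_um
  if (R_if >= R_t) stopf("interface radius must be below the T cell radius")
  if (spec$depth_um > 2 * R_t)
    stopf("pattern template deeper than the T cell: depth %g um", spec$depth_um)
  dims <- c(21L, 32L, 44L)
  set.seed(spec$seed)
  x0 <- 11 + stats::runif(1, -0.25, 0.25)
  zc <- (dims[1] - 1) * vx[1] / 2 + stats::runif(1, -0.4, 0.4)
  yc <- (dims[2] - 1) * vx[2] / 2 + stats::runif(1, -0.4, 0.4)
  seam <- vx[3]  # one-voxel resolution-limited inter-membrane seam
  a_t <- sqrt(R_t^2 - R_if^2)
  a_a <- sqrt(R_a^2 - R_if^2)

  co <- voxel_coords(dims, vx)
  n_frames <- spec$pre_frames + spec$n_timepoints
  frame_pat <- rep(seq_along(spec$pattern), length.out = spec$n_timepoints)
  labels <- c(rep("none", spec$pre_frames), spec$pattern[frame_pat])
  depth_f <- c(rep(0, spec$pre_frames), spec$depth_by_label[frame_pat])
  cov_f <- c(rep(0, spec$pre_frames), spec$cov_by_label[frame_pat])
  cell_ch <- array(0, c(n_frames, dims))
  sens_ch <- array(0, c(n_frames, dims))

  for (f in seq_len(n_frames)) {
    coupled <- f > spec$pre_frames
    shift <- if (coupled) 0 else 1.5  # pre-coupling: cells pulled apart
    ct <- c(zc, yc, x0 + a_t + shift)
    ca <- c(zc, yc, x0 - seam - a_a - shift)
    d_t <- sqrt((co$z - ct[1])^2 + (co$y - ct[2])^2 + (co$x - ct[3])^2)
    d_a <- sqrt((co$z - ca[1])^2 + (co$y - ca[2])^2 + (co$x - ca[3])^2)
    t_mask <- d_t <= R_t & co$x >= x0 + shift
    a_mask <- d_a <= R_a & co$x <= x0 - seam - shift
    cell <- 0.02 + 0.98 * t_mask + 0.68 * a_mask
    sens <- 0.02 + 0.98 * t_mask + 0.03 * a_mask

    lab <- labels[f]
    if (coupled && lab != "none" && spec$fold_over_background > 1) {
      dep <- depth_f[f]; cov <- cov_f[f]
      delta <- co$x - x0
      r_in <- sqrt((co$z - ct[1])^2 + (co$y - ct[2])^2)
      u <- co$y - ct[2]
      tmpl <- switch(lab,
        central = r_in <= cov * R_if & delta <= dep,
        invagination = r_in <= cov * R_if & delta <= dep,
        diffuse = (R_t - d_t <= dep) | (delta <= dep & r_in <= R_if),
        lamellum = r_in <= R_if & delta <= dep,
        peripheral = r_in >= (1 - cov) * R_if & r_in <= R_if & delta <= dep,
        asymmetric = sqrt((u - 0.65 * R_if)^2 + (co$z - ct[1])^2) <=
                     cov * R_if & delta <= dep)
      sens <- sens + (spec$fold_over_background - 1) * (tmpl & t_mask)
    }
    cell <- gaussian_smooth(cell, 0.4)
    sens <- gaussian_smooth(sens, 0.4)
    if (spec$noise_sd > 0) {
      cell <- cell + array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims)
      sens <- sens + array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims)
    }
    cell_ch[f, , , ] <- pmax(cell, 0)
    sens_ch[f, , , ] <- pmax(sens, 0)
  }
  stack <- image_stack4d(list(cell = cell_ch, sensor = sens_ch),
                         voxel_um = vx, dt_s = spec$dt_s)
  list(stack = stack,
       truth = list(labels = labels, pattern = spec$pattern,
                    fold_over_background = spec$fold_over_background,
                    depth_um = spec$depth_um, coverage = spec$coverage,
                    diameter_um = 2 * R_if, interface_x_um = x0,
                    center_zy_um = c(zc, yc),
                    coupling_frame = spec$pre_frames + 1L,
                    seed = spec$seed))
}

#' Generate a volume with a known exponential depth-intensity profile
#'
#' Emulates the box-scan measurement of actin reaching into the T cell:
#' inside the interface footprint the intensity decays exponentially with
#' depth, with separate amplitude/length-constant pairs for the interface
#' center (inner 50% of the diameter) and periphery (outer 25% each side).
#' The defaults solve the two-zone profile so that the 0.5-um slab starting
#' at 1 um sits 57% (periphery) / 40% (center) above background and the slab
#' at 2 um at 19% / 11% — the early lamellal-actin geometry.
#'
#' @param periph_pct percentages above background for the periphery at the
#'   slabs starting 1 um and 2 um into the cell.
#' @param center_pct same for the center zone.
#' @param bg background intensity.
#' @param diameter_um interface diameter.
#' @param voxel_um isotropic voxel size.
#' @param depth_um rendered depth extent.
#' @param step_um slab width the percentages refer to.
#' @param noise_sd additive Gaussian noise.
#' @param seed integer seed.
#' @return list with `volume`, `frame`, `voxel_um`, `truth` (the analytic
#'   amplitude and length constant per zone).
#' @export
gen_actin_depth_volume <- function(periph_pct = c(57, 19),
                                   center_pct = c(40, 11), bg = 1,
                                   diameter_um = 7, voxel_um = 0.25,
                                   depth_um = 5, step_um = 0.5,
                                   noise_sd = 0, seed = 0) {
  solve_zone <- function(p) {
    lambda <- 1 / log(p[1] / p[2])
    slab_mean <- function(A, a) A * lambda *
      (exp(-a / lambda) - exp(-(a + step_um) / lambda)) / step_um
    A <- p[1] / slab_mean(1, 1)
    list(A = A, lambda = lambda)
  }
  zc <- solve_zone(center_pct)
  zp <- solve_zone(periph_pct)
  R <- diameter_um / 2
  dims <- c(ceiling((diameter_um + 2) / voxel_um),
            ceiling((diameter_um + 2) / voxel_um),
            ceiling((depth_um + 1) / voxel_um))
  vx <- rep(voxel_um, 3)
  # put the interface plane half a voxel off the grid so every depth slab is
  # sampled symmetrically by voxel centers (slab means match the analytic
  # slab integrals)
  x0 <- (round(0.5 / voxel_um) - 0.5) * voxel_um
  co <- voxel_coords(dims, vx)
  cz <- (dims[1] - 1) * voxel_um / 2
  cy <- (dims[2] - 1) * voxel_um / 2
  delta <- co$x - x0
  r <- sqrt((co$z - cz)^2 + (co$y - cy)^2)
  rho <- r / R
  vol <- array(bg, dims)
  inside <- rho <= 1 & delta >= 0
  zone_c <- inside & rho <= 0.5
  zone_p <- inside & rho > 0.5
  vol[zone_c] <- bg * (1 + zc$A / 100 * exp(-delta[zone_c] / zc$lambda))
  vol[zone_p] <- bg * (1 + zp$A / 100 * exp(-delta[zone_p] / zp$lambda))
  if (noise_sd > 0) {
    set.seed(seed)
    vol <- pmax(vol + array(stats::rnorm(prod(dims), 0, noise_sd), dims), 0)
  }
  frame <- make_interface_frame(point = c(cz, cy, x0), normal = c(0, 0, 1),
                                diameter_um = diameter_um)
  list(volume = vol, frame = frame, voxel_um = vx,
       truth = list(center = zc, periphery = zp, bg = bg,
                    diameter_um = diameter_um, step_um = step_um))
}
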