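#' Presets for synthetic STED-like actin structure images
#'
#' Early (1-2 min) conjugates show elongated F-actin structures oriented
#' perpendicular to the interface (depth/width 2.6); late (2-5 min)
#' structures are flatter than wide (0.7). Widths default to 1 um, pixels to
#' 25 nm (STED scale).
#'
#' @return named list of preset parameter lists.
#' @export
sted_presets <- function() {
  list(
    sted_early = list(n = 12L, depth_um = 2.6, width_um = 1.0,
                      amplitude = 2.0, bg = 1.0),
    sted_late  = list(n = 12L, depth_um = 0.7, width_um = 1.0,
                      amplitude = 2.0, bg = 1.0)
  )
}

#' Generate a STED-like 2D image of elongated actin structures
#'
#' Renders `n` anisotropic Gaussian bars on a uniform cellular background,
#' oriented perpendicular to a horizontal interface line at the bottom of the
#' image. The specified `depth_um`/`width_um` are the true FWHMs
#' (`FWHM = 2 sqrt(2 ln 2) sigma`); per-structure sizes and amplitudes are
#' mildly jittered. Structures are separated by more than twice their width
#' so line scans resolve them individually.
#'
#' @param n number of structures.
#' @param depth_um,width_um true FWHM perpendicular/parallel to the interface.
#' @param amplitude peak intensity above background.
#' @param bg cellular background intensity.
#' @param seed integer seed.
#' @param pixel_um pixel size (default 25 nm).
#' @param size_jitter relative sd of per-structure FWHM jitter (truncated at
#'   2 sd; symmetric, so the ensemble mean stays at the preset).
#' @param noise_sd additive Gaussian noise sd.
#' @param preset optional name from [sted_presets()].
#' @return list with `image` (matrix rows = y (depth axis), cols = x, with
#'   `pixel_um` attribute) and `truth` data.frame (x_um, y_um, depth_um,
#'   width_um, amplitude per structure).
#' @export
gen_sted_structures <- function(n = 12L, depth_um = 2.6, width_um = 1.0,
                                amplitude = 2.0, bg = 1.0, seed = 0,
                                pixel_um = 0.025, size_jitter = 0.04,
                                noise_sd = 0.02, preset = NULL) {
  if (!is.null(preset)) {
    p <- sted_presets()[[preset]]
    if (is.null(p)) stopf("unknown preset '%s'", preset)
    n <- p$n; depth_um <- p$depth_um; width_um <- p$width_um
    amplitude <- p$amplitude; bg <- p$bg
  }
  set.seed(seed)
  fw2sig <- 1 / (2 * sqrt(2 * log(2)))
  pitch <- max(2.5 * width_um, 2.0)
  h_um <- depth_um + 3
  w_um <- max(n, 1) * pitch + pitch
  ny <- ceiling(h_um / pixel_um)
  nx <- ceiling(w_um / pixel_um)
  img <- matrix(bg, ny, nx)
  yy <- (seq_len(ny) - 1) * pixel_um
  xx <- (seq_len(nx) - 1) * pixel_um
  tnorm <- function(m) pmax(-2, pmin(2, stats::rnorm(m)))
  if (n > 0) {
    d_i <- depth_um * (1 + size_jitter * tnorm(n))
    w_i <- width_um * (1 + size_jitter * tnorm(n))
    a_i <- amplitude * (1 + 0.15 * tnorm(n))
    x_i <- pitch * (seq_len(n) - 0.5) + pitch / 2 +
      0.05 * pitch * tnorm(n)
    y_i <- rep(h_um / 2, n) + 0.1 * tnorm(n)
    for (s in seq_len(n)) {
      gy <- exp(-0.5 * ((yy - y_i[s]) / (d_i[s] * fw2sig))^2)
      gx <- exp(-0.5 * ((xx - x_i[s]) / (w_i[s] * fw2sig))^2)
      img <- img + a_i[s] * outer(gy, gx)
    }
  } else {
    d_i <- w_i <- a_i <- x_i <- y_i <- numeric(0)
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(ny * nx, 0, noise_sd), ny, nx)
  img <- pmax(img, 0)
  attr(img, "pixel_um") <- pixel_um
  list(image = img,
       truth = data.frame(x_um = x_i, y_um = y_i, depth_um = d_i,
                          width_um = w_i, amplitude = a_i),
       bg = bg, seed = seed)
}

#' Measure all structures of a STED-like image
#'
#' Convenience wrapper running [measure_structure_fwhm()] at each seed
#' position; unqualified structures (peak below `qualify_fold * bg`) are
#' dropped.
#'
#' @param image2d image matrix with `pixel_um` attribute (or give `pixel_um`).
#' @param seeds data.frame or matrix with columns x_um, y_um.
#' @param bg background intensity.
#' @param qualify_fold qualification threshold (default 1.35).
#' @param pixel_um pixel size override.
#' @return data.frame with one row per qualified structure (depth_um,
#'   width_um, ratio, intensity_area_ratio).
#' @export
measure_structures <- function(image2d, seeds, bg, qualify_fold = 1.35,
                               pixel_um = NULL) {
  pixel_um <- pixel_um %||% attr(image2d, "pixel_um") %||% 0.025
  seeds <- as.matrix(seeds[, c("x_um", "y_um")])
  rows <- lapply(seq_len(nrow(seeds)), function(i) {
    m <- measure_structure_fwhm(image2d, seeds[i, ], bg = bg,
                                qualify_fold = qualify_fold,
                                pixel_um = pixel_um)
    if (is.null(m)) return(NULL)
    data.frame(depth_um = m$depth_um, width_um = m$width_um, ratio = m$ratio,
               intensity_area_ratio = m$intensity_area_ratio)
  })
  do.call(rbind, rows) %||% data.frame(depth_um = numeric(0),
                                       width_um = numeric(0),
                                       ratio = numeric(0),
                                       intensity_area_ratio = numeric(0))
}
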