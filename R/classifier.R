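#' Cellular fluorescence background of the T cell
#'
#' Median sensor intensity over the T cell mask (the whole cell, including
#' any accumulation; the median is robust to it). Optionally the top decile
#' is excluded first.
#'
#' @param vol 3D sensor volume.
#' @param tcell_mask logical T cell mask.
#' @param exclude_top_decile drop the brightest 10% of T cell voxels first.
#' @return background intensity (scalar).
#' @export
estimate_background <- function(vol, tcell_mask, exclude_top_decile = FALSE) {
  v <- vol[tcell_mask]
  if (length(v) == 0) stopf("empty T cell mask")
  if (exclude_top_decile) v <- v[v <= stats::quantile(v, 0.9)]
  stats::median(v)
}

#' Default classifier thresholds
#'
#' Decision-tree thresholds for pattern assignment (all dimensionless except
#' depths in micrometers). `c_tol` is a coverage quantization guard of about
#' half an in-plane voxel on a typical interface diameter.
#'
#' @return named list of thresholds.
#' @export
classifier_config <- function() {
  list(min_fold = 1.4,        # detection: >40% above cellular background
       max_depth_um = 5,      # detection search depth into the T cell
       lamellum_c = 2 / 3, lamellum_d_um = 1.5,
       central_rho = 0.40, central_c = 0.5,
       invag_d_um = 2.0, invag_c = 1 / 3,
       periph_rho = 0.70,
       c_tol = 0.05)
}

#' Detect the dominant above-background accumulation region
#'
#' Connected voxels at or above `min_fold` times the cellular background,
#' within `max_depth_um` of the interface plane; the largest 26-connected
#' component is kept and summarized in the interface frame:
#' `f` mean fold over background; `c` fraction of the interface diameter
#' covered (measured along a one-voxel strip through the interface center,
#' oriented toward the region's in-plane centroid); `rho_bar`
#' intensity-weighted in-plane radial centroid (0 = center, 1 = edge);
#' `d_um` depth at which the region's depth profile (restricted in-plane to
#' the interface footprint) falls to half its peak; `one_sided` whether the
#' region lies entirely on one side of the interface center.
#'
#' @param vol 3D sensor volume.
#' @param frame an `interface_frame`.
#' @param tcell_mask logical T cell mask.
#' @param bg background from [estimate_background()] (> 0).
#' @param voxel_um voxel sizes.
#' @param min_fold detection threshold (default 1.4).
#' @param max_depth_um detection depth (default 5).
#' @return object of class `accumulation_region`, or `NULL` when no voxel
#'   passes the threshold.
#' @export
detect_accumulation <- function(vol, frame, tcell_mask, bg, voxel_um,
                                min_fold = 1.4, max_depth_um = 5) {
  if (bg <= 0) stopf("bg must be > 0")
  dm <- dim(vol)
  co <- frame_coords(frame, volume_coord_matrix(dm, voxel_um))
  cand <- tcell_mask & vol >= min_fold * bg &
    array(co$delta >= -1 & co$delta <= max_depth_um, dm)
  if (!any(cand)) return(NULL)
  lab <- label_components_3d(cand, 26L)
  sizes <- tabulate(lab[lab > 0])
  region <- lab == which.max(sizes)
  sel <- as.vector(region)
  w <- pmax(as.vector(vol)[sel] - bg, 0)
  if (sum(w) == 0) w <- rep(1, sum(sel))
  R_half <- frame$D_um / 2
  u0 <- co$u[sel]; v0 <- co$v[sel]; dd <- co$delta[sel]; rr <- co$r[sel]

  # axis toward the region's in-plane centroid (falls back to the frame's
  # diameter axis for centered regions)
  cen <- c(sum(u0 * w), sum(v0 * w)) / sum(w)
  if (sqrt(sum(cen^2)) > 0.1 * R_half) {
    ax <- cen / sqrt(sum(cen^2))
  } else ax <- c(1, 0)
  ua <- u0 * ax[1] + v0 * ax[2]
  va <- -u0 * ax[2] + v0 * ax[1]

  # voxel pitch along the measurement axis and across it (anisotropic voxels)
  dir3 <- ax[1] * frame$e1 + ax[2] * frame$e2
  perp3 <- -ax[2] * frame$e1 + ax[1] * frame$e2
  bin_w <- sum(abs(dir3) * voxel_um)
  strip_hw <- 0.5 * sum(abs(perp3) * voxel_um)
  strip <- abs(va) <= strip_hw
  # covered fraction of the diameter: sum of contiguous spans of strip voxels
  # along the axis (runs split at gaps larger than ~1.5 voxel pitches)
  covered <- if (any(strip)) {
    us <- sort(pmin(pmax(ua[strip], -R_half), R_half))
    gaps <- which(diff(us) > 1.6 * bin_w)
    starts <- c(1, gaps + 1)
    ends <- c(gaps, length(us))
    sum(us[ends] - us[starts]) / frame$D_um
  } else 0
  rho_bar <- min(1, sum(rr * w) / sum(w) / R_half)

  # depth profile restricted to the interface footprint
  infp <- rr <= R_half & dd >= 0
  d_um <- NA_real_
  if (any(infp)) {
    step <- 0.5
    bin <- floor(dd[infp] / step)
    prof <- vapply(0:max(bin), function(b) sum(w[infp][bin == b]), 0)
    depth_centers <- (0:max(bin) + 0.5) * step
    d_um <- first_falling_crossing(depth_centers, prof, max(prof) / 2)
    if (is.na(d_um)) d_um <- max(dd[infp])
  } else d_um <- max(0, max(dd))
  tol_u <- bin_w
  structure(list(n_voxels = sum(sel), f = mean(as.vector(vol)[sel]) / bg,
                 c = min(1, covered), rho_bar = rho_bar, d_um = d_um,
                 one_sided = min(ua) > -tol_u || max(ua) < tol_u,
                 axis = ax, voxels = region),
            class = "accumulation_region")
}

#' @export
print.accumulation_region <- function(x, ...) {
  cat(sprintf("<accumulation_region> %d voxels, f = %.2f, c = %.2f, rho_bar = %.2f, d = %.2f um%s\n",
              x$n_voxels, x$f, x$c, x$rho_bar, x$d_um,
              if (x$one_sided) ", one-sided" else ""))
  invisible(x)
}

#' Assign a mutually exclusive interface pattern
#'
#' Decision tree over the geometric features of the accumulation region:
#' broad coverage is split by depth into lamellum (deep) and diffuse
#' (shallow, cortical); accumulation confined to the interface center is
#' split by depth and narrowness into invagination (deep finger) and
#' central; peripheral accumulation on both sides is peripheral; any
#' remaining (one-sided or off-center) accumulation is asymmetric.
#'
#' @param region an `accumulation_region`, or `NULL` for none.
#' @param config thresholds from [classifier_config()] (any subset can be
#'   overridden).
#' @return a single label string.
#' @export
classify_pattern <- function(region, config = classifier_config()) {
  cfg <- utils::modifyList(classifier_config(), config)
  if (is.null(region)) return("none")
  feats <- c(region$c, region$rho_bar, region$d_um)
  if (any(!is.finite(feats))) stopf("non-finite region features")
  ct <- cfg$c_tol
  if (region$c >= cfg$lamellum_c - ct) {
    return(if (region$d_um >= cfg$lamellum_d_um) "lamellum" else "diffuse")
  }
  if (region$rho_bar <= cfg$central_rho && region$c <= cfg$central_c + ct) {
    if (region$d_um >= cfg$invag_d_um && region$c <= cfg$invag_c + ct)
      return("invagination")
    return("central")
  }
  if (region$rho_bar >= cfg$periph_rho && !region$one_sided)
    return("peripheral")
  "asymmetric"
}

#' Classify one frame of a conjugate movie
#'
#' Convenience pipeline: segmentation, interface frame, background,
#' detection, classification; frames without a conjugate or interface yield
#' "none".
#'
#' @param stack an [image_stack4d].
#' @param t frame index.
#' @param channel sensor channel.
#' @param cell_channel whole-cell channel.
#' @param config classifier thresholds.
#' @return list with `label`, `region`, `frame`, `bg` (region/frame NULL for
#'   "none" frames).
#' @export
classify_frame <- function(stack, t = 1, channel = "sensor",
                           cell_channel = "cell",
                           config = classifier_config()) {
  cfg <- utils::modifyList(classifier_config(), config)
  scene <- tryCatch(segment_cells(stack, cell_channel, t),
                    error = function(e) NULL)
  if (is.null(scene)) return(list(label = "none", region = NULL, frame = NULL))
  fr <- tryCatch(build_interface_frame(scene), error = function(e) NULL)
  if (is.null(fr)) return(list(label = "none", region = NULL, frame = NULL))
  vol <- get_volume(stack, channel, t)
  bg <- estimate_background(vol, scene$tcell_mask)
  region <- detect_accumulation(vol, fr, scene$tcell_mask, bg,
                                stack$voxel_um, min_fold = cfg$min_fold,
                                max_depth_um = cfg$max_depth_um)
  list(label = classify_pattern(region, cfg), region = region, frame = fr,
       bg = bg)
}

#' Classify every frame of a conjugate movie
#'
#' Runs [classify_frame()] per frame. The time origin is the first frame
#' with a detected interface (tight cell coupling); earlier frames carry
#' negative times and, lacking a conjugate, the label "none".
#'
#' @param stack an [image_stack4d].
#' @param channel sensor channel name.
#' @param cell_channel whole-cell channel name.
#' @param config classifier thresholds.
#' @param id cell-couple identifier.
#' @return object of class `pattern_timecourse` with `labels`, `t_s`
#'   (relative to coupling) and `coupling_frame`.
#' @export
classify_timecourse <- function(stack, channel = "sensor",
                                cell_channel = "cell",
                                config = classifier_config(), id = "cell1") {
  n <- stack$dim[1]
  labels <- character(n)
  has_if <- logical(n)
  for (t in seq_len(n)) {
    res <- classify_frame(stack, t, channel, cell_channel, config)
    labels[t] <- res$label
    has_if[t] <- !is.null(res$frame)
  }
  coupling <- if (any(has_if)) which(has_if)[1] else NA_integer_
  t_s <- if (is.na(coupling)) (seq_len(n) - 1) * stack$dt_s
         else (seq_len(n) - coupling) * stack$dt_s
  structure(list(id = id, labels = labels, t_s = t_s,
                 coupling_frame = coupling),
            class = "pattern_timecourse")
}

#' @export
print.pattern_timecourse <- function(x, ...) {
  cat(sprintf("<pattern_timecourse> %s: %s\n", x$id,
              paste(sprintf("%+ds:%s", as.integer(x$t_s), x$labels),
                    collapse = " ")))
  invisible(x)
}

pattern_levels <- function() {
  c("central", "invagination", "diffuse", "lamellum", "peripheral",
    "asymmetric", "none")
}

#' Percentage occurrence of each pattern over time
#'
#' @param timecourses list of `pattern_timecourse` objects (times aligned to
#'   coupling).
#' @return object of class `occurrence_table`: matrix of percentages
#'   (patterns x timepoints, including "none" so columns sum to 100) with
#'   per-timepoint n in `attr(, "n")`.
#' @export
occurrence_table <- function(timecourses) {
  times <- sort(unique(unlist(lapply(timecourses, `[[`, "t_s"))))
  pats <- pattern_levels()
  m <- matrix(0, length(pats), length(times),
              dimnames = list(pats, sprintf("%+d", as.integer(times))))
  n_t <- integer(length(times))
  for (j in seq_along(times)) {
    labs <- unlist(lapply(timecourses, function(tc) {
      i <- match(times[j], tc$t_s)
      if (is.na(i)) NULL else tc$labels[i]
    }))
    n_t[j] <- length(labs)
    if (n_t[j] > 0) m[, j] <- 100 * tabulate(match(labs, pats),
                                             length(pats)) / n_t[j]
  }
  attr(m, "n") <- n_t
  class(m) <- c("occurrence_table", "matrix", "array")
  m
}

#' Per-interval change in pattern occurrence
#'
#' @param occ an [occurrence_table()].
#' @return matrix of percentage-point changes per frame interval
#'   (`occ(t) - occ(t - dt)`), one column fewer than `occ`.
#' @export
change_table <- function(occ) {
  if (ncol(occ) < 2) stopf("need at least two timepoints")
  d <- occ[, -1, drop = FALSE] - occ[, -ncol(occ), drop = FALSE]
  class(d) <- c("matrix", "array")
  d
}
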