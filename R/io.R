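# File I/O: TIFF stacks with JSON metadata sidecars, contour/trace CSV,
# ground-truth JSON. CSV dialect: comma-separated, UTF-8, header row, '.'
# decimal; distances in micrometers, times in seconds, rates in 1/s.

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are written in t-major, z-minor order as 32-bit float; axes, voxel
#' sizes and the frame interval go into `<basename>.meta.json` so the stack
#' round-trips through [load_stack()] without guessing.
#'
#' @param stack an [image_stack4d].
#' @param path output `.tif` path.
#' @param channel channel to write (TIFF holds one channel; others get their
#'   own file via repeated calls).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, channel = names(stack$channels)[1]) {
  vol4 <- stack$channels[[channel]]
  if (is.null(vol4)) stopf("no channel '%s'", channel)
  dm <- stack$dim
  # writeTIFF stores [0,1]; rescale by the stack maximum and record the scale
  scale <- max(vol4, 1e-12)
  pages <- vector("list", dm[1] * dm[2])
  i <- 0L
  for (t in seq_len(dm[1])) for (z in seq_len(dm[2])) {
    i <- i + 1L
    pages[[i]] <- matrix(vol4[t, z, , ], dm[3], dm[4]) / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(axes = "TZYX", shape = as.integer(dm),
               voxel_um = stack$voxel_um, dt_s = stack$dt_s,
               channel = channel, intensity_scale = scale)
  jsonlite::write_json(meta, sub("\\.tiff?$", ".meta.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a TIFF stack as an image_stack4d
#'
#' Reads a (multi-page) TIFF; axes/voxel sizes come from the JSON sidecar
#' written by [write_stack()] or from the explicit overrides. 2D images are
#' promoted to a single-frame, single-plane stack.
#'
#' @param path `.tif` path.
#' @param voxel_um,dt_s,shape overrides when no sidecar exists; `shape` is
#'   `c(t, z)` for the page unstacking.
#' @param channel channel name for the loaded data.
#' @return an [image_stack4d].
#' @export
load_stack <- function(path, voxel_um = NULL, dt_s = NULL, shape = NULL,
                       channel = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  meta_path <- sub("\\.tiff?$", ".meta.json", path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else NULL
  voxel_um <- voxel_um %||% meta$voxel_um
  if (is.null(voxel_um))
    stopf("no voxel sizes: supply voxel_um or a %s sidecar", basename(meta_path))
  dt_s <- dt_s %||% meta$dt_s %||% 20
  channel <- channel %||% meta$channel %||% "cell"
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  tz <- shape %||% meta$shape[1:2] %||% c(1L, length(pages))
  if (tz[1] * tz[2] != length(pages))
    stopf("page count %d does not match t*z = %d*%d; supply shape",
          length(pages), tz[1], tz[2])
  scale <- meta$intensity_scale %||% 1
  arr <- array(0, c(tz[1], tz[2], ny, nx))
  i <- 0L
  for (t in seq_len(tz[1])) for (z in seq_len(tz[2])) {
    i <- i + 1L
    arr[t, z, , ] <- pages[[i]] * scale
  }
  ch <- list(arr)
  names(ch) <- channel
  image_stack4d(ch, voxel_um = voxel_um, dt_s = dt_s)
}

#' Write / read a contour as CSV (columns x_um, y_um)
#'
#' Interface endpoints, when marked, are stored in an `interface` column
#' (1 inside the interface segment, 0 outside).
#'
#' @param contour a [contour2d].
#' @param path CSV path.
#' @return `path` / a [contour2d].
#' @export
write_contour_csv <- function(contour, path) {
  df <- data.frame(x_um = contour$xy[, 1], y_um = contour$xy[, 2])
  if (!is.null(contour$interface_idx)) {
    df$interface <- 0L
    df$interface[contour$interface_idx[1]:contour$interface_idx[2]] <- 1L
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path)
  idx <- NULL
  if ("interface" %in% names(df) && any(df$interface == 1)) {
    w <- which(df$interface == 1)
    idx <- c(min(w), max(w))
  }
  contour2d(cbind(df$x_um, df$y_um), closed = TRUE, interface_idx = idx)
}

#' Write / read a FRAP trace as CSV (columns t_s, intensity)
#' @param trace a [frap_trace].
#' @param path CSV path.
#' @return `path` / a [frap_trace].
#' @export
write_frap_csv <- function(trace, path) {
  utils::write.csv(data.frame(t_s = trace$t_s, intensity = trace$y),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_csv
#' @param n_prebleach prebleach samples at the head of the file.
#' @export
read_frap_csv <- function(path, n_prebleach = 3L) {
  df <- utils::read.csv(path)
  frap_trace(df$t_s, df$intensity, n_prebleach)
}

#' Write a ground-truth sidecar next to a generated artifact
#'
#' @param truth list of ground-truth values (as returned by the generators).
#' @param path path of the artifact; the sidecar gets the same basename with
#'   `.truth.json`.
#' @return sidecar path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  out <- sub("\\.[A-Za-z0-9]+$", "", path)
  out <- paste0(out, ".truth.json")
  jsonlite::write_json(truth, out, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(out)
}
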