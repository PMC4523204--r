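# Internal numerics shared across modules. All arrays are base R arrays;
# volumes are indexed (z, y, x), stacks (t, z, y, x), voxel_um = c(dz, dy, dx).

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(n_bins, 1L + floor((x - r[1]) / diff(r) * n_bins)), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + k / n_bins * diff(r)
}

# Separable Gaussian smoothing along one array dimension (reflected edges).
smooth_dim <- function(a, dim_index, sigma) {
  if (sigma <= 0) return(a)
  radius <- max(1L, ceiling(3 * sigma))
  kern <- exp(-0.5 * ((-radius):radius / sigma)^2)
  kern <- kern / sum(kern)
  dm <- dim(a)
  n <- dm[dim_index]
  # move target dim first, convolve columns, move back
  perm <- c(dim_index, setdiff(seq_along(dm), dim_index))
  m <- aperm(a, perm)
  dim(m) <- c(n, length(m) / n)
  pad_top <- m[pmin(n, (radius):1), , drop = FALSE]
  pad_bot <- m[pmax(1, n:(n - radius + 1)), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(kern)) {
    out <- out + kern[i] * mp[(i - 1) + seq_len(n), , drop = FALSE]
  }
  dim(out) <- dm[perm]
  aperm(out, order(perm))
}

gaussian_smooth <- function(a, sigma) {
  # sigma: scalar (all dims) or per-dimension vector, in voxels/pixels
  dm <- dim(a)
  if (length(sigma) == 1) sigma <- rep(sigma, length(dm))
  for (d in seq_along(dm)) a <- smooth_dim(a, d, sigma[d])
  a
}

# Neighbor offsets for 3D connectivity (as matrix of dz,dy,dx rows, origin excluded)
neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  else if (connectivity != 26L) stopf("connectivity must be 6 or 26, got %s", connectivity)
  g
}

# Shift a 3D array by (dz,dy,dx), filling exposed planes with `fill`.
shift3d <- function(a, s, fill = Inf) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (d in 1:3) {
    if (s[d] >= 0) {
      dst[[d]] <- (1 + s[d]):dm[d]; src[[d]] <- 1:(dm[d] - s[d])
    } else {
      dst[[d]] <- 1:(dm[d] + s[d]); src[[d]] <- (1 - s[d]):dm[d]
    }
    if (abs(s[d]) >= dm[d]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Label connected components of a 3D logical mask
#'
#' Iterative minimum-label propagation: each foreground voxel starts with its
#' own (column-major) linear index and repeatedly adopts the smallest label in
#' its neighborhood until convergence. Components are renumbered 1..K in order
#' of their smallest linear index, which makes labeling deterministic
#' (lexicographic seed voxel in z-fastest order).
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26 (default).
#' @return integer array, 0 = background, 1..K component ids.
#' @keywords internal
#' @noRd
label_components_3d <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  if (length(dm) != 3) stopf("mask must be a 3D array")
  offs <- neighbor_offsets(connectivity)
  lab <- array(Inf, dm)
  lab[mask] <- which(mask)
  repeat {
    old <- lab
    for (i in seq_len(nrow(offs))) {
      lab <- pmin(lab, shift3d(lab, offs[i, ]))
      lab[!mask] <- Inf
    }
    if (identical(old, lab)) break
  }
  out <- array(0L, dm)
  if (any(mask)) {
    vals <- sort(unique(lab[mask]))
    out[mask] <- match(lab[mask], vals)
  }
  out
}

# Physical voxel-center coordinate arrays for a (z,y,x) volume.
# 0-based index convention: voxel [i,j,k] (1-based in R) is centered at
# ((i-1)*dz, (j-1)*dy, (k-1)*dx) micrometers.
voxel_coords <- function(dimv, voxel_um) {
  zz <- (seq_len(dimv[1]) - 1) * voxel_um[1]
  yy <- (seq_len(dimv[2]) - 1) * voxel_um[2]
  xx <- (seq_len(dimv[3]) - 1) * voxel_um[3]
  list(
    z = array(rep(zz, times = dimv[2] * dimv[3]), dimv),
    y = array(rep(rep(yy, each = dimv[1]), times = dimv[3]), dimv),
    x = array(rep(xx, each = dimv[1] * dimv[2]), dimv)
  )
}

# 6-neighborhood boundary of a 3D mask: voxels in the mask with at least one
# face neighbor outside it (volume edges count as outside).
mask_boundary <- function(mask) {
  offs <- neighbor_offsets(6L)
  inside <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offs))) {
    inside <- inside & (shift3d(mask + 0, offs[i, ], fill = 0) > 0)
  }
  mask & !inside
}

# Separable dilation of a mask by r voxels per axis (box structuring element;
# scalar r = Chebyshev). Per-axis radii keep physical gap tolerances honest on
# anisotropic voxels.
dilate_mask <- function(mask, r = 1L) {
  if (length(r) == 1) r <- rep(r, 3L)
  out <- mask
  for (d in 1:3) {
    if (r[d] <= 0) next
    for (k in seq_len(r[d])) {
      s_pos <- s_neg <- c(0L, 0L, 0L)
      s_pos[d] <- 1L; s_neg[d] <- -1L
      out <- out | (shift3d(out + 0, s_pos, fill = 0) > 0) |
        (shift3d(out + 0, s_neg, fill = 0) > 0)
    }
  }
  out
}

# First crossing of `level` on the decreasing flank after the profile maximum,
# linearly interpolated. x must be sorted increasing. Returns NA if the
# profile never drops below `level` after its peak.
first_falling_crossing <- function(x, y, level) {
  i0 <- which.max(y)
  if (i0 == length(y)) return(NA_real_)
  for (i in (i0 + 1):length(y)) {
    if (y[i] < level) {
      x1 <- x[i - 1]; x2 <- x[i]; y1 <- y[i - 1]; y2 <- y[i]
      return(x1 + (level - y1) / (y2 - y1) * (x2 - x1))
    }
  }
  NA_real_
}

# Polyline arc length
polyline_length <- function(xy) {
  d <- diff(xy)
  sum(sqrt(rowSums(d^2)))
}
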