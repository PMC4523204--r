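# Independent oracles used across tests. These deliberately avoid the
# package's own implementations.

# Exhaustive union-find connected-component labeling over a 3D logical mask.
uf_label <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(array(0L, dm))
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  pos <- arrayInd(idx, dm)
  lookup <- new.env(hash = TRUE)
  for (k in seq_along(idx)) assign(as.character(idx[k]), k, envir = lookup)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  for (k in seq_along(idx)) {
    for (o in seq_len(nrow(offs))) {
      np <- pos[k, ] + offs[o, ]
      if (any(np < 1) || any(np > dm)) next
      nidx <- np[1] + (np[2] - 1) * dm[1] + (np[3] - 1) * dm[1] * dm[2]
      j <- mget(as.character(nidx), envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) {
        ri <- find(k); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_along(idx), find, 1L)
  out <- array(0L, dm)
  out[idx] <- match(roots, sort(unique(roots)))
  out
}

# Ramanujan approximation of an ellipse perimeter
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Rotate every (y, x) plane of a (t, z, y, x) stack by 90 degrees
rotate_stack_90 <- function(stack) {
  dm <- stack$dim
  chans <- lapply(stack$channels, function(a) {
    out <- array(0, c(dm[1], dm[2], dm[4], dm[3]))
    for (t in seq_len(dm[1])) for (z in seq_len(dm[2])) {
      m <- matrix(a[t, z, , ], dm[3], dm[4])
      out[t, z, , ] <- t(m)[, dm[3]:1]
    }
    out
  })
  image_stack4d(chans, voxel_um = stack$voxel_um[c(1, 3, 2)],
                dt_s = stack$dt_s)
}

make_timecourse <- function(labels, dt = 20, id = "tc") {
  structure(list(id = id, labels = labels,
                 t_s = (seq_along(labels) - 1) * dt, coupling_frame = 1L),
            class = "pattern_timecourse")
}

# occurrence_table-shaped matrix built directly from per-pattern percentages
occ_from_rows <- function(lam_pct, other = "central") {
  pats <- c("central", "invagination", "diffuse", "lamellum", "peripheral",
            "asymmetric", "none")
  m <- matrix(0, 7, length(lam_pct), dimnames = list(pats, NULL))
  m["lamellum", ] <- lam_pct
  m[other, ] <- pmax(0, 60 - lam_pct)
  m["none", ] <- 100 - colSums(m[setdiff(pats, "none"), , drop = FALSE])
  class(m) <- c("occurrence_table", "matrix", "array")
  m
}
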