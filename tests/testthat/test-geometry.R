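couple <- gen_cell_couple_stack(scene_spec("lamellum", seed = 5))

test_that("segmentation recovers both cell masks", {
  scene <- segment_cells(couple$stack)
  # analytic truncated-sphere voxel counts
  vx <- couple$stack$voxel_um
  n_t <- sum(scene$tcell_mask)
  n_a <- sum(scene$apc_mask)
  cap_vol <- function(R, h) pi * h^2 * (3 * R - h) / 3
  v_t <- (4 / 3 * pi * 5^3 - cap_vol(5, 5 - sqrt(5^2 - 3.5^2))) / prod(vx)
  v_a <- (4 / 3 * pi * 5.5^3 - cap_vol(5.5, 5.5 - sqrt(5.5^2 - 3.5^2))) / prod(vx)
  expect_lt(abs(n_t / v_t - 1), 0.04)
  expect_lt(abs(n_a / v_a - 1), 0.04)
  expect_false(any(scene$tcell_mask & scene$apc_mask))
})

test_that("blank or single-cell volumes raise a no-conjugate error", {
  blank <- image_stack4d(list(cell = array(0.01, c(1, 8, 10, 10))),
                         voxel_um = c(1, 1, 1))
  expect_error(segment_cells(blank), "no conjugate")
  one <- array(0.01, c(1, 10, 12, 12))
  one[1, 4:7, 4:8, 4:8] <- 1
  single <- image_stack4d(list(cell = one), voxel_um = c(1, 1, 1))
  expect_error(segment_cells(single), "no conjugate")
})

test_that("interface frame recovers the true diameter and orientation", {
  # the first boundary layer samples the sphere up to half an x-voxel past
  # the cap base, where it is wider; D recovers within 10% of truth
  for (s in c(2, 9, 23, 31, 40, 47, 55, 63, 72, 88, 91, 99)) {
    g <- gen_cell_couple_stack(scene_spec("none", seed = s))
    scene <- segment_cells(g$stack)
    fr <- build_interface_frame(scene)
    expect_lt(abs(fr$D_um / g$truth$diameter_um - 1), 0.10)
    # normal points into the T cell: T centroid at positive depth
    ijk <- which(scene$tcell_mask, arr.ind = TRUE)
    ctr <- colMeans(sweep(ijk - 1, 2, g$stack$voxel_um, `*`))
    expect_gt(frame_coords(fr, matrix(ctr, 1))$delta, 0)
  }
})

test_that("single-point contact yields a degenerate but valid frame", {
  vol <- array(0.01, c(1, 13, 13, 26))
  co <- lamellaR:::voxel_coords(c(13, 13, 26), c(1, 1, 1))
  vol[1, , , ] <- 0.01 + (sqrt((co$z - 6)^2 + (co$y - 6)^2 + (co$x - 6)^2) <= 5) +
    0.7 * (sqrt((co$z - 6)^2 + (co$y - 6)^2 + (co$x - 18)^2) <= 5)
  st <- image_stack4d(list(cell = vol), voxel_um = c(1, 1, 1))
  scene <- segment_cells(st)
  fr <- build_interface_frame(scene, gap_um = 2)  # 1-voxel seam at 1 um voxels
  expect_lte(fr$D_um, 2 * sqrt(2))  # at most ~2 voxels of contact
})

test_that("no contact voxels raise a no-interface error", {
  vol <- array(0.01, c(1, 12, 12, 30))
  co <- lamellaR:::voxel_coords(c(12, 12, 30), c(1, 1, 1))
  vol[1, , , ] <- 0.01 + (sqrt((co$z - 5.5)^2 + (co$y - 5.5)^2 + (co$x - 4)^2) <= 3.5) +
    0.7 * (sqrt((co$z - 5.5)^2 + (co$y - 5.5)^2 + (co$x - 24)^2) <= 3.5)
  st <- image_stack4d(list(cell = vol), voxel_um = c(1, 1, 1))
  scene <- segment_cells(st)
  expect_error(build_interface_frame(scene), "no interface")
})

test_that("depth and radial coordinates are invariant under 90-degree rotation", {
  rot <- rotate_stack_90(couple$stack)
  s1 <- segment_cells(couple$stack)
  s2 <- segment_cells(rot)
  f1 <- build_interface_frame(s1)
  f2 <- build_interface_frame(s2)
  expect_equal(f1$D_um, f2$D_um, tolerance = 1e-8)
  r1 <- classify_frame(couple$stack)
  r2 <- classify_frame(rot)
  expect_identical(r1$label, r2$label)
  expect_equal(r1$region$d_um, r2$region$d_um, tolerance = 1e-8)
})

test_that("interface diameter never exceeds the T cell extent", {
  for (s in 1:5) {
    g <- gen_cell_couple_stack(scene_spec("none", seed = s))
    scene <- segment_cells(g$stack)
    fr <- build_interface_frame(scene)
    ijk <- which(scene$tcell_mask, arr.ind = TRUE)
    P <- sweep(ijk - 1, 2, g$stack$voxel_um, `*`)
    extent <- max(dist(P[sample(nrow(P), min(400, nrow(P))), ]))
    expect_lte(fr$D_um, extent + 1)
  }
})

test_that("midplane outlines match analytic perimeters and round-trip ratios", {
  # ellipsoid pair: perimeter of extracted midplane outline vs Ramanujan
  dims <- c(9, 40, 80)
  co <- lamellaR:::voxel_coords(dims, c(1, 0.25, 0.25))
  a <- 4; b <- 3
  vol <- array(0.01, c(1, dims))
  t_el <- ((co$x - 6) / a)^2 + ((co$y - 5) / b)^2 + ((co$z - 4) / 2.5)^2 <= 1
  a_el <- ((co$x - 14.5) / a)^2 + ((co$y - 5) / b)^2 + ((co$z - 4) / 2.5)^2 <= 1
  vol[1, , , ] <- 0.01 + t_el + 0.7 * a_el
  st <- image_stack4d(list(cell = vol), voxel_um = c(1, 0.25, 0.25))
  scene <- segment_cells(st)
  cc <- extract_midplane_contours(scene, z_mid = 5)
  per <- sum(sqrt(rowSums(diff(rbind(cc$tcell$xy, cc$tcell$xy[1, ]))^2)))
  expect_lt(abs(per / ellipse_perimeter(a, b) - 1), 0.02)
  expect_error(extract_midplane_contours(
    list(tcell_mask = array(FALSE, dims), apc_mask = array(TRUE, dims),
         voxel_um = c(1, 0.25, 0.25))), "empty mask")
})

test_that("label propagation matches the union-find oracle", {
  set.seed(42)
  for (i in 1:8) {
    dm <- c(sample(3:6, 1), sample(3:7, 1), sample(3:7, 1))
    mask <- array(stats::runif(prod(dm)) < 0.4, dm)
    for (conn in c(6L, 26L)) {
      got <- lamellaR:::label_components_3d(mask, conn)
      want <- uf_label(mask, conn)
      # same partition and same deterministic numbering (min linear index)
      expect_identical(got, want)
    }
  }
})
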