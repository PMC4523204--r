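test_that("FWHM of a noiseless Gaussian bar equals 2.3548 sigma", {
  g <- gen_sted_structures(n = 1, depth_um = 2.0, width_um = 0.8,
                           noise_sd = 0, size_jitter = 0, seed = 0)
  m <- measure_structure_fwhm(g$image, unlist(g$truth[1, c("x_um", "y_um")]),
                              bg = g$bg)
  sig_d <- 2.0 / (2 * sqrt(2 * log(2)))
  expect_equal(m$depth_um, 2 * sqrt(2 * log(2)) * sig_d, tolerance = 0.02)
  expect_equal(m$width_um, 0.8, tolerance = 0.02)
})

test_that("FWHM is invariant to additive background and multiplicative gain", {
  g <- gen_sted_structures(n = 1, depth_um = 1.5, width_um = 0.9,
                           noise_sd = 0, size_jitter = 0, seed = 1)
  seed_xy <- unlist(g$truth[1, c("x_um", "y_um")])
  base <- measure_structure_fwhm(g$image, seed_xy, bg = g$bg)
  shifted <- measure_structure_fwhm(g$image + 3, seed_xy, bg = g$bg + 3)
  gained <- measure_structure_fwhm(g$image * 5, seed_xy, bg = g$bg * 5)
  expect_equal(base$depth_um, shifted$depth_um, tolerance = 1e-9)
  expect_equal(base$depth_um, gained$depth_um, tolerance = 1e-9)
  expect_equal(base$width_um, gained$width_um, tolerance = 1e-9)
})

test_that("structures below the qualification fold are rejected", {
  g <- gen_sted_structures(n = 1, depth_um = 1.5, width_um = 0.9,
                           amplitude = 0.2, bg = 1, noise_sd = 0,
                           size_jitter = 0, seed = 0)  # peak 1.2x background
  expect_null(measure_structure_fwhm(g$image,
                                     unlist(g$truth[1, c("x_um", "y_um")]),
                                     bg = 1))
})

test_that("profiles that never drop below half-max raise an error", {
  flatish <- matrix(2, 40, 40)
  flatish[20, 20] <- 2.1
  expect_error(measure_structure_fwhm(flatish + 0, c(19 * 0.025, 19 * 0.025),
                                      bg = 0.1, pixel_um = 0.025),
               "unbounded")
})

test_that("depth profiles match analytic slab averages of an exponential", {
  g <- gen_actin_depth_volume(periph_pct = c(100 * exp(-1), 100 * exp(-2)),
                              center_pct = c(100 * exp(-1), 100 * exp(-2)))
  pr <- depth_profile(g$volume, g$frame, "full", 0.5, g$voxel_um,
                      "pct_above_bg", bg = 1)
  lam <- 1
  analytic <- function(a, b) 100 * g$truth$center$A / 100 * lam *
    (exp(-a / lam) - exp(-b / lam)) / (b - a)
  for (i in 1:6) {
    a <- (i - 1) * 0.5
    expect_lt(abs(pr$value[i] / analytic(a, a + 0.5) - 1), 0.02)
  }
})

test_that("the early-actin preset reproduces the periphery/center depth values", {
  g <- gen_actin_depth_volume()
  pp <- depth_profile(g$volume, g$frame, "periphery", 0.5, g$voxel_um,
                      "pct_above_bg", bg = 1)
  cc <- depth_profile(g$volume, g$frame, "center", 0.5, g$voxel_um,
                      "pct_above_bg", bg = 1)
  expect_equal(pp$value[3], 57, tolerance = 0.02)  # slab starting at 1 um
  expect_equal(pp$value[5], 19, tolerance = 0.02)  # slab starting at 2 um
  expect_equal(cc$value[3], 40, tolerance = 0.02)
  expect_equal(cc$value[5], 11, tolerance = 0.02)
})

test_that("uniform volumes give flat relative profiles", {
  fr <- make_interface_frame(c(5, 5, 1), c(0, 0, 1), diameter_um = 8)
  vol <- array(3, c(21, 21, 12))
  pr <- depth_profile(vol, fr, "full", 0.5, c(0.5, 0.5, 0.5))
  expect_true(all(abs(pr$value - 1) < 1e-12))
})

test_that("half-max depth interpolates linearly and errors when unreached", {
  p <- structure(list(depth_um = c(0, 1, 2), value = c(1, 0.5, 0.1)),
                 class = "depth_profile")
  expect_equal(half_max_depth(p), 1)
  p2 <- structure(list(depth_um = c(0, 1, 2), value = c(1, 0.9, 0.8)),
                  class = "depth_profile")
  expect_error(half_max_depth(p2), "not reached")
  g <- gen_actin_depth_volume(periph_pct = c(100 * exp(-1), 100 * exp(-2)),
                              center_pct = c(100 * exp(-1), 100 * exp(-2)))
  pr <- depth_profile(g$volume, g$frame, "full", 0.25, g$voxel_um,
                      "pct_above_bg", bg = 1)
  expect_lt(abs(half_max_depth(pr) - log(2)), 0.25)  # within bin tolerance
})

test_that("depth-profile slab averaging equals brute-force voxel binning", {
  set.seed(5)
  dims <- c(8, 9, 10)
  vx <- c(0.7, 0.5, 0.6)
  vol <- array(stats::runif(prod(dims)), dims)
  fr <- make_interface_frame(c(2.4, 2.0, 0.9), c(0, 0, 1), diameter_um = 6)
  pr <- depth_profile(vol, fr, "full", 0.6, vx, max_depth_um = 4)
  co <- frame_coords(fr, lamellaR:::volume_coord_matrix(dims, vx))
  sel <- co$delta >= 0 & co$delta < 4 & co$rho <= 1
  want <- tapply(as.vector(vol)[sel], floor(co$delta[sel] / 0.6), mean)
  expect_equal(unname(pr$raw_mean), unname(as.vector(want)))
})

test_that("staging rules combine uropod, elongation and nucleus distance", {
  expect_identical(stage_call(TRUE, 1.0, rule = "fluorescence")$stage, "early")
  expect_identical(stage_call(FALSE, 1.3, rule = "fluorescence")$stage, "early")
  expect_identical(stage_call(FALSE, 1.2, rule = "fluorescence")$stage, "late")
  expect_identical(stage_call(FALSE, 1.2, 0.7, rule = "em")$stage, "late")
  expect_identical(stage_call(FALSE, 1.3, 1.2, rule = "em")$stage, "early")
  expect_identical(stage_call(TRUE, 1.0, 0.5, rule = "em")$stage, "late")
  expect_error(stage_call(FALSE, 0, rule = "fluorescence"), "elongation")
  expect_error(stage_call(FALSE, 1.3, rule = "em"), "nucleus")
})
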