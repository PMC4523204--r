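test_that("generated undulation ratios are measured back exactly", {
  for (ratio in c(1, 1.2, 1.5, 2.1, 3)) {
    g <- gen_interface_contours(ratio = ratio, seed = 3)
    m <- interface_length_diameter(g$tcell)
    expect_equal(m$ratio, ratio, tolerance = 0.005)
  }
})

test_that("straight and semicircular interfaces hit their closed forms", {
  flat <- gen_interface_contours(ratio = 1, seed = 0)
  expect_equal(interface_length_diameter(flat$tcell)$ratio, 1, tolerance = 1e-9)
  semi <- gen_interface_contours(shape = "semicircle", seed = 0)
  expect_equal(interface_length_diameter(semi$tcell)$ratio, pi / 2,
               tolerance = 1e-4)
})

test_that("unreachable ratios and invalid inputs are rejected", {
  expect_error(gen_interface_contours(ratio = 0.9), "ratio")
  expect_error(gen_interface_contours(ratio = 50, n_cycles = 1), "unreachable")
  expect_error(contour2d(cbind(0:1, 0:1), closed = TRUE), "3 vertices")
})

test_that("tight-contact length follows the planted gap profile", {
  # parallel lines: all-or-nothing
  mk <- function(gap_um) {
    x <- seq(0, 5, length.out = 201)
    list(t = contour2d(cbind(c(x, 2.5), c(rep(0, 201), 3)),
                       interface_idx = c(1L, 201L)),
         a = contour2d(cbind(c(x, 2.5), c(rep(-gap_um, 201), -3)),
                       interface_idx = c(1L, 201L)))
  }
  near <- mk(0.010)
  expect_equal(tight_contact_length(near$t, near$a), 5, tolerance = 1e-6)
  far <- mk(0.050)
  expect_equal(tight_contact_length(far$t, far$a), 0)

  for (s in 0:4) {
    g <- gen_interface_contours(preset = "em_early", seed = s)
    m <- interface_length_diameter(g$tcell)
    tc <- tight_contact_length(g$tcell, g$apc)
    expect_lt(abs(tc / m$L_um - g$truth$tight_fraction), 0.03)
    expect_lte(tc, m$L_um)
  }
})

test_that("area extrapolation is exactly the squared length ratio", {
  expect_identical(area_fold_from_length_ratio(1), 1)
  expect_equal(area_fold_from_length_ratio(2.1), 4.41)
  expect_equal(area_fold_from_length_ratio(1.5), 2.25)
  r <- 1 + 2 * stats::runif(50)
  expect_equal(area_fold_from_length_ratio(r), r^2)
})

test_that("ratio >= 1 for any polyline, equality only when straight", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    xy <- cbind(seq(0, 5, length.out = n), stats::rnorm(n, 0, 0.5))
    xy[c(1, n), 2] <- 0
    m <- interface_length_diameter(contour2d(xy, closed = FALSE,
                                             interface_idx = c(1L, n)))
    expect_gte(m$ratio, 1)
  }
})

test_that("contour rendering and re-extraction preserve the undulation", {
  # EM-scale undulation at EM-scale pixels (peak curvature radius ~0.1 um
  # requires pixels well below it)
  g <- gen_interface_contours(preset = "em_early", seed = 3)
  ti <- render_contour_mask(g$tcell, pixel_um = 0.04)
  ai <- render_contour_mask(g$apc, pixel_um = 0.04)
  cc <- contours_from_masks(ti, ai, pixel_um = 0.04)
  expect_equal(interface_length_diameter(cc$tcell)$ratio, 2.1,
               tolerance = 0.05)
  # CFSE-mode (0.4 um) live undulation
  g2 <- gen_interface_contours(preset = "live_early", seed = 3)
  ti2 <- render_contour_mask(g2$tcell, pixel_um = 0.4)
  ai2 <- render_contour_mask(g2$apc, pixel_um = 0.4)
  cc2 <- contours_from_masks(ti2, ai2, pixel_um = 0.4)
  expect_equal(interface_length_diameter(cc2$tcell)$ratio, 1.35,
               tolerance = 0.04)
})

test_that("contour generation is seed-deterministic", {
  a <- gen_interface_contours(preset = "em_late", seed = 11)
  b <- gen_interface_contours(preset = "em_late", seed = 11)
  expect_identical(a, b)
})
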