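test_that("linear threshold masks follow their definition", {
  img <- array(1, c(2, 3, 4))
  expect_true(all(linear_threshold_mask(img, 0.5)))
  img2 <- array(0, c(5, 5, 5)); img2[3, 3, 3] <- 10
  m <- linear_threshold_mask(img2, 0.9)
  expect_identical(sum(m), 1L)
  expect_true(m[3, 3, 3])
  g <- gen_coloc_volume(mode = "cluster_overlap", seed = 2)
  mA <- linear_threshold_mask(g$A, 0.5)
  expect_lt(abs(sum(mA) / (prod(dim(g$A)) / 2) - 1), 0.1)
})

test_that("Pearson correlation hits its closed-form cases and invariances", {
  A <- array(stats::rnorm(1000, 5), c(10, 10, 10))
  expect_equal(pearson_coloc(A, A), 1)
  expect_equal(pearson_coloc(A, -A + 7), -1)
  B <- array(stats::rnorm(1000, 5), c(10, 10, 10))
  expect_equal(pearson_coloc(A, B), pearson_coloc(2 * A + 3, 0.5 * B - 1))
  expect_error(pearson_coloc(A, array(2, dim(A))), "zero variance")
  expect_error(pearson_coloc(A, B, array(FALSE, dim(A))), "empty ROI")
})

test_that("generated correlation is recovered at the planted rho", {
  g <- gen_coloc_volume(rho = 0.6, seed = 0)
  expect_equal(pearson_coloc(g$A, g$B), 0.6, tolerance = 0.02)
})

test_that("Manders coefficients report planted overlap fractions", {
  # identical masks and confined signal give M1 = M2 = 1
  A <- array(0, c(4, 6, 6)); A[2:3, 2:3, 2:3] <- 2
  m <- linear_threshold_mask(A, 0.5)
  mm <- manders_coloc(A, A, m, m)
  expect_equal(mm$M1, 1); expect_equal(mm$M2, 1)

  g <- gen_coloc_volume(mode = "cluster_overlap", overlap_fraction = 0.34,
                        n_clusters = 200, seed = 0)
  mA <- linear_threshold_mask(g$A, 0.5)
  mB <- linear_threshold_mask(g$B, 0.5)
  got <- manders_coloc(g$A, g$B, mA, mB)
  expect_equal(got$M2, 0.34, tolerance = 0.02)
})

test_that("cluster detection finds planted blobs and merges touching ones", {
  expect_identical(nrow(detect_clusters_3d(array(0, c(5, 5, 5)),
                                           threshold = 0.5)), 0L)
  depths <- c(0.5, 1.3, 2.1, 2.9, 3.7, 4.5, 5.3)
  g <- gen_cluster_field(depths, sigma_um = 0.4,
                         volume_shape = c(24, 64, 64), seed = 1)
  cs <- detect_clusters_3d(g$volume, threshold = 0.25,
                           voxel_um = c(0.4, 0.4, 0.4))
  expect_identical(nrow(cs), 7L)
  got <- cs[order(cs$centroid_y_um), ]
  tr <- g$truth$centers_um[order(g$truth$centers_um[, "y_um"]), ]
  expect_true(all(abs(got$centroid_x_um - tr[, "x_um"]) < 0.4))
  expect_true(all(abs(got$centroid_y_um - tr[, "y_um"]) < 0.4))

  # two blobs whose bridge stays above threshold merge into one cluster
  v <- array(0, c(5, 9, 9))
  v[3, 3, 3:7] <- c(1, 0.6, 0.55, 0.6, 1)
  expect_identical(nrow(detect_clusters_3d(v, threshold = 0.5,
                                           min_size_voxels = 1L)), 1L)
  expect_identical(nrow(detect_clusters_3d(v, threshold = 0.58,
                                           min_size_voxels = 1L)), 2L)
})

test_that("cluster counts are invariant under axis transposition", {
  g <- gen_cluster_field(c(0.8, 2.0, 3.2), seed = 3)
  n1 <- nrow(detect_clusters_3d(g$volume, threshold = 0.3))
  n2 <- nrow(detect_clusters_3d(aperm(g$volume, c(3, 1, 2)), threshold = 0.3))
  n3 <- nrow(detect_clusters_3d(aperm(g$volume, c(2, 3, 1)), threshold = 0.3))
  expect_identical(n1, n2)
  expect_identical(n1, n3)
})

test_that("interface distances are read off the APC half-maximum", {
  g <- gen_cluster_field(c(0.5, 2.0), seed = 4)
  cs <- detect_clusters_3d(g$volume, threshold = 0.3,
                           voxel_um = c(0.4, 0.4, 0.4))
  got <- sort(vapply(seq_len(nrow(cs)), function(i) {
    cluster_interface_distance(
      unlist(cs[i, c("centroid_z_um", "centroid_y_um", "centroid_x_um")]),
      g$apc, g$frame, c(0.4, 0.4, 0.4))
  }, 0))
  expect_true(all(abs(got - c(0.5, 2.0)) < 0.4))  # within one voxel
  # cluster on the interface plane
  on_if <- cluster_interface_distance(
    c(4.4, 9.2, g$truth$interface_x_um), g$apc, g$frame, c(0.4, 0.4, 0.4))
  expect_lt(abs(on_if), 0.4)
  expect_error(cluster_interface_distance(c(4.4, 9.2, 12), g$apc * 0 + 1,
                                          g$frame, c(0.4, 0.4, 0.4)),
               "no half-max")
})

test_that("depth correlation reproduces planted correlations", {
  x <- 1:10
  expect_equal(depth_correlation(x, 2 * x + 3)$r, 1)
  expect_error(depth_correlation(1:2, 2:3), "undefined")
  # cross-check p-value against the t distribution via cor.test
  set.seed(2)
  a <- stats::rnorm(15); b <- 0.7 * a + stats::rnorm(15, 0, 0.5)
  got <- depth_correlation(a, b)
  ref <- stats::cor.test(a, b)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(got$p, ref$p.value)
  # planted r = 0.73, n = 15, 200 replicates
  set.seed(3)
  rs <- replicate(200, {
    x <- stats::rnorm(15)
    y <- 0.73 * x + sqrt(1 - 0.73^2) * stats::rnorm(15)
    depth_correlation(x, y)$r
  })
  expect_lt(abs(mean(rs) - 0.73), 0.05)
})
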