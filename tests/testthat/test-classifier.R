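test_that("background estimation is a robust median", {
  m <- array(TRUE, c(4, 5, 5))
  expect_equal(estimate_background(array(100, c(4, 5, 5)), m), 100)
  v <- array(c(rep(100, 50), rep(300, 50)), c(4, 5, 5))
  expect_equal(estimate_background(v, m), 200)
})

test_that("detected accumulation matches the generated fold and geometry", {
  g <- gen_cell_couple_stack(scene_spec("lamellum", seed = 3))
  res <- classify_frame(g$stack)
  expect_lt(abs(res$region$f / 1.8 - 1), 0.1)
  expect_gte(res$region$c, 0.85)  # run-span coverage is half-voxel conservative
  expect_lt(abs(res$region$d_um - 3), 0.5)

  perip <- gen_cell_couple_stack(scene_spec("peripheral", seed = 3))
  rp <- classify_frame(perip$stack)$region
  expect_gt(rp$rho_bar, 0.70)

  none <- gen_cell_couple_stack(scene_spec("none", seed = 3))
  sc <- segment_cells(none$stack)
  fr <- build_interface_frame(sc)
  vol <- get_volume(none$stack, "sensor", 1)
  bg <- estimate_background(vol, sc$tcell_mask)
  expect_null(detect_accumulation(vol, fr, sc$tcell_mask, bg,
                                  none$stack$voxel_um))
})

test_that("the decision tree follows its stated rules", {
  mk <- function(c, rho, d, os = FALSE) {
    structure(list(n_voxels = 100L, f = 1.8, c = c, rho_bar = rho, d_um = d,
                   one_sided = os), class = "accumulation_region")
  }
  expect_identical(classify_pattern(NULL), "none")
  expect_identical(classify_pattern(mk(1.0, 0.6, 0.4)), "diffuse")
  expect_identical(classify_pattern(mk(1.0, 0.6, 3.0)), "lamellum")
  expect_identical(classify_pattern(mk(1.0, 0.6, 1.2)), "diffuse") # tie-break
  expect_identical(classify_pattern(mk(0.45, 0.3, 0.8)), "central")
  expect_identical(classify_pattern(mk(0.25, 0.2, 2.5)), "invagination")
  expect_identical(classify_pattern(mk(0.5, 0.85, 0.8)), "peripheral")
  expect_identical(classify_pattern(mk(0.35, 0.8, 0.8, os = TRUE)), "asymmetric")
  expect_error(classify_pattern(mk(NaN, 0.5, 1)), "non-finite")
})

test_that("each generated pattern classifies to its truth label", {
  for (p in c("central", "invagination", "diffuse", "lamellum",
              "peripheral", "asymmetric")) {
    g <- gen_cell_couple_stack(scene_spec(p, seed = 7))
    expect_identical(classify_frame(g$stack)$label, p)
  }
  g <- gen_cell_couple_stack(scene_spec("lamellum", fold_over_background = 1,
                                        seed = 7))
  expect_identical(classify_frame(g$stack)$label, "none")
})

test_that("classification is invariant to intensity rescaling and deterministic", {
  g <- gen_cell_couple_stack(scene_spec("central", seed = 11))
  r1 <- classify_frame(g$stack)
  scaled <- image_stack4d(lapply(g$stack$channels, function(a) a * 7.3),
                          voxel_um = g$stack$voxel_um, dt_s = g$stack$dt_s)
  r2 <- classify_frame(scaled)
  expect_identical(r1$label, r2$label)
  expect_identical(classify_frame(g$stack)$label, r1$label)
})

test_that("timecourses detect coupling and pattern switches", {
  g <- gen_cell_couple_stack(scene_spec(
    c("central", "central", "lamellum", "lamellum", "lamellum"),
    n_timepoints = 5, pre_frames = 2, seed = 13))
  tc <- classify_timecourse(g$stack)
  expect_identical(tc$coupling_frame, 3L)
  expect_identical(tc$t_s, seq(-40, 80, by = 20))
  expect_identical(tc$labels[1:2], c("none", "none"))
  # switch frame within +/- 1 of the truth
  sw_true <- 3  # first lamellal frame within the coupled part (index 5 overall)
  sw_got <- which(tc$labels == "lamellum")[1] - tc$coupling_frame + 1
  expect_lte(abs(sw_got - sw_true), 1)
  # matching labels on >= 90% of coupled frames
  expect_gte(mean(tc$labels[3:7] == g$truth$labels[3:7]), 0.8)

  blank <- gen_cell_couple_stack(scene_spec("none", n_timepoints = 2,
                                            pre_frames = 1, seed = 13))
  # uncoupled frames of a none-scene still segment; labels stay none
  tcb <- classify_timecourse(blank$stack)
  expect_true(all(tcb$labels == "none"))
})

test_that("occurrence tables tabulate percentages that sum to 100", {
  tcs <- c(replicate(21, make_timecourse(c("lamellum", "lamellum")),
                     simplify = FALSE),
           replicate(35, make_timecourse(c("central", "lamellum")),
                     simplify = FALSE))
  occ <- occurrence_table(tcs)
  expect_equal(unname(occ["lamellum", 1]), 100 * 21 / 56)
  expect_equal(unname(occ["lamellum", 2]), 100)
  expect_equal(unname(colSums(occ)), rep(100, 2))
  expect_identical(attr(occ, "n"), c(56L, 56L))

  ch <- change_table(occ)
  expect_equal(unname(ch["lamellum", 1]), 100 - 100 * 21 / 56)
  const <- occurrence_table(replicate(10, make_timecourse(
    rep("lamellum", 3)), simplify = FALSE))
  expect_true(all(change_table(const) == 0))
})
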