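test_that("normalization rescales to the prebleach mean and re-zeroes time", {
  raw <- c(100, 100, 100, 40, 60, 75, 85, 90, 92, 94, 95, 95, 95)
  tt <- seq(0, by = 0.255, length.out = length(raw))
  tr <- normalize_trace(raw, tt, background = 0)
  expect_equal(tr$y[1:3], rep(1, 3))
  expect_equal(tr$t_s[4], 0)
  expect_error(normalize_trace(raw, tt, background = 100), "background")
  expect_error(normalize_trace(raw[1:3], tt[1:3]), "post-bleach")
})

test_that("generated traces round-trip to their planted floor", {
  g <- gen_frap_trace(0.5, mobile_fraction = 0.6, bleach_depth = 0.5,
                      noise_sd = 0, t_max_s = 20)
  expect_equal(g$trace$y[g$trace$t_s == 0], 0.5)
  expect_equal(mean(g$trace$y[g$trace$t_s < 0]), 1)
  f <- fit_recovery(g$trace)
  expect_equal(f$Ymin, g$truth$Ymin, tolerance = 1e-6)
  expect_equal(f$Ymax, g$truth$Ymax, tolerance = 1e-6)
  expect_equal(f$mobile_fraction, 0.6, tolerance = 1e-6)
})

test_that("noiseless fits recover rate constants to numerical tolerance", {
  expect_equal(fit_recovery(gen_frap_trace(log(2), noise_sd = 0,
                                           t_max_s = 15)$trace)$t_half_s,
               1, tolerance = 1e-6)
  for (k in c(0.05, 0.2, 1, 5)) {
    tm <- max(10, 4 / k)
    f <- fit_recovery(gen_frap_trace(k, noise_sd = 0, t_max_s = tm)$trace)
    expect_equal(f$k_per_s, k, tolerance = 1e-6)
  }
})

test_that("rescaling time rescales the fitted rate exactly", {
  g <- gen_frap_trace(0.8, noise_sd = 0, t_max_s = 12)
  f1 <- fit_recovery(g$trace)
  tr2 <- frap_trace(g$trace$t_s * 3, g$trace$y, g$trace$n_prebleach)
  f2 <- fit_recovery(tr2)
  expect_equal(f2$k_per_s, f1$k_per_s / 3, tolerance = 1e-8)
})

test_that("flat post-bleach traces are flagged as non-recovering", {
  g <- gen_frap_trace(0.5, mobile_fraction = 0, noise_sd = 0, t_max_s = 10)
  f <- fit_recovery(g$trace)
  expect_false(f$recovered)
  expect_true(is.na(f$t_half_s))
  expect_identical(f$mobile_fraction, 0)
})

test_that("estimator bias of t_half stays below 5% under noise", {
  th <- vapply(0:49, function(s) {
    fit_recovery(gen_frap_trace(0.6931, noise_sd = 0.03, t_max_s = 12,
                                seed = s)$trace)$t_half_s
  }, 0)
  expect_lt(abs(mean(th) / 1 - 1), 0.05)
})

test_that("central- and lamellal-type plateaus separate without overlap", {
  mf <- function(plateau_lo, plateau_hi, seeds) {
    vapply(seeds, function(s) {
      set.seed(s)
      pl <- stats::runif(1, plateau_lo, plateau_hi)
      fit_recovery(gen_frap_trace(0.3, mobile_fraction = pl,
                                  noise_sd = 0.03, t_max_s = 25,
                                  seed = s)$trace)$mobile_fraction
    }, 0)
  }
  central <- mf(0.30, 0.44, 1:15)
  lamellal <- mf(0.63, 0.76, 101:115)
  expect_lt(max(central), min(lamellal))
})

test_that("frap_fit behaves like a fitted model object", {
  g <- gen_frap_trace(0.7, noise_sd = 0.02, t_max_s = 12, seed = 1)
  f <- fit_recovery(g$trace)
  expect_named(coef(f), c("Ymin", "Ymax", "k"))
  expect_length(fitted(f), sum(g$trace$t_s >= 0))
  expect_equal(fitted(f) + residuals(f), g$trace$y[g$trace$t_s >= 0])
  expect_equal(predict(f, 1e6), f$Ymax, tolerance = 1e-6)
  expect_output(print(f), "t1/2")
})
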