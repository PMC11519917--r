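test_that("integrated decay image subtracts frames and flags clipped pixels", {
  tc <- timing_cam(80)
  i0 <- matrix(10, 4, 4)
  pair <- frame_pair(i0, i0, tc)
  expect_true(all(integrated_decay_image(pair)$p == 0))
  # a common additive background cancels exactly
  i1 <- matrix(runif(16, 10, 20), 4, 4)
  p_plain <- integrated_decay_image(frame_pair(i0, i1, tc))$p
  p_offset <- integrated_decay_image(frame_pair(i0 + 7, i1 + 7, tc))$p
  expect_identical(p_plain, p_offset)
  # negative differences are clipped and flagged
  neg <- integrated_decay_image(frame_pair(i0 + 1, i0, tc))
  expect_true(all(neg$p == 0))
  expect_true(all(bitwAnd(neg$mask, 2L) > 0))
  expect_error(frame_pair(i0, matrix(0, 3, 3), tc), "identical shape")
})

test_that("rendered pairs match the closed-form frame integrals", {
  law <- law62()
  tc <- timing_cam(80)
  sc <- build_scene("uniform", dim = c(6, 6), o2 = 40)
  pair <- render_pair(sc, law, tc)
  fi <- frame_integrals(kinetics_params(lifetime_from_o2(law, 40)), tc)
  expect_equal(mean(integrated_decay_image(pair)$p), fi$p,
               tolerance = 1e-12)
})

test_that("P_N is invariant to multiplicative brightness and guards zeros", {
  tc <- timing_cam(80)
  set.seed(3)
  i0 <- matrix(runif(64, 5, 10), 8, 8)
  i1 <- i0 + matrix(runif(64, 1, 5), 8, 8)
  a <- normalized_decay_image(frame_pair(i0, i1, tc), guard = 1e-9)
  b <- normalized_decay_image(frame_pair(3 * i0, 3 * i1, tc), guard = 1e-9)
  expect_equal(a$pn, b$pn, tolerance = 1e-14)
  # dark pixel: masked by the division guard, not infinite
  i0[1, 1] <- 0; i1[1, 1] <- 0
  g <- normalized_decay_image(frame_pair(i0, i1, tc), guard = 1)
  expect_true(bitwAnd(g$mask[1, 1], 4L) > 0)
  expect_true(all(is.finite(g$pn)))
})

test_that("P_N flattens a strong illumination gradient (noiseless cuvette)", {
  # 5x top-to-bottom brightness gradient, uniform oxygen: P images vary,
  # P_N is spatially uniform
  law <- law62()
  tc <- timing_cam(80)
  sc <- build_scene("cuvette_gradient", dim = c(48, 32), o2 = 30,
                    illumination_ratio = 5)
  pair <- render_pair(sc, law, tc)
  p <- integrated_decay_image(pair)$p
  expect_gt(max(p) / min(p), 4.9)
  pn <- normalized_decay_image(pair, guard = 1e-9)$pn
  expect_lt((max(pn) - min(pn)) / mean(pn), 0.005)
})

test_that("two-point calibration solves the Stern-Volmer line exactly", {
  cal <- fit_calibration(c(1.58, 0.395), c(0, 100), method = "two-point")
  expect_equal(cal$ksv, 0.03, tolerance = 1e-14)
  expect_equal(cal$pn0, 1.58)
  # published planar-optode constants form a valid calibration (80 us pulse)
  pub <- calibration_curve(pn0 = 1.58, ksv = 0.0391, r2 = 0.99,
                           method = "least-squares",
                           timing = timing_cam(80))
  expect_s3_class(pub, "calibration_curve")
  expect_error(fit_calibration(c(1, 1), c(50, 50)), "distinct")
  expect_warning(fit_calibration(c(1.2, 0.6), c(50, 100), "two-point"),
                 "near 0")
})

test_that("calibration recovers the generating model exactly when linear", {
  # complete-excitation regime: the model's Stern-Volmer plot is exactly
  # linear, so the fit must recover the apparent constant to 1e-10
  law <- law62()
  tc <- timing_config(3000)
  o2 <- c(0, 25, 50, 100, 200)
  pc <- predicted_calibration(law, tc, o2)
  cal <- fit_calibration(pc$table$pn, o2, method = "least-squares",
                         timing = tc)
  expect_equal(cal$ksv, pc$ksv_apparent, tolerance = 1e-10)
  expect_equal(cal$pn0, pc$table$pn[1], tolerance = 1e-12)
  expect_gt(cal$r2, 1 - 1e-10)
})

test_that("oxygen inversion applies the calibration pixel-wise", {
  cal <- calibration_curve(pn0 = 1.58, ksv = 0.0391)
  pn <- matrix(c(1.58, 0.79, 2.0, 0.0), 2, 2)
  map <- o2_from_pn(pn, cal)
  expect_equal(map$o2[1, 1], 0)
  expect_equal(map$o2[2, 1], (1.58 / 0.79 - 1) / 0.0391)
  expect_equal(map$o2[2, 1], 25.575, tolerance = 1e-4)
  # P_N above the anoxic value: reported 0, flagged out-of-range
  expect_equal(map$o2[1, 2], 0)
  expect_true(bitwAnd(map$mask[1, 2], 8L) > 0)
  # non-positive P_N masked
  expect_true(bitwAnd(map$mask[2, 2], 8L) > 0)
})

test_that("inversion round-trips the model beyond air saturation", {
  # supports the > 400% air saturation use case; exact in the linear regime
  law <- law62()
  tc <- timing_config(3000)
  pc <- predicted_calibration(law, tc, c(0, 100))
  cal <- fit_calibration(pc$table$pn, c(0, 100), method = "two-point",
                         timing = tc)
  pn400 <- predicted_calibration(law, tc, c(0, 400))$table$pn[2]
  map <- o2_from_pn(matrix(pn400, 1, 1), cal)
  expect_equal(map$o2[1, 1], 400, tolerance = 1e-6)
})

test_that("mismatched calibration timing is refused unless overridden", {
  law <- law62()
  sc <- build_scene("uniform", dim = c(4, 4), o2 = 50)
  pair <- render_pair(sc, law, timing_cam(80))
  pn <- normalized_decay_image(pair, guard = 1e-9)
  cal <- calibration_curve(pn0 = 0.39, ksv = 0.015, timing = timing_cam(160))
  expect_error(o2_from_pn(pn, cal), "fingerprint")
  expect_warning(o2_from_pn(pn, cal, override = TRUE), "mismatched")
  cal_ok <- calibration_curve(pn0 = 0.39, ksv = 0.015, timing = timing_cam(80))
  expect_silent(o2_from_pn(pn, cal_ok))
})

test_that("smoothing preserves constants and removes impulses", {
  const <- array(2.5, c(6, 6, 4))
  expect_equal(smooth_series(const)$stack, const)
  imp <- array(0, c(9, 9, 3))
  imp[5, 5, 2] <- 100
  sm <- smooth_series(imp)
  expect_lt(max(sm$stack), 1e-12)
  expect_warning(smooth_series(array(1, c(4, 4, 2))), "fewer than 3")
})

test_that("temporal smoothing reduces white-noise variance about threefold", {
  # a 1 x 1 series isolates the temporal stage: the 3 x 3 median over a
  # single replicated pixel is the identity
  set.seed(21)
  x <- array(rnorm(3000), c(1, 1, 3000))
  sm <- smooth_series(x)$stack
  ratio <- var(sm[1, 1, 2:2999]) / var(x[1, 1, ])
  expect_gt(ratio, 0.28)
  expect_lt(ratio, 0.40)
})

test_that("smoothing propagates invalid-pixel masks by majority", {
  st <- array(1, c(5, 5, 3))
  mk <- array(FALSE, c(5, 5, 3))
  mk[1:3, 1:3, ] <- TRUE        # solid invalid block
  mk[5, 5, 2] <- TRUE           # isolated invalid sample
  sm <- smooth_series(st, mask = mk)
  expect_true(sm$mask[2, 2, 2])
  expect_false(sm$mask[5, 5, 2])
})

test_that("two-gate estimator recovers monoexponential lifetimes exactly", {
  # gates at 41 and 47 us on exp(-t/62): lifetime 62 us, exactly
  f1 <- matrix(exp(-41 / 62), 3, 3)
  f2 <- matrix(exp(-47 / 62), 3, 3)
  r <- rld_lifetime(f1, f2, 41, 47)
  expect_equal(r$tau, matrix(62, 3, 3), tolerance = 1e-12)
  # gate separation 6 us with ratio e: 6 us
  r6 <- rld_lifetime(matrix(exp(1), 1, 1), matrix(1, 1, 1), 0, 6)
  expect_equal(r6$tau[1, 1], 6, tolerance = 1e-12)
  # equal gates (infinite lifetime) and non-positive ratios are masked
  bad <- rld_lifetime(matrix(c(1, -1, 0, 2), 2, 2),
                      matrix(c(1, 1, 1, 1), 2, 2), 41, 47)
  expect_true(bad$mask[1, 1])
  expect_true(bad$mask[2, 1])
  expect_true(bad$mask[1, 2])
  expect_error(rld_lifetime(f1, f2, 41, 41), "non-zero")
})

test_that("two-gate and frame-straddling responses are monotone together", {
  # across a noiseless oxygen gradient both readouts must order the pixels
  # identically (both are strictly monotone in lifetime)
  law <- law62()
  o2 <- seq(0, 300, by = 30)
  tau <- lifetime_from_o2(law, o2)
  pn <- predicted_calibration(law, timing_ideal(80), o2)$table$pn
  f1 <- matrix(exp(-41 / tau), 1)
  f2 <- matrix(exp(-47 / tau), 1)
  rld <- rld_lifetime(f1, f2, 41, 47)$tau[1, ]
  expect_true(all(diff(pn) < 0))
  expect_true(all(diff(rld) < 0))
  expect_equal(order(pn), order(rld))
})
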