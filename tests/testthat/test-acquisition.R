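test_that("frame integrals reproduce quadrature-derived reference values", {
  # tau_p = tau_d = 62 us, 80 us pulse, complete capture, no carry-over;
  # reference values frozen from adaptive quadrature of the timecourse
  fi <- frame_integrals(kinetics_params(62), timing_ideal(80))
  expect_equal(fi$i0, 35.06128, tolerance = 1e-6)
  expect_equal(fi$f1, 44.93872, tolerance = 1e-6)
  expect_equal(fi$i1, 80, tolerance = 1e-10)
  expect_equal(fi$p, 44.93872, tolerance = 1e-6)
  fi160 <- frame_integrals(kinetics_params(62), timing_ideal(160))
  expect_equal(fi160$i0, 102.695, tolerance = 1e-5)
  expect_equal(fi160$f1, 57.30504, tolerance = 1e-6)
  expect_equal(fi160$i1, 160, tolerance = 1e-10)
  # vanishing lifetime: no afterglow, frames identical
  tiny <- frame_integrals(kinetics_params(1e-6), timing_ideal(80))
  expect_lt(tiny$f1, 1e-5)
  expect_lt(tiny$p, 1e-5)
})

test_that("carry-over is the shifted decay integral of the previous pulse", {
  tc <- timing_config(80, exposure = Inf, interframe = 6, carry_over = TRUE)
  fi <- frame_integrals(kinetics_params(62), tc)
  expect_equal(fi$carry / fi$f1, exp(-6 / 62), tolerance = 1e-12)
  expect_equal(fi$carry / fi$f1, 0.9077, tolerance = 1e-4)
  off <- frame_integrals(kinetics_params(62),
                         timing_config(80, interframe = 6,
                                       carry_over = FALSE))
  expect_identical(off$carry, 0)
})

test_that("closed-form integrals match adaptive quadrature on random draws", {
  set.seed(42)
  for (i in 1:200) {
    cs <- draw_case()
    a <- frame_integrals(cs$kin, cs$timing)
    b <- frame_integrals_numeric(cs$kin, cs$timing)
    for (f in c("i0", "i1", "f1", "carry", "p")) {
      scale <- max(abs(b[[f]]), 1e-12)
      expect_lt(abs(a[[f]] - b[[f]]) / scale, 1e-8)
    }
  }
})

test_that("every photon excited by the pulse is counted exactly once", {
  # with tau_p = tau_d, complete capture, no carry-over and no background,
  # I0 + F1 = F0 * tau_L
  set.seed(7)
  for (i in 1:30) {
    tau <- runif(1, 5, 400)
    f0 <- runif(1, 0.1, 10)
    tl <- runif(1, 10, 500)
    fi <- frame_integrals(kinetics_params(tau, f0 = f0),
                          timing_config(tl, carry_over = FALSE))
    expect_equal(fi$i0 + fi$f1, f0 * tl, tolerance = 1e-10)
  }
})

test_that("a common background contributes equally and cancels exactly in P", {
  tc <- timing_config(80, exposure = 2000, interframe = 50)
  base <- frame_integrals(kinetics_params(62), tc)
  with_bg <- frame_integrals(kinetics_params(62, background = 3.7), tc)
  expect_identical(with_bg$p, base$p)
  expect_equal(with_bg$i0 - base$i0, 3.7 * 2000)
  expect_equal(with_bg$i1 - base$i1, 3.7 * 2000)
  # pure background: both frames identical, P exactly zero
  pure <- frame_integrals(kinetics_params(62, f0 = 0, background = 5), tc)
  expect_identical(pure$p, 0)
})

test_that("P grows with lifetime and carry-over decays with interframe time", {
  taus <- seq(5, 300, by = 5)
  p <- vapply(taus, function(td)
    frame_integrals(kinetics_params(td), timing_ideal(80))$p, 0)
  expect_true(all(diff(p) > 0))
  tcs <- c(1, 5, 20, 100, 500, 5000)
  cc <- vapply(tcs, function(tci)
    frame_integrals(kinetics_params(62),
                    timing_config(80, interframe = tci))$carry, 0)
  expect_true(all(diff(cc) < 0))
  expect_lt(cc[length(cc)], 1e-30)
  expect_error(timing_config(80, exposure = 40), "exposure")
})

test_that("predicted calibration handles the unquenched sensor", {
  pc <- predicted_calibration(sv_law(62, 0), timing_ideal(80),
                              seq(0, 200, by = 50))
  expect_equal(diff(range(pc$table$pn)), 0)
  expect_equal(pc$ksv_apparent, 0)
  expect_error(predicted_calibration(law62(), timing_ideal(80), 50),
               "at least two")
})

test_that("apparent K_SV converges to the sensor K_SV for long pulses", {
  # integrating the full decay makes P proportional to tau_d only once the
  # pulse fully excites the dye; the residual bias of the apparent constant
  # shrinks as pulse_length / tau_d0 grows (about tau_d0 / (2 tau_L))
  law <- law62()
  rel_err <- vapply(c(5, 10, 20), function(ratio) {
    pc <- predicted_calibration(law, timing_ideal(62 * ratio),
                                seq(0, 100, by = 25))
    abs(pc$ksv_apparent - law$ksv) / law$ksv
  }, 0)
  expect_true(all(diff(rel_err) < 0))
  expect_lt(rel_err[3], 0.03)
})

test_that("model Stern-Volmer ratio at 80 us lies in the published 2-4 band", {
  pc <- predicted_calibration(law62(), timing_ideal(80), c(0, 100))
  ratio <- pc$table$pn[1] / pc$table$pn[2]
  expect_gt(ratio, 2)
  expect_lt(ratio, 4)
})

test_that("timing scan is deterministic and SNR grows with photon budget", {
  law <- law62()
  tc <- timing_cam(80)
  nm <- noise_model()
  grid <- c(60, 120, 240)
  s1 <- timing_scan(law, tc, grid, nm, replicates = 4, seed = 5, region = 24)
  s2 <- timing_scan(law, tc, grid, nm, replicates = 4, seed = 5, region = 24)
  expect_identical(s1$table, s2$table)
  snr_at_120 <- vapply(c(1e3, 1e4, 2.5e4), function(budget) {
    timing_scan(law, tc, 120, nm, photon_budget = budget, replicates = 6,
                seed = 9, region = 32)$table$snr
  }, 0)
  expect_true(all(diff(snr_at_120) > 0))
  expect_error(timing_scan(law, tc, 120, nm, photon_budget = 0), "positive")
  expect_error(timing_scan(law, tc, 120, nm, replicates = 1), "replicates")
})

test_that("the zero-noise limit reports the capped SNR sentinel", {
  sc <- timing_scan(law62(), timing_cam(80), 80, noise_model(),
                    photon_budget = Inf, replicates = 2, seed = 1,
                    region = 8)
  expect_equal(sc$table$snr, 1e6)
})

test_that("recommended pulse window picks the qualifying contiguous range", {
  fake <- list(table = data.frame(
    pulse_length_us = seq(60, 300, by = 20),
    ksv_apparent = 0.02,
    snr = ifelse(seq(60, 300, by = 20) >= 100 &
                 seq(60, 300, by = 20) <= 200, 25, 5)))
  expect_equal(recommend_pulse_window(fake, snr_threshold = 20), c(100, 200))
  none <- fake
  none$table$snr <- 5
  expect_equal(recommend_pulse_window(none), c(NA_real_, NA_real_))
  # windows are nested in the threshold
  scan <- timing_scan(law62(), timing_cam(80), seq(40, 280, by = 40),
                      noise_model(), replicates = 6, seed = 2, region = 32)
  w20 <- recommend_pulse_window(scan, snr_threshold = 20)
  w30 <- recommend_pulse_window(scan, snr_threshold = 30)
  if (!anyNA(w30)) {
    expect_gte(w30[1], w20[1])
    expect_lte(w30[2], w20[2])
  } else {
    succeed("higher threshold yields the empty window, a subset")
  }
})
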