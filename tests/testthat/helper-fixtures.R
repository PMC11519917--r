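# Shared fixtures: the PtTFPP-like sensor (62 us unquenched, 22 us at air
# saturation) and a few standard timings.

law62 <- function() sv_law(62, (62 / 22 - 1) / 100)

# idealized complete-decay-capture timing (theoretical model)
timing_ideal <- function(pulse = 80) timing_config(pulse)

# realistic scientific-camera timing: long exposure, 300 us interframe
timing_cam <- function(pulse = 80) {
  timing_config(pulse, exposure = 2500, interframe = 300)
}

# random but valid kinetics/timing draws for property tests
draw_case <- function() {
  tau_d <- runif(1, 5, 500)
  tau_p <- if (runif(1) < 0.5) tau_d else runif(1, 5, 500)
  tl <- runif(1, 20, 400)
  exposure <- if (runif(1) < 0.5) Inf else tl + runif(1, 0, 3000)
  interframe <- if (runif(1) < 0.5) Inf else runif(1, 1, 500)
  list(
    kin = kinetics_params(tau_d = tau_d, tau_p = tau_p,
                          f0 = runif(1, 0.1, 10),
                          background = if (is.finite(exposure))
                            runif(1, 0, 0.5) else 0),
    timing = timing_config(tl, exposure = exposure, interframe = interframe,
                           carry_over = runif(1) < 0.7,
                           frame1_decay_overlap =
                             if (runif(1) < 0.3) runif(1, 0, 5) else 0))
}

# Gaussian-particle image for PIV fixtures; particles at (row, col)
particle_image <- function(particles, dim = c(128, 128), baseline = 0.05) {
  sc <- build_scene("uniform", dim = dim, o2 = 0, dye = baseline,
                    particles = particles)
  framestraddle:::.dye_with_particles(sc)
}

random_particles <- function(n, dim = c(128, 128), margin = 5, sigma = 1) {
  data.frame(row = runif(n, margin, dim[1] - margin),
             col = runif(n, margin, dim[2] - margin),
             sigma = sigma, amplitude = 1)
}
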