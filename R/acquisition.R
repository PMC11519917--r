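#' Frame-straddling acquisition timing
#'
#' Describes the synchronized pulse/camera timing: the excitation pulse of
#' length `pulse_length` sits at the very end of the first (dim) exposure and
#' at the very beginning of the second (bright) exposure; the camera needs the
#' interframe time `interframe` between the two exposures to read out. The
#' decay of the second pulse is recorded during the remaining
#' `exposure - pulse_length` of the bright frame (the decay-capture window).
#' `exposure = Inf` expresses the idealized complete-decay-capture model used
#' for the theoretical predictions; `interframe = Inf` disables carry-over of
#' the first pulse's afterglow into the bright frame.
#'
#' @param pulse_length excitation pulse trigger length (microseconds), `> 0`.
#' @param exposure camera exposure per frame (microseconds),
#'   `>= pulse_length`; may be `Inf`.
#' @param interframe interframe (readout) time between the two exposures
#'   (microseconds), `> 0`; may be `Inf`.
#' @param carry_over logical; include the previous pulse's decay tail that
#'   falls into the bright frame. Only the immediately preceding pulse is
#'   modeled: at realistic pair periods (>= 10 ms at <= 100 double-frame
#'   pairs per second) earlier pulses contribute less than `exp(-150)` of the
#'   peak emission.
#' @param frame1_decay_overlap duration (microseconds) of decay recorded at
#'   the end of the dim frame, to model trigger skew between the pulse end
#'   and the first exposure end. Default 0: the dim exposure ends exactly
#'   with its pulse.
#' @return An object of class `timing_config`.
#' @export
#' @examples
#' timing_config(80)                      # idealized full-capture model
#' timing_config(80, exposure = 2500, interframe = 10)  # high-speed camera
timing_config <- function(pulse_length, exposure = Inf, interframe = Inf,
                          carry_over = TRUE, frame1_decay_overlap = 0) {
  if (!is.numeric(pulse_length) || length(pulse_length) != 1L ||
      !is.finite(pulse_length) || pulse_length <= 0)
    stop("'pulse_length' must be a single positive number (microseconds)")
  if (!is.numeric(exposure) || length(exposure) != 1L || exposure < pulse_length)
    stop("'exposure' must be >= 'pulse_length' ",
         "(the pulse must fit inside the exposure)")
  if (!is.numeric(interframe) || length(interframe) != 1L || interframe <= 0)
    stop("'interframe' must be a single positive number (microseconds)")
  if (frame1_decay_overlap < 0)
    stop("'frame1_decay_overlap' must be non-negative")
  structure(
    list(pulse_length = pulse_length, exposure = exposure,
         interframe = interframe, carry_over = isTRUE(carry_over),
         frame1_decay_overlap = frame1_decay_overlap),
    class = "timing_config")
}

#' @export
print.timing_config <- function(x, ...) {
  cat("Frame-straddling timing: pulse", x$pulse_length, "us, exposure",
      x$exposure, "us, interframe", x$interframe, "us\n")
  cat("  decay-capture window:", x$exposure - x$pulse_length,
      "us; carry-over", if (x$carry_over) "on" else "off", "\n")
  invisible(x)
}

# timing fingerprint used to tie calibrations to acquisition settings
.timing_fingerprint <- function(timing) {
  c(pulse_length = timing$pulse_length, exposure = timing$exposure,
    interframe = timing$interframe)
}

.same_timing <- function(a, b, tol = 1e-6) {
  fa <- .timing_fingerprint(a); fb <- .timing_fingerprint(b)
  ok <- (is.infinite(fa) & is.infinite(fb)) |
    abs(fa - fb) <= tol * pmax(abs(fa), abs(fb), 1)
  all(ok)
}

# Vectorized closed-form straddling integrals over tau_d (and tau_p), at unit
# equilibrium emission and zero background. Returns per-element rise integral
# (i0 without background), decay integral f1, and carry-over c.
.straddle_core <- function(tau_d, tau_p, timing) {
  tl <- timing$pulse_length
  w  <- timing$exposure - tl          # decay-capture window, may be Inf
  fm <- -expm1(-tl / tau_p)           # peak emission at pulse end
  rise  <- tl - tau_p * fm            # integral of the rise over the pulse
  decay_frac <- if (is.finite(w)) -expm1(-w / tau_d) else 1
  f1 <- fm * tau_d * decay_frac
  ov <- timing$frame1_decay_overlap
  if (ov > 0) rise <- rise + fm * tau_d * (-expm1(-ov / tau_d))
  cc <- 0
  if (timing$carry_over && is.finite(timing$interframe)) {
    # decay of the previous pulse enters the bright frame a delay of
    # (frame-1 overlap + interframe) after that pulse ended, and is recorded
    # for the full bright exposure
    delay <- ov + timing$interframe
    seen <- if (is.finite(timing$exposure))
      exp(-delay / tau_d) - exp(-(delay + timing$exposure) / tau_d)
    else exp(-delay / tau_d)
    cc <- fm * tau_d * seen
  }
  list(rise = rise, f1 = f1, carry = cc)
}

.assemble_integrals <- function(core, f0, bg_per_frame, timing) {
  i0 <- f0 * core$rise + bg_per_frame
  f1 <- f0 * core$f1
  cc <- f0 * core$carry
  i1 <- i0 + f1 + cc
  p  <- f1 + cc
  structure(
    list(i0 = i0, i1 = i1, f1 = f1, carry = cc, p = p,
         pn = p / (i0 + i1), timing = timing),
    class = "decay_integrals")
}

.background_per_frame <- function(background, timing) {
  if (background == 0) return(0)
  if (!is.finite(timing$exposure))
    stop("a non-zero background requires a finite exposure ",
         "(an infinite exposure would integrate infinite background)")
  background * timing$exposure
}

#' Closed-form frame-straddling integrals
#'
#' Evaluates the dim-frame integral `I0` (excitation rise only, plus
#' background over the full exposure), the bright-frame integral
#' `I1 = I0 + F1 + C` (rise, recorded decay `F1`, and carry-over `C` of the
#' previous pulse's afterglow), the integrated luminescence decay
#' `P = I1 - I0`, and its normalized form `P_N = P / (I0 + I1)`. The
#' normalization denominator is fixed package-wide so that calibration and
#' measurement always share it. A constant background rate contributes
#' `background * exposure` to both frames and cancels exactly in `P`.
#'
#' @param kinetics a [kinetics_params()] object (its `t_on`/`t_off` are
#'   ignored; the pulse placement is taken from `timing`).
#' @param timing a [timing_config()] object.
#' @return An object of class `decay_integrals` with elements `i0`, `i1`,
#'   `f1`, `carry`, `p`, `pn` (all intensity-microseconds except the
#'   dimensionless `pn`).
#' @seealso [frame_integrals_numeric()] for the quadrature cross-check.
#' @export
#' @examples
#' kp <- kinetics_params(tau_d = 62)
#' frame_integrals(kp, timing_config(80))   # idealized complete capture
frame_integrals <- function(kinetics, timing) {
  stopifnot(inherits(kinetics, "kinetics_params"),
            inherits(timing, "timing_config"))
  core <- .straddle_core(kinetics$tau_d, kinetics$tau_p, timing)
  bg <- .background_per_frame(kinetics$background, timing)
  .assemble_integrals(core, kinetics$f0, bg, timing)
}

#' @export
print.decay_integrals <- function(x, ...) {
  cat("Frame-straddling integrals (intensity us):\n")
  cat(sprintf("  I0 = %.6g  I1 = %.6g  F1 = %.6g  carry = %.6g\n",
              x$i0, x$i1, x$f1, x$carry))
  cat(sprintf("  P = %.6g  P_N = %.6g (%.2f%%)\n", x$p, x$pn, 100 * x$pn))
  invisible(x)
}

#' Frame-straddling integrals by adaptive quadrature
#'
#' Computes the same quantities as [frame_integrals()] by numerically
#' integrating [emission_timecourse()] over the exposure windows with
#' [stats::integrate()]. Intended as an independent oracle in tests; the
#' closed form should agree to better than `1e-8` relative.
#'
#' @inheritParams frame_integrals
#' @param rel_tol relative accuracy requested from the quadrature.
#' @return An object of class `decay_integrals`.
#' @export
frame_integrals_numeric <- function(kinetics, timing, rel_tol = 1e-10) {
  stopifnot(inherits(kinetics, "kinetics_params"),
            inherits(timing, "timing_config"))
  tl <- timing$pulse_length
  kp <- kinetics_params(tau_d = kinetics$tau_d, f0 = kinetics$f0,
                        tau_p = kinetics$tau_p, t_on = 0, t_off = tl,
                        background = 0)
  quad <- function(f, lower, upper) {
    if (upper <= lower) return(0)
    r <- integrate(f, lower, upper, rel.tol = rel_tol, abs.tol = 0,
                   stop.on.error = FALSE)
    if (!r$message %in% "OK")
      stop("quadrature did not converge: ", r$message)
    r$value
  }
  emis <- function(t) .emission_eval(kp, t)
  rise <- quad(emis, 0, tl)
  ov <- timing$frame1_decay_overlap
  if (ov > 0) rise <- rise + quad(emis, tl, tl + ov)
  w <- timing$exposure - tl
  f1 <- quad(emis, tl, if (is.finite(w)) tl + w else Inf)
  cc <- 0
  if (timing$carry_over && is.finite(timing$interframe)) {
    lo <- tl + ov + timing$interframe
    hi <- if (is.finite(timing$exposure)) lo + timing$exposure else Inf
    cc <- quad(emis, lo, hi)
  }
  bg <- .background_per_frame(kinetics$background, timing)
  .assemble_integrals(list(rise = rise / kinetics$f0, f1 = f1 / kinetics$f0,
                           carry = cc / kinetics$f0),
                      kinetics$f0, bg, timing)
}

# least-squares fit of pn0/pn = 1 + k * o2 with the intercept fixed at 1
.fit_sv_ratio <- function(pn, o2) {
  i0 <- which.min(o2)
  pn0 <- pn[i0]
  y <- pn0 / pn
  k <- sum((y - 1) * o2) / sum(o2^2)
  fitted <- 1 + k * o2
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum((y - fitted)^2) / ss_tot
  list(pn0 = pn0, k = max(k, 0), r2 = r2)
}

#' Predicted calibration curve of the acquisition model
#'
#' Evaluates the closed-form frame integrals along an oxygen grid, taking the
#' lifetime at each grid point from the sensor law (with the rise time tied
#' to the decay lifetime), and fits the apparent Stern-Volmer response
#' `P_N(0)/P_N = 1 + K_SV_apparent * o2` by least squares with the intercept
#' fixed at 1. Because the frames integrate the decay rather than sample it,
#' the apparent constant differs slightly from the sensor's lifetime
#' constant; it converges to it as `pulse_length / tau_d0` grows.
#'
#' @param law a [sv_law()] or [empirical_law()] object.
#' @param timing a [timing_config()] object.
#' @param o2_grid numeric vector (>= 2 points) of oxygen levels,
#'   % air saturation; should include 0 (otherwise the lowest level is used
#'   as the reference with a warning).
#' @param f0 equilibrium emission rate used for the model evaluation.
#' @return An object of class `predicted_calibration`: a list with `table`
#'   (data frame `o2`, `tau_d`, `i0`, `i1`, `p`, `pn`), `ksv_apparent`,
#'   `pn0`, `r2`, `law` and `timing`.
#' @export
#' @examples
#' law <- sv_law(62, (62 / 22 - 1) / 100)
#' pc <- predicted_calibration(law, timing_config(80), seq(0, 100, by = 25))
#' pc$ksv_apparent
predicted_calibration <- function(law, timing, o2_grid, f0 = 1) {
  stopifnot(inherits(law, "lifetime_law"), inherits(timing, "timing_config"))
  if (!is.numeric(o2_grid) || length(o2_grid) < 2L)
    stop("'o2_grid' must contain at least two oxygen levels to fit a curve")
  if (any(o2_grid < 0)) stop("'o2_grid' must be non-negative")
  if (min(o2_grid) > 0)
    warning("'o2_grid' does not include 0; using the lowest level (",
            min(o2_grid), "% air sat.) as the P_N reference")
  tau_d <- lifetime_from_o2(law, o2_grid)
  core <- .straddle_core(tau_d, tau_d, timing)
  i0 <- f0 * core$rise
  p <- f0 * (core$f1 + core$carry)
  i1 <- i0 + p
  pn <- p / (i0 + i1)
  fit <- .fit_sv_ratio(pn, o2_grid)
  structure(
    list(table = data.frame(o2 = o2_grid, tau_d = tau_d, i0 = i0, i1 = i1,
                            p = p, pn = pn),
         ksv_apparent = fit$k, pn0 = fit$pn0, r2 = fit$r2,
         law = law, timing = timing),
    class = "predicted_calibration")
}

#' @export
print.predicted_calibration <- function(x, ...) {
  cat("Predicted frame-straddling calibration over",
      nrow(x$table), "O2 levels\n")
  cat(sprintf("  apparent K_SV = %.6g per %% air sat., P_N(0) = %.4g, R2 = %.4f\n",
              x$ksv_apparent, x$pn0, x$r2))
  invisible(x)
}

#' Scan pulse lengths for apparent K_SV and signal-to-noise ratio
#'
#' For each candidate pulse length the apparent Stern-Volmer constant is
#' computed from the noiseless model ([predicted_calibration()]), and the
#' signal-to-noise ratio of the normalized decay is measured by Monte-Carlo:
#' a homogeneous square region at a fixed reference oxygen level is rendered
#' repeatedly through the camera noise model and
#' `SNR = mean(P_N) / sd(P_N)` is evaluated over all pixels of all
#' replicates. The photon budget sets the expected counts per pixel in the
#' bright frame, so SNR grows with it.
#'
#' @param law sensor lifetime law.
#' @param timing a [timing_config()] template; each scan point replaces its
#'   pulse length (the exposure is kept at least as long as the pulse).
#' @param pulse_grid pulse lengths to scan (microseconds), each `> 0` and
#'   `<=` the template exposure.
#' @param noise a [noise_model()]; its photon scale is replaced by the one
#'   implied by `photon_budget`.
#' @param photon_budget expected counts per pixel in the bright frame at the
#'   template's pulse length, `> 0`. The implied photon scale is held fixed
#'   across the scan, so longer pulses collect proportionally more counts
#'   (and may saturate, which bounds the usable pulse range), shorter ones
#'   fewer.
#' @param replicates number of Monte-Carlo replicate pairs per pulse length,
#'   `>= 2`.
#' @param seed integer seed; the scan is deterministic given the seed.
#' @param o2_ref oxygen level of the homogeneous region (% air sat.).
#' @param o2_grid grid used for the apparent-K_SV fit.
#' @param region edge length (pixels) of the homogeneous square region.
#' @return An object of class `timing_scan_result` with a `table` data frame
#'   (`pulse_length_us`, `ksv_apparent`, `snr`) and the scan settings.
#' @export
timing_scan <- function(law, timing, pulse_grid, noise,
                        photon_budget = 2.5e4, replicates = 8, seed = 1,
                        o2_ref = 100, o2_grid = seq(0, 100, by = 25),
                        region = 64) {
  stopifnot(inherits(law, "lifetime_law"), inherits(timing, "timing_config"),
            inherits(noise, "noise_model"))
  if (any(pulse_grid <= 0) || any(pulse_grid > timing$exposure))
    stop("'pulse_grid' must lie in (0, exposure]")
  if (replicates < 2) stop("'replicates' must be at least 2")
  if (photon_budget <= 0) stop("'photon_budget' must be positive")
  set.seed(as.integer(seed %% .Machine$integer.max))
  scene <- build_scene("uniform", dim = c(region, region), o2 = o2_ref)
  snr_cap <- 1e6
  # anchor the photon budget at the template's pulse length: one fixed
  # photon scale for the whole scan, so longer pulses collect more photons
  # (and shorter ones fewer), as they do on a real camera
  i1_ref <- frame_integrals(
    kinetics_params(tau_d = lifetime_from_o2(law, o2_ref)), timing)$i1
  nm <- noise
  nm$photon_scale <- photon_budget / i1_ref
  rows <- lapply(pulse_grid, function(tl) {
    tcfg <- timing
    tcfg$pulse_length <- tl
    ksv <- predicted_calibration(law, tcfg, o2_grid)$ksv_apparent
    pn_vals <- unlist(lapply(seq_len(replicates), function(r) {
      pair <- render_pair(scene, law, tcfg, noise = nm,
                          seed = sample.int(.Machine$integer.max, 1))
      pni <- normalized_decay_image(pair)
      pni$pn[pni$mask == 0L]
    }))
    snr <- if (length(pn_vals) < 2L) {
      0  # saturation (or guard) masked the whole region: unusable signal
    } else {
      s <- sd(pn_vals)
      if (!is.finite(s) || s == 0) snr_cap else min(mean(pn_vals) / s, snr_cap)
    }
    c(ksv_apparent = ksv, snr = snr)
  })
  tab <- data.frame(pulse_length_us = pulse_grid,
                    do.call(rbind, rows))
  structure(list(table = tab, law = law, timing = timing,
                 photon_budget = photon_budget, o2_ref = o2_ref,
                 replicates = replicates, region = region, seed = seed),
            class = "timing_scan_result")
}

#' @export
print.timing_scan_result <- function(x, ...) {
  cat("Pulse-length scan over", nrow(x$table), "pulse lengths (",
      min(x$table$pulse_length_us), "-", max(x$table$pulse_length_us),
      "us ), photon budget", x$photon_budget, "counts/px\n")
  w <- recommend_pulse_window(x)
  if (anyNA(w)) cat("  no pulse window reaches the default SNR threshold\n")
  else cat("  recommended pulse window (SNR >= 20):", w[1], "-", w[2], "us\n")
  invisible(x)
}

#' Recommend a pulse-length operating window from a timing scan
#'
#' Returns the largest contiguous interval of scanned pulse lengths whose SNR
#' meets the threshold and whose apparent K_SV stays within a relative band
#' around its plateau value (the median apparent K_SV over the
#' SNR-qualifying points). An empty result (`c(NA, NA)`) is valid and means
#' no scanned pulse length qualifies.
#'
#' @param scan a [timing_scan()] result, or any list with a `table` data
#'   frame holding `pulse_length_us`, `ksv_apparent` and `snr` columns.
#' @param snr_threshold minimum acceptable SNR.
#' @param ksv_tolerance maximal relative deviation of the apparent K_SV from
#'   its plateau value.
#' @return Numeric vector `c(min_pulse, max_pulse)` in microseconds, or
#'   `c(NA, NA)` if no window qualifies.
#' @export
recommend_pulse_window <- function(scan, snr_threshold = 20,
                                   ksv_tolerance = 0.2) {
  tab <- scan$table
  if (is.null(tab) || nrow(tab) == 0L) stop("'scan' has an empty table")
  o <- order(tab$pulse_length_us)
  tab <- tab[o, ]
  good_snr <- tab$snr >= snr_threshold
  if (!any(good_snr)) return(c(NA_real_, NA_real_))
  plateau <- median(tab$ksv_apparent[good_snr])
  ok <- good_snr &
    abs(tab$ksv_apparent - plateau) <= ksv_tolerance * abs(plateau)
  if (!any(ok)) return(c(NA_real_, NA_real_))
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  best <- keep[which.max(runs$lengths[keep])]
  c(tab$pulse_length_us[starts[best]], tab$pulse_length_us[ends[best]])
}
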