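#' Camera noise model
#'
#' Photon shot noise, additive read noise and quantization for the synthetic
#' renderer. The noiseless signal is scaled by `photon_scale` (expected
#' counts per unit of noiseless signal), Poisson-sampled, read noise is
#' added, the counts are rounded to whole counts and clipped at the
#' full scale, and the result is divided back by the photon scale so the
#' rendered images stay in the units of the noiseless forward model. The
#' photon scale is therefore a single interpretable photon-budget knob.
#'
#' @param photon_scale expected counts per unit of noiseless signal, `> 0`;
#'   `Inf` selects the zero-noise limit (signal passed through untouched).
#' @param read_noise read noise standard deviation (counts), `>= 0`.
#' @param bit_depth sensor bit depth: 8, 12 or 16.
#' @param full_scale full-scale signal in counts; defaults to
#'   `2^bit_depth - 1`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(photon_scale = 125, read_noise = 2,
                        bit_depth = 16, full_scale = 2^bit_depth - 1) {
  if (!is.numeric(photon_scale) || photon_scale <= 0)
    stop("'photon_scale' must be positive")
  if (read_noise < 0) stop("'read_noise' must be non-negative")
  if (!bit_depth %in% c(8, 12, 16)) stop("'bit_depth' must be 8, 12 or 16")
  structure(list(photon_scale = photon_scale, read_noise = read_noise,
                 bit_depth = bit_depth, full_scale = full_scale),
            class = "noise_model")
}

#' Camera presets for the synthetic renderer
#'
#' Two double-frame camera archetypes: `"piv8"`, an 8-bit PIV camera with a
#' 62-microsecond interframe time, and `"highspeed12"`, a 12-bit high-speed
#' camera with a 10-microsecond interframe time. The returned list holds a
#' [timing_config()] (with the requested pulse length) and a matching
#' [noise_model()].
#'
#' @param name `"piv8"` or `"highspeed12"`.
#' @param pulse_length excitation pulse length (microseconds).
#' @param exposure camera exposure (microseconds).
#' @return List with elements `timing` and `noise`.
#' @export
camera_preset <- function(name = c("piv8", "highspeed12"),
                          pulse_length = 80, exposure = 2500) {
  name <- match.arg(name)
  switch(name,
    piv8 = list(
      timing = timing_config(pulse_length, exposure, interframe = 62),
      noise = noise_model(bit_depth = 8, full_scale = 255)),
    highspeed12 = list(
      timing = timing_config(pulse_length, exposure, interframe = 10),
      noise = noise_model(bit_depth = 12, full_scale = 4095)))
}

.check_field <- function(x, dim, name) {
  if (length(x) == 1L) x <- matrix(x, dim[1], dim[2])
  if (!is.matrix(x) || !all(dim(x) == dim))
    stop("'", name, "' must be a scalar or a ", dim[1], " x ", dim[2],
         " matrix")
  if (any(x < 0)) stop("'", name, "' must be non-negative")
  x
}

#' Assemble a synthetic scene
#'
#' A scene bundles the per-pixel fields the forward model needs: oxygen
#' (% air saturation), relative excitation irradiance, relative dye density,
#' a non-decaying background emission rate, and an optional ensemble of
#' tracer particles rendered as Gaussian spots on the dye-density field (so
#' the same frames serve both the chemical and the PIV readout).
#'
#' Available kinds:
#' \describe{
#'   \item{`uniform`}{constant fields; parameters `o2`, `illumination`,
#'     `dye`, `background`.}
#'   \item{`cuvette_gradient`}{uniform oxygen with an exponential
#'     illumination attenuation along the rows (light entering from the
#'     top), emulating absorption by a dense sensor-particle suspension;
#'     parameter `illumination_ratio` is the top-to-bottom irradiance ratio
#'     (default 5).}
#'   \item{`optode_patch`}{ambient oxygen with circular patches of
#'     different oxygen (e.g. gas vesicles over an algal thallus);
#'     parameter `patches` is a data frame with columns `row`, `col`, `r`,
#'     `o2`.}
#'   \item{`granule_wake`}{ambient oxygen with oxygen-depleted sinking
#'     granules and Gaussian-cross-section wakes trailing above them;
#'     parameters `granules` (data frame `row`, `col`, `r`), `core_o2`,
#'     `wake_width`, `wake_length` (pixels), `ambient`.}
#' }
#'
#' @param kind scene kind, see Details.
#' @param dim image size `c(rows, cols)` in pixels.
#' @param ... kind-specific parameters, see Details; all kinds accept
#'   `illumination`, `dye`, `background` and `particles` (data frame with
#'   columns `row`, `col`, and optionally `sigma`, `amplitude`).
#' @return An object of class `scene` with matrix fields `o2`,
#'   `illumination`, `dye`, `background` and the `particles` data frame (or
#'   `NULL`).
#' @export
#' @examples
#' sc <- build_scene("cuvette_gradient", dim = c(64, 64), o2 = 0,
#'                   illumination_ratio = 5)
#' range(sc$illumination)
build_scene <- function(kind = c("uniform", "cuvette_gradient",
                                 "optode_patch", "granule_wake"),
                        dim = c(64, 64), ...) {
  kind <- match.arg(kind)
  args <- list(...)
  dim <- as.integer(dim)
  take <- function(name, default) if (!is.null(args[[name]])) args[[name]]
                                  else default
  illum <- .check_field(take("illumination", 1), dim, "illumination")
  dye <- .check_field(take("dye", 1), dim, "dye")
  bg <- .check_field(take("background", 0), dim, "background")
  o2 <- switch(kind,
    uniform = .check_field(take("o2", 100), dim, "o2"),
    cuvette_gradient = {
      ratio <- take("illumination_ratio", 5)
      if (ratio < 1) stop("'illumination_ratio' must be >= 1")
      depth <- (seq_len(dim[1]) - 1) / max(dim[1] - 1, 1)
      illum <- illum * matrix(exp(-log(ratio) * depth), dim[1], dim[2])
      .check_field(take("o2", 100), dim, "o2")
    },
    optode_patch = {
      ambient <- take("ambient", 100)
      field <- matrix(ambient, dim[1], dim[2])
      patches <- take("patches", NULL)
      if (!is.null(patches)) {
        rr <- row(field); cc <- col(field)
        for (i in seq_len(nrow(patches))) {
          inside <- (rr - patches$row[i])^2 + (cc - patches$col[i])^2 <=
            patches$r[i]^2
          field[inside] <- patches$o2[i]
        }
      }
      field
    },
    granule_wake = {
      ambient <- take("ambient", 100)
      core <- take("core_o2", 40)
      width <- take("wake_width", 3)
      wlen <- take("wake_length", 20)
      granules <- take("granules", data.frame(row = dim[1] / 2,
                                              col = dim[2] / 2, r = 2))
      field <- matrix(ambient, dim[1], dim[2])
      rr <- row(field); cc <- col(field)
      deficit <- matrix(0, dim[1], dim[2])
      for (i in seq_len(nrow(granules))) {
        gr <- granules$row[i]; gc <- granules$col[i]
        # wake trails above a sinking granule (smaller row index)
        behind <- pmax(gr - rr, 0)
        d <- exp(-(cc - gc)^2 / (2 * width^2)) * exp(-behind / wlen)
        d[rr > gr + granules$r[i]] <- 0
        core_px <- (rr - gr)^2 + (cc - gc)^2 <= granules$r[i]^2
        d[core_px] <- 1
        deficit <- pmax(deficit, d)
      }
      field - (ambient - core) * deficit
    })
  o2 <- .check_field(o2, dim, "o2")
  particles <- take("particles", NULL)
  if (!is.null(particles)) {
    if (!all(c("row", "col") %in% names(particles)))
      stop("'particles' must have columns 'row' and 'col'")
    if (is.null(particles$sigma)) particles$sigma <- 1
    if (is.null(particles$amplitude)) particles$amplitude <- 1
  }
  structure(list(o2 = o2, illumination = illum, dye = dye, background = bg,
                 particles = particles, dim = dim),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat("Scene", x$dim[1], "x", x$dim[2], "px; O2",
      sprintf("%.1f - %.1f %% air sat.", min(x$o2), max(x$o2)))
  if (!is.null(x$particles)) cat(";", nrow(x$particles), "tracer particles")
  cat("\n")
  invisible(x)
}

# dye-density field including Gaussian tracer spots
.dye_with_particles <- function(scene, particles = scene$particles) {
  dye <- scene$dye
  if (is.null(particles) || nrow(particles) == 0L) return(dye)
  nr <- nrow(dye); nc <- ncol(dye)
  for (i in seq_len(nrow(particles))) {
    s <- particles$sigma[i]
    ext <- ceiling(4 * s)
    pr <- particles$row[i]; pc <- particles$col[i]
    rs <- max(1L, floor(pr - ext)):min(nr, ceiling(pr + ext))
    cs <- max(1L, floor(pc - ext)):min(nc, ceiling(pc + ext))
    if (!length(rs) || !length(cs)) next
    g <- outer(exp(-(rs - pr)^2 / (2 * s^2)), exp(-(cs - pc)^2 / (2 * s^2)))
    dye[rs, cs] <- dye[rs, cs] + particles$amplitude[i] * g
  }
  dye
}

.apply_noise <- function(img, noise) {
  s <- noise$photon_scale
  if (!is.finite(s)) {
    # infinite photon scale: the zero-noise limit, pass the signal through
    return(list(img = img,
                saturated = matrix(FALSE, nrow(img), ncol(img))))
  }
  lam <- as.vector(img) * s
  big <- lam > 1e7   # Gaussian tail where rpois would overflow
  counts <- numeric(length(lam))
  counts[!big] <- rpois(sum(!big), lambda = lam[!big])
  if (any(big)) counts[big] <- lam[big] + sqrt(lam[big]) * rnorm(sum(big))
  if (noise$read_noise > 0)
    counts <- counts + rnorm(length(img), 0, noise$read_noise)
  counts <- round(counts)
  counts[counts < 0] <- 0
  sat <- counts >= noise$full_scale
  counts[sat] <- noise$full_scale
  list(img = matrix(counts / s, nrow(img), ncol(img)),
       saturated = matrix(sat, nrow(img), ncol(img)))
}

#' Render a straddled frame pair through the forward model
#'
#' For each pixel the lifetime is taken from the sensor law at the local
#' oxygen level, the closed-form frame integrals are evaluated (rise time
#' tied to the decay lifetime) and scaled by the local excitation irradiance
#' times dye density, and the background rate times the exposure is added to
#' both frames. With a noise model, Poisson shot noise, Gaussian read noise,
#' quantization and full-scale clipping are then applied; the result is
#' bit-identical for a fixed seed.
#'
#' @param scene a [build_scene()] scene used for the dim frame (and, by
#'   default, the bright frame).
#' @param law sensor lifetime law ([sv_law()] or [empirical_law()]).
#' @param timing a [timing_config()]; a non-zero background requires a
#'   finite exposure.
#' @param noise a [noise_model()], or `NULL` for a noiseless render.
#' @param seed integer seed for the noise realization (required when
#'   `noise` is given).
#' @param scene_b optional scene for the bright frame, to model motion of
#'   particles/granules between the two pulses; must share the oxygen and
#'   background fields' shape.
#' @return A [frame_pair()]; with noise the `full_scale` element is the
#'   sensor full scale expressed in image units.
#' @export
render_pair <- function(scene, law, timing, noise = NULL, seed = NULL,
                        scene_b = NULL) {
  stopifnot(inherits(scene, "scene"), inherits(law, "lifetime_law"),
            inherits(timing, "timing_config"))
  if (is.null(scene_b)) scene_b <- scene
  tau_d <- lifetime_from_o2(law, as.vector(scene$o2))
  core <- .straddle_core(tau_d, tau_d, timing)
  dims <- scene$dim
  has_bg <- any(scene$background > 0) || any(scene_b$background > 0)
  bgf <- if (has_bg) .background_per_frame(1, timing) else 0
  bg_a <- bgf * scene$background
  bg_b <- bgf * scene_b$background
  gain_a <- scene$illumination * .dye_with_particles(scene)
  gain_b <- scene_b$illumination * .dye_with_particles(scene_b)
  rise <- matrix(core$rise, dims[1], dims[2])
  decay <- matrix(core$f1 + core$carry, dims[1], dims[2])
  i0 <- gain_a * rise + bg_a
  i1 <- gain_b * (rise + decay) + bg_b
  meta <- list(law = law, seed = seed)
  if (is.null(noise))
    return(frame_pair(i0, i1, timing, meta = meta))
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(seed)) stop("'seed' is required for a noisy render")
  set.seed(as.integer(seed %% .Machine$integer.max))
  na <- .apply_noise(i0, noise)
  nb <- .apply_noise(i1, noise)
  meta$noise <- noise
  frame_pair(na$img, nb$img, timing,
             full_scale = if (is.finite(noise$photon_scale))
               noise$full_scale / noise$photon_scale else NULL,
             saturated = na$saturated | nb$saturated, meta = meta)
}

#' Sinking-granule scenario for sequence rendering
#'
#' Describes oxygen-scavenging granules sinking through aerated water: each
#' granule carries an oxygen-depleted core and leaves a wake of reduced
#' oxygen behind it, while tracer particles are advected by a uniform
#' ambient flow. Physical units are converted to pixels through the pixel
#' pitch.
#'
#' @param dim image size `c(rows, cols)` in pixels.
#' @param granules data frame of initial granule positions: columns `row`,
#'   `col` (pixels) and `r` (radius, pixels).
#' @param sinking_speed granule sinking speed (mm/s), `>= 0`.
#' @param core_o2 oxygen at the granule core (% air saturation).
#' @param ambient_o2 ambient oxygen (% air saturation).
#' @param wake_width Gaussian cross-section width of the wake (mm).
#' @param wake_length exponential decay length of the wake behind the
#'   granule (mm).
#' @param fps double-frame pair rate (pairs per second), `> 0`.
#' @param pixel_pitch image scale (mm per pixel), `> 0`.
#' @param flow_speed uniform downward ambient flow speed advecting the
#'   tracer particles (mm/s); defaults to the sinking speed.
#' @param n_tracers number of Gaussian tracer particles.
#' @param tracer_sigma tracer spot width (pixels).
#' @param tracer_amplitude tracer amplitude relative to the dye field.
#' @return An object of class `granule_scenario`.
#' @export
granule_scenario <- function(dim = c(128, 128),
                             granules = data.frame(row = 20, col = 64, r = 3),
                             sinking_speed = 10, core_o2 = 40,
                             ambient_o2 = 100, wake_width = 0.15,
                             wake_length = 1, fps = 100, pixel_pitch = 0.05,
                             flow_speed = sinking_speed, n_tracers = 200,
                             tracer_sigma = 1, tracer_amplitude = 2) {
  if (sinking_speed < 0 || flow_speed < 0) stop("speeds must be >= 0")
  if (fps <= 0) stop("'fps' must be positive")
  if (pixel_pitch <= 0) stop("'pixel_pitch' must be positive")
  structure(list(dim = as.integer(dim), granules = granules,
                 sinking_speed = sinking_speed, core_o2 = core_o2,
                 ambient_o2 = ambient_o2, wake_width = wake_width,
                 wake_length = wake_length, fps = fps,
                 pixel_pitch = pixel_pitch, flow_speed = flow_speed,
                 n_tracers = n_tracers, tracer_sigma = tracer_sigma,
                 tracer_amplitude = tracer_amplitude),
            class = "granule_scenario")
}

#' Time between the two straddled excitation pulses
#'
#' Center-to-center separation of the two pulses of a pair: the pulse length
#' plus the interframe time. This is the time base for converting PIV
#' displacements (px per pair) to velocities.
#'
#' @param timing a [timing_config()] with finite interframe time.
#' @return Pulse separation in microseconds.
#' @export
pulse_separation <- function(timing) {
  stopifnot(inherits(timing, "timing_config"))
  if (!is.finite(timing$interframe))
    stop("pulse separation requires a finite interframe time")
  timing$pulse_length + timing$interframe
}

#' Render a straddled image sequence of sinking granules
#'
#' Advances the granules by the sinking speed and the tracer particles by the
#' ambient flow between successive pairs (displacement per pair =
#' speed / fps / pixel pitch) and within each pair (displacement =
#' flow speed x pulse separation), then renders every pair through
#' [render_pair()]. Ground truth (oxygen field, intra-pair tracer
#' displacement, granule positions) is returned alongside for pipeline
#' validation.
#'
#' @param scenario a [granule_scenario()].
#' @param law sensor lifetime law.
#' @param timing a [timing_config()] with finite interframe time.
#' @param noise a [noise_model()] or `NULL`.
#' @param n_pairs number of pairs to render, `>= 1`.
#' @param seed integer seed for tracer seeding and noise.
#' @return A list of class `straddle_sequence`: `pairs` (list of
#'   [frame_pair()]), `truth` (list per pair with `o2`, `u_px`, `v_px`,
#'   `granules`), and the scenario.
#' @export
render_sequence <- function(scenario, law, timing, noise = NULL,
                            n_pairs = 1, seed = 1) {
  stopifnot(inherits(scenario, "granule_scenario"))
  if (n_pairs < 1) stop("'n_pairs' must be at least 1")
  set.seed(as.integer(seed %% .Machine$integer.max))
  dims <- scenario$dim
  px <- scenario$pixel_pitch
  # intra-pair displacement of tracers, px (downward = growing row index)
  dt_pair_s <- pulse_separation(timing) * 1e-6
  v_intra <- scenario$flow_speed * dt_pair_s / px
  if (v_intra > dims[1] / 2)
    warning("intra-pair displacement exceeds half the image; ",
            "PIV will be unreliable")
  # inter-pair advection, px
  v_inter_flow <- scenario$flow_speed / scenario$fps / px
  v_inter_sink <- scenario$sinking_speed / scenario$fps / px
  tracers <- data.frame(
    row = runif(scenario$n_tracers, 1, dims[1]),
    col = runif(scenario$n_tracers, 1, dims[2]),
    sigma = scenario$tracer_sigma,
    amplitude = scenario$tracer_amplitude)
  granules <- scenario$granules
  wrap_rows <- function(r) 1 + (r - 1) %% dims[1]
  pairs <- vector("list", n_pairs)
  truth <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    scene_o2 <- build_scene(
      "granule_wake", dim = dims, granules = granules,
      core_o2 = scenario$core_o2, ambient = scenario$ambient_o2,
      wake_width = scenario$wake_width / px,
      wake_length = scenario$wake_length / px)
    tr_b <- tracers
    tr_b$row <- wrap_rows(tr_b$row + v_intra)
    gr_b <- granules
    gr_b$row <- gr_b$row + scenario$sinking_speed * dt_pair_s / px
    scene_a <- build_scene("granule_wake", dim = dims, granules = granules,
                           core_o2 = scenario$core_o2,
                           ambient = scenario$ambient_o2,
                           wake_width = scenario$wake_width / px,
                           wake_length = scenario$wake_length / px,
                           particles = tracers)
    scene_bb <- build_scene("granule_wake", dim = dims, granules = gr_b,
                            core_o2 = scenario$core_o2,
                            ambient = scenario$ambient_o2,
                            wake_width = scenario$wake_width / px,
                            wake_length = scenario$wake_length / px,
                            particles = tr_b)
    pairs[[k]] <- render_pair(
      scene_a, law, timing, noise = noise,
      seed = if (is.null(noise)) NULL else
        sample.int(.Machine$integer.max, 1),
      scene_b = scene_bb)
    truth[[k]] <- list(o2 = scene_o2$o2, u_px = 0, v_px = v_intra,
                       granules = granules)
    tracers$row <- wrap_rows(tracers$row + v_inter_flow)
    granules$row <- granules$row + v_inter_sink
  }
  structure(list(pairs = pairs, truth = truth, scenario = scenario,
                 timing = timing),
            class = "straddle_sequence")
}
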