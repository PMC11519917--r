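#' Two-pass PIV configuration
#'
#' @param pass1 first-pass interrogation window size (pixels, power of two).
#' @param pass2 second-pass window size (pixels, power of two,
#'   `<= pass1`).
#' @param overlap window overlap fraction in `[0, 1)`.
#' @param velocity_range valid displacement magnitude range
#'   (pixels per pair) used by [validate_field()].
#' @return An object of class `piv_config`.
#' @export
piv_config <- function(pass1 = 64, pass2 = 32, overlap = 0.5,
                       velocity_range = c(0, Inf)) {
  is_pow2 <- function(n) n >= 2 && bitwAnd(as.integer(n), as.integer(n - 1)) == 0
  if (!is_pow2(pass1) || !is_pow2(pass2))
    stop("window sizes must be powers of two")
  if (pass2 > pass1) stop("'pass2' must not exceed 'pass1'")
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)")
  structure(list(pass1 = as.integer(pass1), pass2 = as.integer(pass2),
                 overlap = overlap, velocity_range = velocity_range),
            class = "piv_config")
}

#' PIV image preprocessing chain
#'
#' Contrast-limited adaptive histogram equalization (CLAHE, 32-pixel tiles)
#' to flatten the lifetime-dependent phosphorescence brightness, a 5-pixel
#' high-pass (image minus boxcar mean) to enhance particles, and a 3-pixel
#' locally adaptive (Wiener-style) low-pass to suppress noise, applied in
#' that order. The oxygen pipeline always works on the unpreprocessed
#' frames; only the cross-correlation uses this chain.
#'
#' @param img numeric matrix (2-D image).
#' @param clahe_tile CLAHE tile size (pixels).
#' @param highpass boxcar kernel size of the high-pass stage (pixels, odd).
#' @param wiener window size of the adaptive low-pass (pixels, odd).
#' @return Preprocessed image matrix (zero-mean after the high-pass stage).
#' @export
piv_preprocess <- function(img, clahe_tile = 32, highpass = 5, wiener = 3) {
  if (!is.matrix(img)) stop("'img' must be a 2-D matrix")
  if (any(dim(img) < clahe_tile))
    stop("image (", nrow(img), " x ", ncol(img),
         ") is smaller than the CLAHE tile (", clahe_tile, " px)")
  rng <- range(img)
  x <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  if (diff(rng) > 0) {
    nx <- max(1L, floor(ncol(x) / clahe_tile))
    ny <- max(1L, floor(nrow(x) / clahe_tile))
    x <- as.matrix(EBImage::clahe(x, nx = nx, ny = ny, bins = 256,
                                  limit = 2, keep.range = TRUE))
  }
  box <- function(n) matrix(1 / n^2, n, n)
  x <- x - EBImage::filter2(x, box(highpass), boundary = "replicate")
  # Wiener-style adaptive low-pass: shrink towards the local mean where the
  # local variance is close to the global noise floor
  m <- EBImage::filter2(x, box(wiener), boundary = "replicate")
  v <- EBImage::filter2(x^2, box(wiener), boundary = "replicate") - m^2
  v[v < 0] <- 0
  noise <- mean(v)
  denom <- pmax(v, noise)
  out <- m + ifelse(denom > 0, pmax(v - noise, 0) / denom, 0) * (x - m)
  matrix(out, nrow(img), ncol(img))
}

# circular FFT cross-correlation of two equal square windows; returns the
# correlation plane with displacement 0 at [1, 1]
.xcorr_plane <- function(wa, wb) {
  wa <- wa - mean(wa); wb <- wb - mean(wb)
  n <- length(wa)
  Re(fft(Conj(fft(wa)) * fft(wb), inverse = TRUE)) / n
}

# wrap a 1-based FFT index to a signed displacement in (-n/2, n/2]
.wrap_disp <- function(idx, n) {
  d <- idx - 1L
  ifelse(d > n / 2, d - n, d)
}

# 3-point Gaussian (log-parabolic) subpixel peak fit along one axis;
# parabolic fallback when a neighbor is non-positive
.subpixel <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0 && c0 >= cm && c0 >= cp) {
    den <- 2 * (log(cm) + log(cp) - 2 * log(c0))
    if (den < 0) return((log(cm) - log(cp)) / den)
  }
  den <- 2 * (cm - 2 * c0 + cp)
  if (den < 0) (cm - cp) / den else 0
}

# correlate one window pair: integer peak + subpixel offset + peak metrics
.window_disp <- function(wa, wb) {
  n <- nrow(wa)
  cc <- .xcorr_plane(wa, wb)
  pk <- arrayInd(which.max(cc), dim(cc))
  pr <- pk[1]; pc <- pk[2]
  wrap <- function(i) 1L + (i - 1L) %% n
  c0 <- cc[pr, pc]
  sub_r <- .subpixel(cc[wrap(pr - 1L), pc], c0, cc[wrap(pr + 1L), pc])
  sub_c <- .subpixel(cc[pr, wrap(pc - 1L)], c0, cc[pr, wrap(pc + 1L)])
  # peak ratio: primary over strongest peak outside the 3x3 neighborhood
  excl <- cc
  excl[wrap(pr + (-1:1)), wrap(pc + (-1:1))] <- -Inf
  second <- max(excl)
  norm <- sqrt(sum((wa - mean(wa))^2) * sum((wb - mean(wb))^2))
  list(v = .wrap_disp(pr, n) + sub_r,
       u = .wrap_disp(pc, n) + sub_c,
       peak = if (norm > 0) c0 * length(wa) / norm else 0,
       peak_ratio = if (is.finite(second) && second > 0) c0 / second else Inf)
}

# window top-left anchors for size n, step s inside extent len
.window_anchors <- function(len, n, s) {
  if (n > len) stop("interrogation window (", n, " px) larger than image (",
                    len, " px)")
  a <- seq(1L, len - n + 1L, by = s)
  if (a[length(a)] != len - n + 1L) a <- c(a, len - n + 1L)
  a
}

#' Two-pass FFT cross-correlation PIV
#'
#' Pass 1 estimates integer displacements on coarse windows (default 64 px,
#' 50% overlap); the median-filtered integer predictor then offsets the
#' second-pass interrogation windows (default 32 px) in frame B before the
#' final correlation, and a 3-point Gaussian fit per axis refines the peak
#' to subpixel precision. Window deformation is implemented as this discrete
#' window offsetting, which is sufficient for the displacement regimes of
#' straddled pairs.
#'
#' @param a,b frame A and frame B images (matrices of equal shape),
#'   typically [piv_preprocess()]ed.
#' @param config a [piv_config()].
#' @return An object of class `velocity_field`: a data frame with columns
#'   `x_px`, `y_px` (window centers; x = column, y = row), `u_px`, `v_px`
#'   (displacement of B relative to A; u = column, v = row), `peak`
#'   (normalized correlation peak), `peak_ratio`, `valid`.
#' @export
piv_displacement <- function(a, b, config = piv_config()) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)))
    stop("'a' and 'b' must be matrices of identical shape")
  stopifnot(inherits(config, "piv_config"))
  nr <- nrow(a); nc <- ncol(a)

  run_pass <- function(n, pred_fun) {
    s <- max(1L, as.integer(round(n * (1 - config$overlap))))
    ar <- .window_anchors(nr, n, s)
    ac <- .window_anchors(nc, n, s)
    grid <- expand.grid(r = ar, c = ac)
    res <- lapply(seq_len(nrow(grid)), function(i) {
      r0 <- grid$r[i]; c0 <- grid$c[i]
      pred <- pred_fun(r0 + n / 2, c0 + n / 2)
      # offset window B by the integer predictor, clamped to the image
      rb <- min(max(r0 + pred[1], 1L), nr - n + 1L)
      cb <- min(max(c0 + pred[2], 1L), nc - n + 1L)
      shift <- c(rb - r0, cb - c0)
      wa <- a[r0:(r0 + n - 1L), c0:(c0 + n - 1L)]
      wb <- b[rb:(rb + n - 1L), cb:(cb + n - 1L)]
      d <- .window_disp(wa, wb)
      c(y = r0 + n / 2, x = c0 + n / 2,
        v = shift[1] + d$v, u = shift[2] + d$u,
        peak = d$peak, peak_ratio = d$peak_ratio)
    })
    as.data.frame(do.call(rbind, res))
  }

  p1 <- run_pass(config$pass1, function(r, c) c(0L, 0L))
  p1_pred <- function(r, c) {
    d2 <- (p1$y - r)^2 + (p1$x - c)^2
    i <- which.min(d2)
    # local median over the 4 nearest pass-1 nodes, robust to outliers
    near <- order(d2)[seq_len(min(4L, nrow(p1)))]
    c(as.integer(round(median(p1$v[near]))),
      as.integer(round(median(p1$u[near]))))
  }
  p2 <- if (config$pass2 < config$pass1) run_pass(config$pass2, p1_pred)
        else p1
  out <- data.frame(x_px = p2$x, y_px = p2$y, u_px = p2$u, v_px = p2$v,
                    peak = p2$peak, peak_ratio = p2$peak_ratio,
                    valid = TRUE)
  structure(list(field = out, config = config, dim = c(nr, nc)),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  f <- x$field
  ok <- f$valid
  cat("Velocity field:", nrow(f), "vectors (", sum(!ok), "masked )\n")
  if (any(ok))
    cat(sprintf("  mean displacement u = %.3f, v = %.3f px/pair\n",
                mean(f$u_px[ok]), mean(f$v_px[ok])))
  invisible(x)
}

#' Validate a velocity field against a magnitude range
#'
#' Vectors whose displacement magnitude falls outside the configured range
#' are masked and (optionally) replaced by the median of their valid
#' neighbors on the interrogation grid.
#'
#' @param field a [piv_displacement()] result.
#' @param range displacement magnitude range `c(min, max)` in px/pair;
#'   defaults to the range stored in the field's configuration.
#' @param replace logical; replace masked vectors by the local median of
#'   valid neighbors.
#' @return The field with updated `valid`, `u_px`, `v_px`.
#' @export
validate_field <- function(field, range = NULL, replace = TRUE) {
  stopifnot(inherits(field, "velocity_field"))
  if (is.null(range)) range <- field$config$velocity_range
  if (length(range) != 2L || any(!is.finite(range[1])))
    stop("'range' must be c(min, max) with a finite minimum")
  f <- field$field
  mag <- sqrt(f$u_px^2 + f$v_px^2)
  bad <- mag < range[1] | mag > range[2]
  f$valid <- f$valid & !bad
  if (replace && any(bad) && any(f$valid)) {
    sx <- sort(unique(f$x_px)); sy <- sort(unique(f$y_px))
    step <- min(c(diff(sx), diff(sy), Inf))
    for (i in which(bad)) {
      nb <- f$valid &
        abs(f$x_px - f$x_px[i]) <= 1.5 * step &
        abs(f$y_px - f$y_px[i]) <= 1.5 * step
      if (!any(nb)) nb <- f$valid
      f$u_px[i] <- median(f$u_px[nb])
      f$v_px[i] <- median(f$v_px[nb])
    }
  }
  field$field <- f
  field
}

#' Convert PIV displacements to velocities
#'
#' @param field a [piv_displacement()] result (px/pair).
#' @param timing the acquisition [timing_config()]; the time base is the
#'   [pulse_separation()].
#' @param pixel_pitch image scale (mm per pixel).
#' @return The field's data frame with added `u_mms`, `v_mms` columns
#'   (mm/s).
#' @export
displacement_to_velocity <- function(field, timing, pixel_pitch) {
  stopifnot(inherits(field, "velocity_field"))
  dt_s <- pulse_separation(timing) * 1e-6
  f <- field$field
  f$u_mms <- f$u_px * pixel_pitch / dt_s
  f$v_mms <- f$v_px * pixel_pitch / dt_s
  f
}
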