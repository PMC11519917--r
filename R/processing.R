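# Mask reason codes shared by the processing pipeline. Codes are additive
# bit flags so a pixel can carry several reasons.
MASK_VALID     <- 0L
MASK_SATURATED <- 1L  # sensor full-scale reached in either frame
MASK_CLIPPED   <- 2L  # negative P clipped to zero (noise)
MASK_GUARD     <- 4L  # normalization denominator below the division guard
MASK_RANGE     <- 8L  # outside the calibrated range (e.g. P_N > P_N0)

#' One straddled dim/bright frame pair
#'
#' @param i0 dim-frame image: numeric matrix of non-negative integrated
#'   intensities.
#' @param i1 bright-frame image, same shape.
#' @param timing the [timing_config()] the pair was acquired with.
#' @param full_scale sensor full-scale in image units, used to flag
#'   saturated pixels and to set the default division guard; `NULL` if
#'   unknown.
#' @param saturated optional logical matrix of saturated pixels; derived
#'   from `full_scale` when omitted.
#' @param meta optional list of acquisition metadata (seed, law, ...).
#' @return An object of class `frame_pair`.
#' @export
frame_pair <- function(i0, i1, timing, full_scale = NULL, saturated = NULL,
                       meta = list()) {
  if (!is.matrix(i0) || !is.matrix(i1) || !all(dim(i0) == dim(i1)))
    stop("'i0' and 'i1' must be matrices of identical shape")
  stopifnot(inherits(timing, "timing_config"))
  if (is.null(saturated)) {
    saturated <- if (is.null(full_scale)) {
      matrix(FALSE, nrow(i0), ncol(i0))
    } else {
      i0 >= full_scale | i1 >= full_scale
    }
  }
  structure(list(i0 = i0, i1 = i1, timing = timing,
                 full_scale = full_scale, saturated = saturated, meta = meta),
            class = "frame_pair")
}

#' @export
print.frame_pair <- function(x, ...) {
  cat("Frame pair", nrow(x$i0), "x", ncol(x$i0), "px; pulse",
      x$timing$pulse_length, "us;", sum(x$saturated), "saturated px\n")
  invisible(x)
}

#' Integrated luminescence decay image P = I1 - I0
#'
#' The pixel-wise frame difference removes everything the two frames share:
#' the excitation build-up and any non-decaying background. What remains is
#' the integrated phosphorescence decay, proportional to the lifetime.
#' Negative differences (noise) are clipped to zero and flagged rather than
#' propagated into later divisions.
#'
#' @param pair a [frame_pair()].
#' @return A list of class `decay_image`: `p` (matrix) and `mask` (integer
#'   matrix of reason codes; 0 = valid).
#' @export
integrated_decay_image <- function(pair) {
  stopifnot(inherits(pair, "frame_pair"))
  p <- pair$i1 - pair$i0
  mask <- matrix(MASK_VALID, nrow(p), ncol(p))
  mask[p < 0] <- mask[p < 0] + MASK_CLIPPED
  p[p < 0] <- 0
  mask[pair$saturated] <- mask[pair$saturated] + MASK_SATURATED
  structure(list(p = p, mask = mask, timing = pair$timing),
            class = "decay_image")
}

#' Normalized integrated luminescence decay image
#'
#' Computes `P_N = (I1 - I0) / (I1 + I0)` pixel-wise. Because numerator and
#' denominator scale identically with excitation irradiance and dye density,
#' P_N is invariant to any common multiplicative factor on both frames and
#' compensates inhomogeneous illumination. Pixels whose denominator falls
#' below the division guard are masked instead of producing unstable values.
#'
#' @param pair a [frame_pair()].
#' @param guard division guard on the denominator `I0 + I1`
#'   (intensity-microsecond units). Defaults to 1% of the sensor full-scale
#'   (or, if the full scale is unknown, 1% of the largest denominator in the
#'   image).
#' @return A list of class `pn_image`: `pn` matrix, `mask` integer matrix of
#'   reason codes, and the acquisition `timing`.
#' @export
normalized_decay_image <- function(pair, guard = NULL) {
  stopifnot(inherits(pair, "frame_pair"))
  denom <- pair$i0 + pair$i1
  if (is.null(guard)) {
    guard <- if (!is.null(pair$full_scale)) 0.01 * pair$full_scale
             else 0.01 * max(denom, 0)
  }
  if (!is.numeric(guard) || length(guard) != 1L || guard <= 0)
    stop("'guard' must be a single positive number")
  di <- integrated_decay_image(pair)
  pn <- matrix(0, nrow(denom), ncol(denom))
  low <- denom < guard
  pn[!low] <- di$p[!low] / denom[!low]
  mask <- di$mask
  mask[low] <- mask[low] + MASK_GUARD
  structure(list(pn = pn, mask = mask, timing = pair$timing),
            class = "pn_image")
}

#' Stern-Volmer calibration of the normalized decay
#'
#' Holds the constants that map `P_N` to oxygen:
#' `o2 = (pn0 / P_N - 1) / ksv`. The acquisition timing is stored as a
#' fingerprint because the apparent quenching constant depends on pulse
#' length and interframe time; [o2_from_pn()] refuses to apply a calibration
#' to a pair acquired with different timing unless overridden.
#'
#' @param pn0 normalized decay at 0% air saturation, `> 0`.
#' @param ksv apparent Stern-Volmer constant (per % air sat.), `>= 0`.
#' @param r2 coefficient of determination of the fit (`NA` for a two-point
#'   calibration).
#' @param method `"two-point"` or `"least-squares"`.
#' @param timing optional [timing_config()] fingerprint.
#' @return An object of class `calibration_curve`.
#' @export
#' @examples
#' calibration_curve(pn0 = 1.58, ksv = 0.0391, r2 = 0.99,
#'                   method = "least-squares")
calibration_curve <- function(pn0, ksv, r2 = NA_real_,
                              method = c("least-squares", "two-point"),
                              timing = NULL) {
  method <- match.arg(method)
  if (!is.numeric(pn0) || length(pn0) != 1L || pn0 <= 0)
    stop("'pn0' must be a single positive number")
  if (!is.numeric(ksv) || length(ksv) != 1L || ksv < 0)
    stop("'ksv' must be a single non-negative number")
  if (!is.null(timing)) stopifnot(inherits(timing, "timing_config"))
  structure(list(pn0 = pn0, ksv = ksv, r2 = r2, method = method,
                 timing = timing),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration (%s): P_N0 = %.4g, K_SV = %.4g per %% air sat.",
              x$method, x$pn0, x$ksv))
  if (is.finite(x$r2)) cat(sprintf(", R2 = %.4f", x$r2))
  cat("\n")
  if (!is.null(x$timing))
    cat("  timing fingerprint: pulse", x$timing$pulse_length, "us, exposure",
        x$timing$exposure, "us, interframe", x$timing$interframe, "us\n")
  invisible(x)
}

#' Fit a Stern-Volmer calibration from mean P_N per oxygen level
#'
#' The two-point method solves the Stern-Volmer line exactly from the lowest
#' and highest oxygen level; the least-squares method fits
#' `P_N(0)/P_N = 1 + K_SV * o2` with the intercept fixed at 1 across all
#' levels and reports the coefficient of determination.
#'
#' @param pn numeric vector of mean normalized decay values, one per level.
#' @param o2 corresponding oxygen levels (% air saturation); at least two
#'   distinct levels, one of them near 0.
#' @param method `"least-squares"` (default) or `"two-point"`.
#' @param timing optional [timing_config()] recorded as the calibration's
#'   acquisition fingerprint.
#' @return A [calibration_curve()].
#' @export
#' @examples
#' fit_calibration(c(1.58, 0.395), c(0, 100), method = "two-point")$ksv
fit_calibration <- function(pn, o2,
                            method = c("least-squares", "two-point"),
                            timing = NULL) {
  method <- match.arg(method)
  if (length(pn) != length(o2)) stop("'pn' and 'o2' must have equal length")
  if (length(unique(o2)) < 2L)
    stop("at least two distinct oxygen levels are required")
  if (min(o2) > 5)
    warning("no calibration level near 0% air saturation; ",
            "P_N0 will be extrapolated from the lowest level")
  ord <- order(o2)
  o2 <- o2[ord]; pn <- pn[ord]
  if (any(diff(pn) > 0.02 * max(abs(pn))))
    warning("P_N is not monotonically decreasing with oxygen beyond noise ",
            "tolerance; fitting anyway")
  if (method == "two-point") {
    lo <- 1L; hi <- length(o2)
    ksv <- (pn[lo] - pn[hi]) / (pn[hi] * o2[hi] - pn[lo] * o2[lo])
    pn0 <- pn[lo] * (1 + ksv * o2[lo])
    calibration_curve(pn0, max(ksv, 0), r2 = NA_real_, method = "two-point",
                      timing = timing)
  } else {
    fit <- .fit_sv_ratio(pn, o2)
    pn0 <- fit$pn0 * (1 + fit$k * min(o2))
    calibration_curve(pn0, fit$k, r2 = fit$r2, method = "least-squares",
                      timing = timing)
  }
}

#' Invert a P_N image to an oxygen map
#'
#' Applies the pixel-wise Stern-Volmer inversion
#' `o2 = (pn0 / P_N - 1) / ksv`. Pixels already masked stay masked;
#' non-positive P_N pixels are masked; pixels with `P_N > pn0`
#' (super-unquenched, outside the calibrated range) are reported as 0% air
#' saturation with the out-of-range flag set.
#'
#' @param pn_img a `pn_image` from [normalized_decay_image()], or a bare
#'   P_N matrix (in which case no timing fingerprint check is possible).
#' @param cal a [calibration_curve()].
#' @param override logical; apply the calibration even if its timing
#'   fingerprint does not match the image's acquisition timing.
#' @return A list of class `o2_map`: `o2` matrix (% air saturation) and
#'   `mask` integer matrix of reason codes.
#' @export
o2_from_pn <- function(pn_img, cal, override = FALSE) {
  stopifnot(inherits(cal, "calibration_curve"))
  if (cal$ksv <= 0) stop("calibration has 'ksv' = 0; oxygen is undefined")
  if (inherits(pn_img, "pn_image")) {
    pn <- pn_img$pn
    mask <- pn_img$mask
    if (!is.null(cal$timing) && !is.null(pn_img$timing) &&
        !.same_timing(cal$timing, pn_img$timing)) {
      if (!override)
        stop("calibration timing fingerprint does not match the image ",
             "acquisition timing; calibrations are only valid for the ",
             "settings they were recorded with (use 'override = TRUE' to ",
             "force)")
      warning("applying a calibration with a mismatched timing fingerprint")
    }
  } else if (is.matrix(pn_img)) {
    pn <- pn_img
    mask <- matrix(MASK_VALID, nrow(pn), ncol(pn))
  } else stop("'pn_img' must be a 'pn_image' or a matrix")
  o2 <- matrix(0, nrow(pn), ncol(pn))
  bad <- mask != MASK_VALID
  nonpos <- !bad & pn <= 0
  mask[nonpos] <- mask[nonpos] + MASK_RANGE
  over <- !bad & !nonpos & pn > cal$pn0
  mask[over] <- mask[over] + MASK_RANGE   # reported as 0 with flag
  ok <- !bad & !nonpos & !over
  o2[ok] <- (cal$pn0 / pn[ok] - 1) / cal$ksv
  structure(list(o2 = o2, mask = mask), class = "o2_map")
}

#' @export
print.o2_map <- function(x, ...) {
  ok <- x$mask == 0L
  cat("O2 map", nrow(x$o2), "x", ncol(x$o2), "px;",
      sum(!ok), "masked px\n")
  if (any(ok))
    cat(sprintf("  valid range %.2f - %.2f %% air sat.\n",
                min(x$o2[ok]), max(x$o2[ok])))
  invisible(x)
}

# shift a matrix by (dr, dc) with edge replication
.shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  c <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[r, c, drop = FALSE]
}

# 3x3 spatial median with edge replication
.median3x3 <- function(m) {
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  stack <- vapply(seq_len(nrow(shifts)),
                  function(i) .shift_replicate(m, shifts$dr[i], shifts$dc[i]),
                  m)
  dim(stack) <- c(length(m), 9L)
  matrix(apply(stack, 1L, median), nrow(m), ncol(m))
}

#' Temporal and spatial smoothing of an image series
#'
#' Applies a centered pixel-wise 3-point moving average through the time
#' series (the first and last frame use their available neighbors) followed
#' by a per-frame 3 x 3 spatial median filter with edge replication. With
#' fewer than 3 frames the temporal step is skipped with a warning. An
#' optional invalid-pixel mask is propagated by majority: a smoothed pixel is
#' invalid when more than half of the samples entering its spatial kernel
#' were invalid.
#'
#' @param stack 3-D array (rows x cols x frames) or a list of matrices.
#' @param mask optional logical array/list of the same shape, `TRUE` for
#'   invalid pixels.
#' @return A list with `stack` (3-D array) and `mask` (logical array or
#'   `NULL`).
#' @export
smooth_series <- function(stack, mask = NULL) {
  if (is.list(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) == 2L) dim(stack) <- c(dim(stack), 1L)
  if (length(dim(stack)) != 3L) stop("'stack' must be rows x cols x frames")
  if (is.list(mask)) mask <- simplify2array(mask)
  if (!is.null(mask)) {
    if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
    if (!all(dim(mask) == dim(stack)))
      stop("'mask' must have the same shape as 'stack'")
  }
  nt <- dim(stack)[3]
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  as_frame <- function(a, k) matrix(a[, , k], nr, nc)
  tmean <- function(a) {
    if (nt < 3L) return(a)
    out <- a
    for (k in seq_len(nt)) {
      idx <- max(1L, k - 1L):min(nt, k + 1L)
      out[, , k] <- apply(a[, , idx, drop = FALSE], c(1, 2), mean)
    }
    out
  }
  if (nt < 3L)
    warning("fewer than 3 frames: temporal moving average skipped")
  sm <- tmean(stack)
  for (k in seq_len(nt)) sm[, , k] <- .median3x3(as_frame(sm, k))
  out_mask <- NULL
  if (!is.null(mask)) {
    frac <- tmean(mask * 1)
    for (k in seq_len(nt)) {
      bf <- as_frame(frac, k)
      box <- (.shift_replicate(bf, -1, -1) + .shift_replicate(bf, -1, 0) +
              .shift_replicate(bf, -1, 1) + .shift_replicate(bf, 0, -1) + bf +
              .shift_replicate(bf, 0, 1) + .shift_replicate(bf, 1, -1) +
              .shift_replicate(bf, 1, 0) + .shift_replicate(bf, 1, 1)) / 9
      frac[, , k] <- box
    }
    out_mask <- frac > 0.5
  }
  list(stack = sm, mask = out_mask)
}

#' Rapid lifetime determination from two gated images
#'
#' Two intensity images gated at delays `t1` and `t2` after the excitation
#' pulse sample a monoexponential decay at two points; the lifetime follows
#' as `tau = (t1 - t2) / log(F2 / F1)`. Pixels where the ratio is
#' non-positive, equal to 1 (infinite lifetime) or yields a non-positive
#' lifetime are masked.
#'
#' @param f1 gate-1 image (matrix), recorded at delay `t1`.
#' @param f2 gate-2 image, same shape, recorded at delay `t2`.
#' @param t1,t2 gate delays after excitation (microseconds), `t1 != t2`.
#' @return A list of class `lifetime_image`: `tau` matrix (microseconds) and
#'   logical `mask` (`TRUE` = invalid).
#' @export
#' @examples
#' f1 <- matrix(exp(-41 / 62), 2, 2)
#' f2 <- matrix(exp(-47 / 62), 2, 2)
#' rld_lifetime(f1, f2, t1 = 41, t2 = 47)$tau  # recovers 62 us
rld_lifetime <- function(f1, f2, t1, t2) {
  if (!is.matrix(f1) || !is.matrix(f2) || !all(dim(f1) == dim(f2)))
    stop("'f1' and 'f2' must be matrices of identical shape")
  if (t1 == t2) stop("gate separation 't1' - 't2' must be non-zero")
  tau <- matrix(NA_real_, nrow(f1), ncol(f1))
  ratio <- f2 / f1
  ok <- is.finite(ratio) & f1 > 0 & f2 > 0 & ratio != 1
  tau[ok] <- (t1 - t2) / log(ratio[ok])
  ok <- ok & is.finite(tau) & tau > 0
  tau[!ok] <- NA_real_
  structure(list(tau = tau, mask = !ok), class = "lifetime_image")
}
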