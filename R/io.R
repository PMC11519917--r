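#' Write a TIFF image stack with a JSON sidecar
#'
#' Integer stacks (`uint8`, `uint16`) are written losslessly as multi-page
#' TIFF; floating-point images (`float32`) are stored in the 32-bit TIFF
#' container as fixed-point values with an offset and scale recorded in the
#' sidecar (round-trip accurate to about `range / 2^32`). The sidecar (a
#' JSON file at `<path>.json`) carries the storage format, offset/scale, and
#' any user metadata (timing, seed, sensor law) so every artifact can be
#' re-interpreted without guessing.
#'
#' @param stack a matrix, a list of matrices, or a rows x cols x frames
#'   array.
#' @param path output TIFF path.
#' @param format `"uint16"`, `"uint8"` or `"float32"`.
#' @param meta named list of metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path,
                              format = c("uint16", "uint8", "float32"),
                              meta = list()) {
  format <- match.arg(format)
  if (is.matrix(stack)) stack <- list(stack)
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  stopifnot(is.list(stack), all(vapply(stack, is.matrix, TRUE)))
  sidecar <- list(format = format, n_frames = length(stack),
                  dim = dim(stack[[1]]))
  if (format %in% c("uint8", "uint16")) {
    bits <- if (format == "uint8") 8L else 16L
    maxv <- 2^bits - 1
    rng <- range(unlist(lapply(stack, range)))
    if (rng[1] < 0 || rng[2] > maxv)
      stop("values outside [0, ", maxv, "] cannot be stored as ", format)
    tiff::writeTIFF(lapply(stack, function(m) round(m) / maxv), path,
                    bits.per.sample = bits, compression = "none")
  } else {
    lo <- min(unlist(lapply(stack, min)))
    hi <- max(unlist(lapply(stack, max)))
    scale <- if (hi > lo) hi - lo else 1
    sidecar$offset <- lo
    sidecar$scale <- scale
    tiff::writeTIFF(lapply(stack, function(m) (m - lo) / scale), path,
                    bits.per.sample = 32, compression = "none")
  }
  sidecar$meta <- meta
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a TIFF image stack and its JSON sidecar
#'
#' @param path TIFF path written by [write_image_stack()] (or any
#'   single-/multi-page grayscale TIFF; without a sidecar, defaults are
#'   assumed with a warning).
#' @return A list with `stack` (list of numeric matrices in the original
#'   units), `format`, and `meta`.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  side_path <- paste0(path, ".json")
  sidecar <- if (file.exists(side_path)) {
    jsonlite::read_json(side_path, simplifyVector = TRUE)
  } else {
    warning("no sidecar metadata at ", side_path, "; assuming raw values")
    NULL
  }
  fmt <- if (!is.null(sidecar)) sidecar$format else "unknown"
  pages <- tiff::readTIFF(path, all = TRUE, as.is = fmt != "float32",
                          info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse accidental channels
    storage.mode(p) <- "double"
    p
  })
  if (identical(fmt, "float32")) {
    pages <- lapply(pages, function(p) p * sidecar$scale + sidecar$offset)
  }
  list(stack = pages, format = fmt,
       meta = if (!is.null(sidecar)) sidecar$meta else list())
}

#' Write a straddled frame pair as a two-page TIFF
#'
#' The dim frame is page 1 and the bright frame page 2; acquisition timing
#' and metadata go to the sidecar.
#'
#' @param pair a [frame_pair()].
#' @param path output TIFF path.
#' @param format storage format, see [write_image_stack()].
#' @return `path`, invisibly.
#' @export
write_frame_pair <- function(pair, path, format = "float32") {
  stopifnot(inherits(pair, "frame_pair"))
  meta <- c(list(timing = unclass(pair$timing),
                 full_scale = pair$full_scale),
            .serializable_meta(pair$meta))
  write_image_stack(list(pair$i0, pair$i1), path, format = format,
                    meta = meta)
}

.serializable_meta <- function(meta) {
  lapply(meta, function(x) if (is.list(x)) unclass(x) else x)
}

#' Read a straddled frame pair written by [write_frame_pair()]
#'
#' @param path TIFF path.
#' @return A [frame_pair()].
#' @export
read_frame_pair <- function(path) {
  r <- read_image_stack(path)
  if (length(r$stack) != 2L)
    stop("a frame pair must have exactly 2 pages, found ", length(r$stack))
  tm <- r$meta$timing
  if (is.null(tm)) stop("sidecar lacks the acquisition timing")
  timing <- timing_config(tm$pulse_length,
                          exposure = if (is.null(tm$exposure)) Inf
                                     else tm$exposure,
                          interframe = if (is.null(tm$interframe)) Inf
                                       else tm$interframe,
                          carry_over = isTRUE(tm$carry_over),
                          frame1_decay_overlap =
                            if (is.null(tm$frame1_decay_overlap)) 0
                            else tm$frame1_decay_overlap)
  frame_pair(r$stack[[1]], r$stack[[2]], timing,
             full_scale = r$meta$full_scale, meta = r$meta)
}

#' Write an oxygen map as float TIFF plus 8-bit mask TIFF
#'
#' @param map an `o2_map` from [o2_from_pn()].
#' @param path output TIFF path for the oxygen image; the mask goes to
#'   `<path base>_mask.tif`.
#' @param meta extra sidecar metadata.
#' @return `path`, invisibly.
#' @export
write_o2_map <- function(map, path, meta = list()) {
  stopifnot(inherits(map, "o2_map"))
  write_image_stack(map$o2, path, format = "float32",
                    meta = c(list(content = "o2_percent_airsat"), meta))
  mask_path <- paste0(sub("\\.tiff?$", "", path), "_mask.tif")
  write_image_stack(map$mask + 0, mask_path, format = "uint8",
                    meta = list(content = "mask_reason_codes"))
  invisible(path)
}

#' Save / load a calibration curve as JSON
#'
#' @param cal a [calibration_curve()].
#' @param path JSON path.
#' @return `path` (write) or a [calibration_curve()] (read).
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_curve"))
  out <- unclass(cal)
  if (!is.null(out$timing)) out$timing <- unclass(out$timing)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  timing <- NULL
  if (!is.null(x$timing)) {
    tm <- x$timing
    inf_or <- function(v) if (is.null(v) || is.na(v)) Inf else v
    timing <- timing_config(tm$pulse_length, exposure = inf_or(tm$exposure),
                            interframe = inf_or(tm$interframe),
                            carry_over = isTRUE(tm$carry_over))
  }
  calibration_curve(x$pn0, x$ksv,
                    r2 = if (is.null(x$r2) || is.na(x$r2)) NA_real_ else x$r2,
                    method = x$method, timing = timing)
}

#' Export a timing scan as CSV
#'
#' Columns: `pulse_length_us`, `ksv_apparent`, `snr`.
#'
#' @param scan a [timing_scan()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_timing_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "timing_scan_result"))
  write.csv(scan$table, path, row.names = FALSE)
  invisible(path)
}

#' Export a velocity field as CSV
#'
#' Columns: `x_px`, `y_px`, `u_px`, `v_px`, `peak`, `valid`.
#'
#' @param field a [piv_displacement()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_velocity_csv <- function(field, path) {
  stopifnot(inherits(field, "velocity_field"))
  f <- field$field[, c("x_px", "y_px", "u_px", "v_px", "peak", "valid")]
  write.csv(f, path, row.names = FALSE)
  invisible(path)
}
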