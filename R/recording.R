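#' Construct a high-speed videoendoscopy recording
#'
#' A recording is a stack of 8-bit colour frames together with its acquisition
#' metadata. Frames are held as an integer array with dimensions
#' `H x W x 3 x T` (rows, columns, RGB channels, time).
#'
#' @param frames Integer or numeric array `H x W x 3 x T` with values in
#'   `[0, 255]`. A single `H x W x 3` frame is promoted to `T = 1`.
#' @param fps Frame rate in frames per second. High-speed laryngeal imaging
#'   conventionally runs at 4,000 fps so that every glottal cycle is resolved.
#' @param date Acquisition date (`Date` or coercible).
#' @param mode Storage mode the frames came from: `"raw"` (never compressed),
#'   `"lossy"` or `"lossless"`.
#' @param quality_tier Ordinal quality rating: 0 (insufficient), 1 (okay),
#'   2 (excellent).
#'
#' @return An object of class `gk_recording`.
#' @export
recording <- function(frames, fps = 4000, date = Sys.Date(),
                      mode = c("raw", "lossy", "lossless"),
                      quality_tier = 2L) {
  mode <- match.arg(mode)
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 4L || dim(frames)[3] != 3L) {
    stop("`frames` must be an H x W x 3 x T array", call. = FALSE)
  }
  if (dim(frames)[4] < 1L) stop("a recording needs at least one frame", call. = FALSE)
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("frame intensities must lie in [0, 255]", call. = FALSE)
  }
  if (!quality_tier %in% 0:2) {
    stop("`quality_tier` must be 0, 1 or 2", call. = FALSE)
  }
  storage.mode(frames) <- "integer"
  structure(
    list(frames = frames, fps = fps, date = as.Date(date), mode = mode,
         quality_tier = as.integer(quality_tier)),
    class = "gk_recording"
  )
}

#' @export
print.gk_recording <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<gk_recording> %d frames, %dx%d px, %g fps, %s, tier %d, %s\n",
    d[4], d[1], d[2], x$fps, x$mode, x$quality_tier, format(x$date)))
  invisible(x)
}

#' Number of frames in a recording or mask sequence
#' @param x A `gk_recording`, `gk_masks` or `gk_phantom`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  if (inherits(x, "gk_recording")) return(dim(x$frames)[4])
  if (inherits(x, "gk_masks")) return(dim(x$masks)[3])
  if (inherits(x, "gk_phantom")) return(dim(x$rec$frames)[4])
  stop("unsupported object", call. = FALSE)
}

#' Construct a per-frame glottis mask sequence
#'
#' Masks store the segmenter's sigmoid output rescaled to 8 bit: 0 is
#' background, 255 is glottis. Binarisation happens at `threshold` on the
#' unit (sigmoid) scale.
#'
#' @param masks Array `H x W x T` with values in `[0, 255]` (a single matrix
#'   is promoted to `T = 1`).
#' @param threshold Binarisation cut on the unit scale, in (0, 1).
#' @return An object of class `gk_masks`.
#' @export
mask_sequence <- function(masks, threshold = 0.5) {
  if (is.matrix(masks)) dim(masks) <- c(dim(masks), 1L)
  if (length(dim(masks)) != 3L) {
    stop("`masks` must be an H x W x T array", call. = FALSE)
  }
  rng <- range(masks)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("mask values must lie in [0, 255]", call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  }
  storage.mode(masks) <- "integer"
  structure(list(masks = masks, threshold = threshold), class = "gk_masks")
}

#' @export
print.gk_masks <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("<gk_masks> %d frames, %dx%d px, threshold %.2f\n",
              d[3], d[1], d[2], x$threshold))
  invisible(x)
}

#' Binarise a mask sequence
#'
#' @param masks A `gk_masks` object, or an array on the 0--255 scale.
#' @param threshold Cut on the unit scale; defaults to the threshold stored in
#'   the object (0.5 otherwise). Binarisation is idempotent: applying it to an
#'   already binary 0/255 stack reproduces the same result.
#' @return Logical array of the same shape (`TRUE` = glottis).
#' @export
binarize_masks <- function(masks, threshold = NULL) {
  if (inherits(masks, "gk_masks")) {
    threshold <- threshold %||% masks$threshold
    masks <- masks$masks
  }
  threshold <- threshold %||% 0.5
  masks / 255 > threshold
}

#' Construct a glottal area waveform
#'
#' The GAW is the per-frame glottal area in squared pixels, the central
#' clinical signal derived from glottis segmentation.
#'
#' @param areas Numeric vector of non-negative per-frame areas.
#' @return A tibble of class `gk_gaw` with columns `frame` and `area_px2`.
#' @export
gaw <- function(areas) {
  if (any(areas < 0)) stop("GAW areas must be non-negative", call. = FALSE)
  out <- tibble::tibble(frame = seq_along(areas), area_px2 = as.numeric(areas))
  class(out) <- c("gk_gaw", class(out))
  out
}

gaw_areas <- function(x) {
  if (inherits(x, "gk_gaw") || is.data.frame(x)) return(x$area_px2)
  as.numeric(x)
}

#' Construct a rectangular region of interest
#'
#' ROIs use 0-based, half-open pixel coordinates: the box covers pixel columns
#' `x0 ... x0 + width - 1` and rows `y0 ... y0 + height - 1`, with x running
#' rightward and y downward.
#'
#' @param x0,y0 Top-left corner (0-based pixels, non-negative).
#' @param width,height Extent in pixels (positive).
#' @return An object of class `gk_roi`.
#' @export
roi_box <- function(x0, y0, width, height) {
  vals <- c(x0 = x0, y0 = y0, width = width, height = height)
  if (any(vals != round(vals))) stop("ROI coordinates must be integers", call. = FALSE)
  if (x0 < 0 || y0 < 0) stop("ROI corner must be non-negative", call. = FALSE)
  if (width <= 0 || height <= 0) {
    stop("ROI width and height must be positive", call. = FALSE)
  }
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "gk_roi")
}

#' @export
print.gk_roi <- function(x, ...) {
  cat(sprintf("<gk_roi> x0=%d y0=%d %dx%d\n", x$x0, x$y0, x$width, x$height))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
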