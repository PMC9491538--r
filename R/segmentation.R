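#' Extract the luminance channel of a colour frame
#'
#' Glottis segmentation operates on grayscale input; colour carries no
#' essential information for the task. Uses the Rec.601 luma weighting
#' `Y = 0.299 R + 0.587 G + 0.114 B`, rounded back to the 8-bit grid.
#'
#' @param frame `H x W x 3` array (8-bit intensities), or an `H x W x 3 x T`
#'   stack (returns `H x W x T`).
#' @return Numeric matrix (or array) of luminance values in `[0, 255]`.
#' @export
to_luminance <- function(frame) {
  d <- dim(frame)
  if (length(d) == 4L && d[3] == 3L) {
    out <- array(0, d[c(1, 2, 4)])
    for (t in seq_len(d[4])) out[, , t] <- to_luminance(frame[, , , t])
    return(out)
  }
  if (length(d) != 3L || d[3] != 3L) {
    stop("dimension error: expected an H x W x 3 colour frame", call. = FALSE)
  }
  round(0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3])
}

#' Normalise 8-bit intensities onto the symmetric unit scale
#'
#' The segmenter's input convention: `x -> x / 127.5 - 1`, so 0 maps to -1
#' and 255 to +1.
#'
#' @param img Numeric matrix or array on the 0--255 scale.
#' @return The same shape on the `[-1, 1]` scale.
#' @export
normalize_intensity <- function(img) {
  img / 127.5 - 1
}

#' Adjust an ROI to 32-divisible dimensions
#'
#' Encoder-decoder segmentation networks downsample by powers of two, so the
#' crop fed to them must have width and height divisible by 32. The result is
#' the smallest ROI containing the request whose dimensions are multiples of
#' 32: each side is grown symmetrically to the next multiple, then shifted
#' inward (never shrunk) to stay inside the frame.
#'
#' @param roi A [roi_box()] intersecting the frame.
#' @param frame_shape Frame size as `c(height, width)` in pixels.
#' @return An adjusted `gk_roi` containing the input ROI.
#' @export
adjust_roi <- function(roi, frame_shape) {
  stopifnot(inherits(roi, "gk_roi"))
  H <- frame_shape[1]; W <- frame_shape[2]
  if (roi$x0 >= W || roi$y0 >= H) {
    stop("geometry error: ROI lies outside the frame", call. = FALSE)
  }
  fit_axis <- function(p0, len, limit) {
    len2 <- max(32L, as.integer(ceiling(len / 32) * 32))
    if (len2 > limit) {
      stop("geometry error: frame too small for a 32-divisible ROI",
           call. = FALSE)
    }
    p <- p0 - (len2 - len) %/% 2
    p <- max(0L, min(p, limit - len2))
    c(p, len2)
  }
  x <- fit_axis(roi$x0, roi$width, W)
  y <- fit_axis(roi$y0, roi$height, H)
  roi_box(x[1], y[1], x[2], y[2])
}

crop_roi <- function(mat_or_arr, roi) {
  rows <- (roi$y0 + 1):(roi$y0 + roi$height)
  cols <- (roi$x0 + 1):(roi$x0 + roi$width)
  if (is.matrix(mat_or_arr)) return(mat_or_arr[rows, cols, drop = FALSE])
  mat_or_arr[rows, cols, , drop = FALSE]
}
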