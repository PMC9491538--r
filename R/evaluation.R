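as_binary_pair <- function(truth, pred) {
  if (inherits(truth, "gk_masks")) truth <- binarize_masks(truth)
  if (inherits(pred, "gk_masks")) pred <- binarize_masks(pred)
  truth <- truth > 0.5; pred <- pred > 0.5
  if (!identical(dim(truth), dim(pred))) {
    stop("dimension error: masks must have identical shape", call. = FALSE)
  }
  list(G = truth, P = pred)
}

#' Segmentation overlap metrics for binary mask pairs
#'
#' * `iou()` -- Intersection over Union (Jaccard), `|G n P| / |G u P|`.
#' * `dice_score()` -- Dice coefficient `2 |G n P| / (|G| + |P|)`,
#'   algebraically `2 IoU / (1 + IoU)`.
#' * `pixel_accuracy()` -- fraction of correctly labelled pixels.
#'
#' When both masks are empty all three are defined as 1 (perfect agreement
#' on absence); closed-glottis frames make this case routine. Set
#' `empty_value = NA` to mark such frames undefined instead.
#'
#' @param truth,pred Binary masks (logical/0-1 matrices or arrays of equal
#'   shape, or [mask_sequence()] objects, binarised at their threshold).
#' @param empty_value Value returned when both masks are empty.
#' @return A score in `[0, 1]` (or `empty_value`).
#' @export
iou <- function(truth, pred, empty_value = 1) {
  pr <- as_binary_pair(truth, pred)
  u <- sum(pr$G | pr$P)
  if (u == 0) return(empty_value)
  sum(pr$G & pr$P) / u
}

#' @rdname iou
#' @export
dice_score <- function(truth, pred, empty_value = 1) {
  pr <- as_binary_pair(truth, pred)
  denom <- sum(pr$G) + sum(pr$P)
  if (denom == 0) return(empty_value)
  2 * sum(pr$G & pr$P) / denom
}

#' @rdname iou
#' @export
pixel_accuracy <- function(truth, pred) {
  pr <- as_binary_pair(truth, pred)
  mean(pr$G == pr$P)
}

# pixels of M within `band` (Chebyshev distance) of the mask contour,
# computed as M intersected with the dilated complement
boundary_band <- function(M, band) {
  if (!any(M)) return(M)
  if (all(M)) return(M & FALSE)  # no complement, hence no contour band
  brush <- EBImage::makeBrush(2 * band + 1, shape = "box")
  dil <- EBImage::dilate(EBImage::Image(!M), brush) > 0.5
  M & dil
}

#' Boundary IoU between two binary masks
#'
#' IoU restricted to thin bands around each mask's contour: every mask is
#' replaced by its intersection with the dilated complement (a band of
#' `band_px` pixels, Chebyshev metric, inside the contour), and Eq-style IoU
#' is computed between the two bands. Sensitive to boundary errors that
#' plain IoU averages away; as `band_px` grows beyond the image diagonal it
#' reduces to plain IoU.
#'
#' @inheritParams iou
#' @param band_px Band radius in pixels (>= 1). The default of 2 px suits
#'   128 px frames; scale with the image diagonal for larger imagery.
#' @return A score in `[0, 1]`.
#' @export
boundary_iou <- function(truth, pred, band_px = 2, empty_value = 1) {
  if (band_px < 1) stop("`band_px` must be >= 1", call. = FALSE)
  pr <- as_binary_pair(truth, pred)
  gb <- boundary_band(pr$G, band_px)
  pb <- boundary_band(pr$P, band_px)
  u <- sum(gb | pb)
  if (u == 0) return(empty_value)
  sum(gb & pb) / u
}

#' Detect segmentation artifacts in a mask sequence
#'
#' Automates the two artifact classes seen in clinical review of glottis
#' segmentations: (1) *spurious* masks -- a frame containing a connected
#' component of at least `min_component_px` pixels lying entirely outside
#' the prior region where the glottis can legitimately appear; and
#' (2) *empty-while-open* masks -- an empty frame whose temporal neighbours
#' within `neighbor_k` frames on both sides are non-empty, indicating the
#' glottis was visible but missed. A whole video is flagged when the
#' fraction of artifact frames exceeds `video_flag_frac`.
#'
#' @param masks A [mask_sequence()].
#' @param prior A [roi_box()] delimiting where the glottis may appear.
#' @param min_component_px Minimum component size counted as spurious.
#' @param neighbor_k Temporal half-window for the empty-while-open rule;
#'   0 disables the rule (appropriate when the frames are not consecutive).
#' @param video_flag_frac Artifact-frame fraction above which `video_flag`
#'   is set.
#' @return An object of class `gk_artifacts`: a list with `empty_frames`,
#'   `spurious_frames`, `artifact_count`, `n_frames` and `video_flag`.
#' @export
detect_artifacts <- function(masks, prior, min_component_px = 20,
                             neighbor_k = 2, video_flag_frac = 0.1) {
  stopifnot(inherits(masks, "gk_masks"), inherits(prior, "gk_roi"))
  bin <- binarize_masks(masks)
  T <- dim(bin)[3]
  inside <- matrix(FALSE, dim(bin)[1], dim(bin)[2])
  rows <- (prior$y0 + 1):min(prior$y0 + prior$height, nrow(inside))
  cols <- (prior$x0 + 1):min(prior$x0 + prior$width, ncol(inside))
  inside[rows, cols] <- TRUE

  nonempty <- apply(bin, 3, any)
  spurious <- logical(T)
  for (t in seq_len(T)) {
    if (!nonempty[t]) next
    lab <- EBImage::bwlabel(bin[, , t])
    if (max(lab) == 0) next
    sizes <- tabulate(lab[lab > 0])
    overlap <- tabulate(lab[lab > 0 & inside], nbins = length(sizes))
    if (any(sizes >= min_component_px & overlap == 0)) spurious[t] <- TRUE
  }

  empty <- logical(T)
  if (neighbor_k > 0) {
    for (t in seq_len(T)) {
      if (nonempty[t]) next
      before <- nonempty[max(1, t - neighbor_k):max(1, t - 1)]
      after <- nonempty[min(T, t + 1):min(T, t + neighbor_k)]
      if (t > 1 && t < T && any(before) && any(after)) empty[t] <- TRUE
    }
  }

  count <- sum(spurious | empty)
  structure(
    list(empty_frames = which(empty), spurious_frames = which(spurious),
         artifact_count = count, n_frames = T,
         video_flag = count / T > video_flag_frac),
    class = "gk_artifacts"
  )
}

#' @export
print.gk_artifacts <- function(x, ...) {
  cat(sprintf("<gk_artifacts> %d/%d artifact frames (%d spurious, %d empty)%s\n",
              x$artifact_count, x$n_frames, length(x$spurious_frames),
              length(x$empty_frames), if (x$video_flag) " [video flagged]" else ""))
  invisible(x)
}

#' Agreement between two glottal area waveforms
#'
#' @param a,b `gk_gaw` tibbles (or numeric area vectors) of equal length.
#' @return A one-row tibble with `pearson_r` (NA with a message when either
#'   waveform is constant), `max_abs_deviation` and `rmse`.
#' @export
gaw_agreement <- function(a, b) {
  x <- gaw_areas(a); y <- gaw_areas(b)
  if (length(x) != length(y)) {
    stop("length mismatch between waveforms", call. = FALSE)
  }
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::inform("correlation undefined for constant waveform; reporting NA")
    NA_real_
  } else {
    stats::cor(x, y)
  }
  tibble::tibble(pearson_r = r,
                 max_abs_deviation = max(abs(x - y)),
                 rmse = sqrt(mean((x - y)^2)))
}

#' Evaluate predicted masks against ground truth
#'
#' Computes the full per-frame metric bundle (IoU, boundary IoU, Dice, pixel
#' accuracy), artifact flags, and GAW agreement between the two mask
#' sequences.
#'
#' @param pred,truth [mask_sequence()] objects of identical geometry.
#' @param prior [roi_box()] prior region for artifact detection; `NULL`
#'   skips artifact flags.
#' @param band_px Boundary-IoU band radius.
#' @param ... Passed to [detect_artifacts()].
#' @return An object of class `gk_eval` with fields `frames` (per-frame
#'   tibble), `artifacts` (`gk_artifacts` or `NULL`) and `gaw` (agreement
#'   tibble). Use [generics::tidy()] / [generics::glance()] for tidy access.
#' @export
evaluate_segmentation <- function(pred, truth, prior = NULL, band_px = 2, ...) {
  stopifnot(inherits(pred, "gk_masks"), inherits(truth, "gk_masks"))
  gb <- binarize_masks(truth); pb <- binarize_masks(pred)
  if (!identical(dim(gb), dim(pb))) {
    stop("dimension error: mask sequences must have identical shape", call. = FALSE)
  }
  T <- dim(gb)[3]
  frames <- tibble::tibble(
    frame = seq_len(T),
    iou = vapply(seq_len(T), function(t) iou(gb[, , t], pb[, , t]), numeric(1)),
    boundary_iou = vapply(seq_len(T), function(t)
      boundary_iou(gb[, , t], pb[, , t], band_px), numeric(1)),
    dice = vapply(seq_len(T), function(t) dice_score(gb[, , t], pb[, , t]),
                  numeric(1)),
    pixel_acc = vapply(seq_len(T), function(t)
      pixel_accuracy(gb[, , t], pb[, , t]), numeric(1))
  )
  art <- NULL
  if (!is.null(prior)) {
    art <- detect_artifacts(pred, prior, ...)
    frames$spurious_flag <- frames$frame %in% art$spurious_frames
    frames$empty_flag <- frames$frame %in% art$empty_frames
  }
  ga <- suppressMessages(gaw_agreement(compute_gaw(truth), compute_gaw(pred)))
  structure(list(frames = frames, artifacts = art, gaw = ga),
            class = "gk_eval")
}

#' @export
print.gk_eval <- function(x, ...) {
  cat(sprintf("<gk_eval> %d frames, median IoU %.3f, median Dice %.3f\n",
              nrow(x$frames), stats::median(x$frames$iou),
              stats::median(x$frames$dice)))
  if (!is.null(x$artifacts)) print(x$artifacts)
  invisible(x)
}
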