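#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-frame metrics of a segmentation evaluation
#'
#' @param x A `gk_eval` from [evaluate_segmentation()].
#' @param ... Unused.
#' @return The per-frame metric tibble.
#' @method tidy gk_eval
#' @export
tidy.gk_eval <- function(x, ...) x$frames

#' One-row summary of a segmentation evaluation
#'
#' Frames are aggregated by the median (scores) and by counts (artifacts).
#'
#' @param x A `gk_eval`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance gk_eval
#' @export
glance.gk_eval <- function(x, ...) {
  tibble::tibble(
    n_frames = nrow(x$frames),
    median_iou = stats::median(x$frames$iou),
    median_boundary_iou = stats::median(x$frames$boundary_iou),
    median_dice = stats::median(x$frames$dice),
    median_pixel_acc = stats::median(x$frames$pixel_acc),
    artifact_frames = if (is.null(x$artifacts)) NA_integer_ else
      x$artifacts$artifact_count,
    gaw_pearson_r = x$gaw$pearson_r
  )
}

#' Tidy per-step metrics of a continual-learning run
#'
#' @param x A `gk_continual` from [run_experiment()].
#' @param ... Unused.
#' @return The per-step metric tibble (step 0 is the baseline model).
#' @method tidy gk_continual
#' @export
tidy.gk_continual <- function(x, ...) x$steps

#' One-row summary of a continual-learning run
#'
#' @param x A `gk_continual`.
#' @param ... Unused.
#' @return A one-row tibble with baseline and final metrics and the artifact
#'   change after the first step.
#' @method glance gk_continual
#' @export
glance.gk_continual <- function(x, ...) {
  s <- x$steps
  tibble::tibble(
    n_steps = max(s$step),
    baseline_iou = s$mean_iou[s$step == 0],
    final_iou = s$mean_iou[which.max(s$step)],
    baseline_artifacts = s$artifact_frames[s$step == 0],
    after_first_step_artifacts = if (any(s$step == 1))
      s$artifact_frames[s$step == 1] else NA_real_,
    final_artifacts = s$artifact_frames[which.max(s$step)]
  )
}

#' Tidy a mask-derived glottal area waveform
#'
#' @param x A `gk_gaw` tibble (already tidy; returned unchanged).
#' @param ... Unused.
#' @return The `frame` / `area_px2` tibble.
#' @method tidy gk_gaw
#' @export
tidy.gk_gaw <- function(x, ...) x
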