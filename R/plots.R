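#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a glottal area waveform
#'
#' @param object A `gk_gaw` tibble.
#' @param ... Unused.
#' @return A ggplot: area in squared pixels across frames.
#' @method autoplot gk_gaw
#' @export
autoplot.gk_gaw <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$area_px2)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "frame", y = expression("glottal area" ~ (px^2)),
                  title = "Glottal area waveform") +
    ggplot2::theme_minimal()
}

#' Plot per-frame segmentation scores
#'
#' @param object A `gk_eval` from [evaluate_segmentation()].
#' @param ... Unused.
#' @return A ggplot of IoU, boundary IoU, Dice and pixel accuracy per frame.
#' @method autoplot gk_eval
#' @export
autoplot.gk_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$frames,
    cols = c("iou", "boundary_iou", "dice", "pixel_acc"),
    names_to = "metric", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$score,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "frame", y = "score",
                  title = "Per-frame segmentation metrics") +
    ggplot2::theme_minimal()
}

#' Plot a continual-learning trajectory
#'
#' @param object A `gk_continual` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot with mean IoU and artifact frames per continual step.
#' @method autoplot gk_continual
#' @export
autoplot.gk_continual <- function(object, ...) {
  s <- object$steps
  long <- tidyr::pivot_longer(
    s[, c("step", "mean_iou", "artifact_frames")],
    cols = c("mean_iou", "artifact_frames"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "continual step", y = NULL,
                  title = "Continual-learning trajectory") +
    ggplot2::theme_minimal()
}
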