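unet_plan <- function(depth, base, in_ch = 1L) {
  plan <- list()
  for (i in seq_len(depth)) {
    cin <- if (i == 1) in_ch else base * 2^(i - 2)
    plan[[length(plan) + 1]] <- list(name = paste0("enc", i),
                                     cin = cin, cout = base * 2^(i - 1), k = 3L)
  }
  plan[[length(plan) + 1]] <- list(name = "bottleneck",
                                   cin = base * 2^(depth - 1),
                                   cout = base * 2^depth, k = 3L)
  for (i in rev(seq_len(depth))) {
    up <- if (i == depth) base * 2^depth else base * 2^i
    plan[[length(plan) + 1]] <- list(name = paste0("dec", i),
                                     cin = up + base * 2^(i - 1),
                                     cout = base * 2^(i - 1), k = 3L)
  }
  plan[[length(plan) + 1]] <- list(name = "out", cin = base, cout = 1L, k = 1L)
  plan
}

#' Build a glottis segmentation model
#'
#' A compact U-Net-style encoder-decoder: `depth` downsampling stages of
#' 3x3 convolution + ReLU + 2x2 max-pooling, a bottleneck convolution,
#' a mirrored expanding path with nearest-neighbour upsampling and skip
#' concatenation, and a 1x1 sigmoid head emitting a per-pixel glottis
#' probability in (0, 1). Output spatial shape always equals input shape;
#' inputs must have dimensions divisible by 32. Weights use seeded He
#' initialisation, so construction is reproducible.
#'
#' @param depth Number of downsampling stages (>= 1; default 3, a desk-scale
#'   setting for 128 px phantoms -- clinical-scale imagery would use 5).
#' @param base_channels Channel width of the first stage (doubles per stage).
#' @param seed Integer seed for the initialisation.
#' @return An object of class `gk_unet`.
#' @export
build_model <- function(depth = 3L, base_channels = 8L, seed = 42L) {
  if (depth < 1) stop("`depth` must be at least 1", call. = FALSE)
  plan <- unet_plan(depth, base_channels)
  params <- with_seed(seed, {
    p <- list()
    for (l in plan) {
      fanin <- l$k^2 * l$cin
      p[[paste0(l$name, "_W")]] <-
        matrix(stats::rnorm(l$cout * fanin, sd = sqrt(2 / fanin)), l$cout, fanin)
      p[[paste0(l$name, "_b")]] <- rep(0, l$cout)
    }
    p
  })
  structure(
    list(depth = as.integer(depth), base = as.integer(base_channels),
         params = params,
         n_params = unet_n_params_cpp(depth, base_channels, 1L),
         loss_history = numeric(0), steps_trained = 0L),
    class = "gk_unet"
  )
}

#' @export
print.gk_unet <- function(x, ...) {
  cat(sprintf("<gk_unet> depth %d, base %d channels, %d parameters, %d training steps\n",
              x$depth, x$base, x$n_params, x$steps_trained))
  invisible(x)
}

check_div32 <- function(H, W) {
  if (H %% 32 != 0 || W %% 32 != 0) {
    stop("geometry error: input dimensions must be divisible by 32, got ",
         H, "x", W, call. = FALSE)
  }
}

as_stack <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("expected an H x W x N array", call. = FALSE)
  x
}

#' Train or fine-tune a segmentation model
#'
#' Minimises soft Dice loss (`1 - (2 sum(p g) + s) / (sum p + sum g + s)`)
#' with the Adam optimiser, one image per step, shuffled each epoch under the
#' given seed. Dice loss matches the IoU-family evaluation criteria and is
#' robust to the foreground/background imbalance of glottis masks. Training
#' is deterministic given (model, data, seed).
#'
#' @param model A [build_model()] result.
#' @param images `H x W x N` array of luminance frames normalised to
#'   `[-1, 1]` (see [normalize_intensity()]); `H`, `W` divisible by 32.
#' @param masks `H x W x N` array of binary ground-truth (or pseudo-label)
#'   masks in `{0, 1}`.
#' @param epochs Number of passes over the data.
#' @param learning_rate Adam step size. The default 1e-4 suits from-scratch
#'   desk-scale training; continual fine-tuning conventionally uses much
#'   smaller rates (see [fine_tune_config()]).
#' @param seed Integer seed driving the shuffling.
#' @param smooth Dice smoothing constant.
#' @return The trained `gk_unet`, with `loss_history` extended by the mean
#'   per-epoch loss.
#' @export
train_model <- function(model, images, masks, epochs = 10L,
                        learning_rate = 1e-4, seed = 1L, smooth = 1) {
  stopifnot(inherits(model, "gk_unet"))
  images <- as_stack(images); masks <- as_stack(masks)
  d <- dim(images)
  if (!identical(d, dim(masks))) {
    stop("`images` and `masks` must be aligned", call. = FALSE)
  }
  if (d[3] == 0) stop("configuration error: empty training set", call. = FALSE)
  check_div32(d[1], d[2])
  X <- matrix(images, d[1] * d[2], d[3])
  Y <- matrix(as.numeric(masks > 0.5), d[1] * d[2], d[3])
  ord <- with_seed(seed, {
    unlist(lapply(seq_len(epochs), function(e) sample.int(d[3]) - 1L))
  })
  res <- unet_train_cpp(model$params, X, Y, ord, d[3], d[1], d[2],
                        model$depth, model$base, learning_rate,
                        0.9, 0.999, 1e-8, smooth)
  model$params <- res$params
  model$loss_history <- c(model$loss_history, as.numeric(res$epoch_loss))
  model$steps_trained <- model$steps_trained + length(ord)
  model
}

#' Mean soft Dice loss of a model on a labelled set
#'
#' @inheritParams train_model
#' @return Mean soft Dice loss across the images.
#' @export
model_loss <- function(model, images, masks, smooth = 1) {
  images <- as_stack(images); masks <- as_stack(masks)
  d <- dim(images)
  check_div32(d[1], d[2])
  unet_loss_cpp(model$params, matrix(images, d[1] * d[2], d[3]),
                matrix(as.numeric(masks > 0.5), d[1] * d[2], d[3]),
                d[1], d[2], model$depth, model$base, smooth)
}

#' Predict glottis masks for a recording
#'
#' Runs the full inference chain per frame: luminance extraction,
#' normalisation to `[-1, 1]`, optional ROI crop, forward pass, and rescaling
#' of the sigmoid output to 8 bit (x255). With an ROI, pixels outside the ROI
#' are 0 in the returned full-frame masks.
#'
#' @param model A [build_model()] result (trained or not).
#' @param rec A [recording()], or an `H x W x N` array of already normalised
#'   luminance frames.
#' @param roi Optional [roi_box()]; adjusted with [adjust_roi()] if its
#'   dimensions are not multiples of 32.
#' @param threshold Binarisation threshold stored in the result.
#' @return A [mask_sequence()] of 8-bit masks, one per frame.
#' @export
predict_masks <- function(model, rec, roi = NULL, threshold = 0.5) {
  stopifnot(inherits(model, "gk_unet"))
  if (inherits(rec, "gk_recording")) {
    lum <- normalize_intensity(to_luminance(rec$frames))
  } else {
    lum <- as_stack(rec)
  }
  d <- dim(lum)
  H <- d[1]; W <- d[2]; N <- d[3]
  if (!is.null(roi)) {
    if (roi$width %% 32 != 0 || roi$height %% 32 != 0) {
      roi <- adjust_roi(roi, c(H, W))
    }
    lum_in <- crop_roi(lum, roi)
  } else {
    check_div32(H, W)
    lum_in <- lum
  }
  din <- dim(lum_in)
  check_div32(din[1], din[2])
  P <- unet_predict_cpp(model$params, matrix(lum_in, din[1] * din[2], N),
                        din[1], din[2], model$depth, model$base)
  masks <- array(0L, c(H, W, N))
  if (!is.null(roi)) {
    rows <- (roi$y0 + 1):(roi$y0 + roi$height)
    cols <- (roi$x0 + 1):(roi$x0 + roi$width)
    masks[rows, cols, ] <- as.integer(round(array(P, din) * 255))
  } else {
    masks[] <- as.integer(round(array(P, din) * 255))
  }
  mask_sequence(masks, threshold = threshold)
}

#' Compute the glottal area waveform from masks
#'
#' The GAW is obtained by summing the segmented pixels in each frame: frame
#' `t`'s area is the count of pixels whose mask value exceeds the
#' binarisation threshold (on the unit scale).
#'
#' @param masks A [mask_sequence()].
#' @return A `gk_gaw` tibble with columns `frame` and `area_px2`.
#' @export
compute_gaw <- function(masks) {
  stopifnot(inherits(masks, "gk_masks"))
  gaw(apply(binarize_masks(masks), 3, sum))
}
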