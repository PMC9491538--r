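#' Dynamic range of an image
#'
#' Normalised absolute difference of the minimum and maximum pixel value:
#' `(max - min) / bit_depth_max`. 0 means a constant image, 1 full range.
#'
#' @param img Numeric matrix or array of intensities.
#' @param bit_depth_max Normalisation constant (255 for 8-bit data).
#' @return A fraction in `[0, 1]`.
#' @export
dynamic_range <- function(img, bit_depth_max = 255) {
  (max(img) - min(img)) / bit_depth_max
}

check_same_shape <- function(I, K) {
  if (!identical(dim(I) %||% length(I), dim(K) %||% length(K))) {
    stop("dimension error: images must have identical shape", call. = FALSE)
  }
}

#' Mean squared error between two images
#'
#' `MSE = (1 / (m n)) * sum((I - K)^2)` over all pixels.
#'
#' @param I,K Numeric matrices (or arrays) of identical shape.
#' @return Non-negative mean squared error; symmetric in `I` and `K`.
#' @export
mse <- function(I, K) {
  check_same_shape(I, K)
  mean((as.numeric(I) - as.numeric(K))^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `PSNR = 10 * log10(max_val^2 / MSE)`. Identical images have zero MSE and
#' return the documented `+Inf` sentinel -- lossless comparisons hit this
#' routinely.
#'
#' @param I,K Numeric matrices (or arrays) of identical shape.
#' @param max_val Peak representable intensity (255 for 8-bit).
#' @return PSNR in dB, or `Inf` when `I == K`.
#' @export
psnr <- function(I, K, max_val = 255) {
  m <- mse(I, K)
  if (m == 0) return(Inf)
  10 * log10(max_val^2 / m)
}

# mean over w x w windows fully inside the image, via integral images
box_means <- function(M, w) {
  S <- rbind(0, apply(M, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  H <- nrow(M); W <- ncol(M)
  i <- seq_len(H - w + 1); j <- seq_len(W - w + 1)
  (S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
     S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]) / (w * w)
}

gaussian_kernel <- function(w, sigma) {
  half <- (w - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# weighted local means over valid windows with an arbitrary kernel
kernel_means <- function(M, k) {
  H <- nrow(M); W <- ncol(M); w <- nrow(k)
  out <- matrix(0, H - w + 1, W - w + 1)
  for (a in seq_len(w)) {
    for (b in seq_len(w)) {
      out <- out + k[a, b] * M[a:(a + H - w), b:(b + W - w), drop = FALSE]
    }
  }
  out
}

#' Structural similarity index between two images
#'
#' Windowed product of luminance, contrast and structure comparisons:
#' `SSIM = mean over windows of l^alpha * c^beta * s^gamma` with the standard
#' stabilised forms
#' `l = (2 mu_x mu_y + C1) / (mu_x^2 + mu_y^2 + C1)`,
#' `c = (2 s_x s_y + C2) / (s_x^2 + s_y^2 + C2)`,
#' `s = (s_xy + C3) / (s_x s_y + C3)`, `C1 = (k1 L)^2`, `C2 = (k2 L)^2`,
#' `C3 = C2 / 2`. Local moments are plain (biased) moments over each window.
#' The score is symmetric and equals 1 exactly when `I == K`.
#'
#' @param I,K Numeric matrices of identical shape, at least `window` pixels
#'   in each dimension.
#' @param alpha,beta,gamma Positive exponents of the three comparisons.
#' @param window Odd local-window size in pixels (default 7, uniform).
#' @param gaussian If `TRUE`, use a Gaussian window (sigma = 1.5) of size
#'   `window` instead of the uniform window.
#' @param k1,k2 Stabilisation fractions.
#' @param L Intensity dynamic range (255 for 8-bit).
#' @return A score in `[-1, 1]`.
#' @export
ssim <- function(I, K, alpha = 1, beta = 1, gamma = 1, window = 7,
                 gaussian = FALSE, k1 = 0.01, k2 = 0.03, L = 255) {
  check_same_shape(I, K)
  if (alpha <= 0 || beta <= 0 || gamma <= 0) {
    stop("SSIM exponents must be positive", call. = FALSE)
  }
  if (window %% 2 != 1) stop("`window` must be odd", call. = FALSE)
  if (nrow(I) < window || ncol(I) < window) {
    stop("dimension error: image smaller than the SSIM window", call. = FALSE)
  }
  I <- matrix(as.numeric(I), nrow(I)); K <- matrix(as.numeric(K), nrow(K))
  mfun <- if (gaussian) {
    kk <- gaussian_kernel(window, 1.5)
    function(M) kernel_means(M, kk)
  } else {
    function(M) box_means(M, window)
  }
  mu_x <- mfun(I); mu_y <- mfun(K)
  var_x <- pmax(0, mfun(I * I) - mu_x^2)
  var_y <- pmax(0, mfun(K * K) - mu_y^2)
  cov_xy <- mfun(I * K) - mu_x * mu_y
  sx <- sqrt(var_x); sy <- sqrt(var_y)
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2; C3 <- C2 / 2
  l <- (2 * mu_x * mu_y + C1) / (mu_x^2 + mu_y^2 + C1)
  cc <- (2 * sx * sy + C2) / (sx^2 + sy^2 + C2)
  ss <- (cov_xy + C3) / (sx * sy + C3)
  # s can be negative (anti-correlated structure); keep its sign under
  # non-integer exponents
  mean(l^alpha * cc^beta * sign(ss) * abs(ss)^gamma)
}

#' Per-frame quality report for a lossy/lossless recording pair
#'
#' Computes, for every frame, the dynamic range of both versions, PSNR and
#' SSIM of lossy against lossless (on the luminance channel), and optionally
#' NIQE scores for both. Per-recording summaries aggregate frames by the
#' median.
#'
#' @param lossy,lossless [recording()]s of identical geometry.
#' @param niqe_model Optional [fit_niqe_model()] result; when supplied the
#'   report includes `niqe_lossy` and `niqe_lossless` columns.
#' @return A tibble with one row per frame.
#' @export
quality_report <- function(lossy, lossless, niqe_model = NULL) {
  stopifnot(inherits(lossy, "gk_recording"), inherits(lossless, "gk_recording"))
  check_same_shape(lossy$frames, lossless$frames)
  T <- dim(lossy$frames)[4]
  rows <- lapply(seq_len(T), function(t) {
    a <- to_luminance(lossy$frames[, , , t])
    b <- to_luminance(lossless$frames[, , , t])
    row <- tibble::tibble(
      frame = t,
      dyn_range_lossy = dynamic_range(a),
      dyn_range_lossless = dynamic_range(b),
      psnr_db = psnr(a, b),
      ssim = ssim(a, b)
    )
    if (!is.null(niqe_model)) {
      row$niqe_lossy <- niqe_score(a, niqe_model)
      row$niqe_lossless <- niqe_score(b, niqe_model)
    }
    row
  })
  dplyr::bind_rows(rows)
}
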