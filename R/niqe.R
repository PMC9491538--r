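#' Blind image quality assessment
#'
#' @section NIQE:
#' The blind "natural image quality evaluator" scores an image by the
#' distance between the statistics of its mean-subtracted contrast-normalised
#' (MSCN) coefficients and a multivariate-Gaussian model of those statistics
#' fitted to a pristine corpus. Lower is better. Because the score is a
#' distance to a corpus model, absolute values are only comparable within one
#' model; this package fits its model on clean tier-2 phantom frames and
#' asserts orderings, never absolute published values.
#' @name niqe
NULL

# symmetric-padded Gaussian filtering (same size output)
sym_filter <- function(M, k) {
  h <- (nrow(k) - 1) / 2
  H <- nrow(M); W <- ncol(M)
  ri <- c(rep(1, h), seq_len(H), rep(H, h))
  ci <- c(rep(1, h), seq_len(W), rep(W, h))
  kernel_means(M[ri, ci, drop = FALSE], k)
}

# MSCN coefficients and the local-contrast (sigma) field
mscn_transform <- function(img, window = 7, sigma_w = 7 / 6, C = 1) {
  k <- gaussian_kernel(window, sigma_w)
  mu <- sym_filter(img, k)
  sig <- sqrt(pmax(sym_filter(img * img, k) - mu^2, 0))
  list(mscn = (img - mu) / (sig + C), sigma = sig)
}

# generalized Gaussian shape lookup table
ggd_grid <- local({
  gam <- seq(0.2, 10, by = 0.001)
  r <- gamma(1 / gam) * gamma(3 / gam) / gamma(2 / gam)^2
  list(gam = gam, r = r)
})

ggd_fit <- function(x) {
  sigma_sq <- mean(x^2)
  E <- mean(abs(x))
  rho <- sigma_sq / E^2
  alpha <- ggd_grid$gam[which.min((ggd_grid$r - rho)^2)]
  c(alpha = alpha, sigma_sq = sigma_sq)
}

aggd_fit <- function(x) {
  left <- x[x < 0]; right <- x[x > 0]
  sl <- sqrt(if (length(left)) mean(left^2) else 0)
  sr <- sqrt(if (length(right)) mean(right^2) else 0)
  gammahat <- if (sr > 0) sl / sr else 1
  rhat <- if (mean(x^2) > 0) mean(abs(x))^2 / mean(x^2) else 0
  rhatnorm <- rhat * (gammahat^3 + 1) * (gammahat + 1) / (gammahat^2 + 1)^2
  alpha <- ggd_grid$gam[which.min((1 / ggd_grid$r - rhatnorm)^2)]
  eta <- (sr - sl) * (gamma(2 / alpha) / gamma(1 / alpha)) *
    sqrt(gamma(1 / alpha) / gamma(3 / alpha))
  c(alpha = alpha, eta = eta, sigma_l_sq = sl^2, sigma_r_sq = sr^2)
}

# 18 features of one MSCN patch: GGD of the coefficients plus AGGD of the
# four orientation pairwise products
patch_features <- function(m) {
  H <- nrow(m); W <- ncol(m)
  f <- ggd_fit(as.numeric(m))
  pairs <- list(
    m[, -W, drop = FALSE] * m[, -1, drop = FALSE],            # horizontal
    m[-H, , drop = FALSE] * m[-1, , drop = FALSE],            # vertical
    m[-H, -W, drop = FALSE] * m[-1, -1, drop = FALSE],        # diagonal
    m[-H, -1, drop = FALSE] * m[-1, -W, drop = FALSE]         # anti-diagonal
  )
  c(f, unlist(lapply(pairs, function(p) aggd_fit(as.numeric(p)))))
}

downscale2 <- function(M) {
  H <- 2 * (nrow(M) %/% 2); W <- 2 * (ncol(M) %/% 2)
  M <- M[1:H, 1:W, drop = FALSE]
  (M[seq(1, H, 2), seq(1, W, 2)] + M[seq(2, H, 2), seq(1, W, 2)] +
     M[seq(1, H, 2), seq(2, W, 2)] + M[seq(2, H, 2), seq(2, W, 2)]) / 4
}

# 36-dimensional feature vectors, one per patch, over two scales
image_niqe_features <- function(img, patch_size, sharpness_threshold = 0) {
  img <- matrix(as.numeric(img), nrow(img))
  if (nrow(img) < patch_size || ncol(img) < patch_size) {
    stop("dimension error: image smaller than the NIQE patch size", call. = FALSE)
  }
  t1 <- mscn_transform(img)
  t2 <- mscn_transform(downscale2(img))
  p1 <- patch_size; p2 <- patch_size / 2
  nbi <- nrow(img) %/% p1; nbj <- ncol(img) %/% p1
  feats <- NULL; sharp <- numeric(0)
  for (bi in seq_len(nbi)) {
    for (bj in seq_len(nbj)) {
      i1 <- (bi - 1) * p1 + 1; j1 <- (bj - 1) * p1 + 1
      m1 <- t1$mscn[i1:(i1 + p1 - 1), j1:(j1 + p1 - 1)]
      i2 <- (bi - 1) * p2 + 1; j2 <- (bj - 1) * p2 + 1
      m2 <- t2$mscn[i2:(i2 + p2 - 1), j2:(j2 + p2 - 1)]
      feats <- rbind(feats, c(patch_features(m1), patch_features(m2)))
      sharp <- c(sharp,
                 mean(t1$sigma[i1:(i1 + p1 - 1), j1:(j1 + p1 - 1)]))
    }
  }
  if (sharpness_threshold > 0 && length(sharp) > 1) {
    keep <- sharp >= sharpness_threshold * max(sharp)
    if (any(keep)) feats <- feats[keep, , drop = FALSE]
  }
  feats
}

#' Fit a pristine NIQE model
#'
#' Extracts MSCN-based natural-scene-statistics features (a generalized
#' Gaussian fit of the MSCN coefficients plus asymmetric generalized Gaussian
#' fits of four orientation products, over two scales; 36 features per patch)
#' from a corpus of pristine images and summarises them by their mean vector
#' and covariance.
#'
#' @param pristine List of grayscale images (matrices, 0--255 scale).
#' @param patch_size Patch side length in pixels (must be even).
#' @param sharpness_threshold Optional patch pre-selection: keep patches
#'   whose mean local contrast is at least this fraction of the sharpest
#'   patch (0 keeps everything, appropriate for homogeneous corpora).
#' @return An object of class `gk_niqe_model` with fields `mean`, `cov`,
#'   `patch_size` and `n_patches`.
#' @export
fit_niqe_model <- function(pristine, patch_size = 32,
                           sharpness_threshold = 0) {
  if (patch_size %% 2 != 0) stop("`patch_size` must be even", call. = FALSE)
  feats <- do.call(rbind, lapply(pristine, image_niqe_features,
                                 patch_size = patch_size,
                                 sharpness_threshold = sharpness_threshold))
  dim_f <- ncol(feats)
  if (nrow(feats) < 10 * dim_f) {
    stop(sprintf(
      "estimation error: %d patches are too few to estimate the %d-feature covariance (need >= %d)",
      nrow(feats), dim_f, 10 * dim_f), call. = FALSE)
  }
  structure(
    list(mean = colMeans(feats), cov = stats::cov(feats),
         patch_size = patch_size, n_patches = nrow(feats)),
    class = "gk_niqe_model"
  )
}

#' @export
print.gk_niqe_model <- function(x, ...) {
  cat(sprintf("<gk_niqe_model> %d features, %d pristine patches, patch %d px\n",
              length(x$mean), x$n_patches, x$patch_size))
  invisible(x)
}

#' Blind NIQE quality score (lower is better)
#'
#' Distance between the image's fitted feature statistics and the pristine
#' model: `sqrt((nu1 - nu2)' ((S1 + S2)/2)^+ (nu1 - nu2))` with the
#' pseudo-inverse of the pooled covariance.
#'
#' @param img Grayscale image (matrix, 0--255 scale), larger than the model's
#'   patch size.
#' @param model A [fit_niqe_model()] result.
#' @return Non-negative score; deterministic.
#' @export
niqe_score <- function(img, model) {
  stopifnot(inherits(model, "gk_niqe_model"))
  feats <- image_niqe_features(img, model$patch_size)
  nu <- colMeans(feats)
  S2 <- if (nrow(feats) > 1) stats::cov(feats) else matrix(0, length(nu), length(nu))
  d <- model$mean - nu
  pooled <- (model$cov + S2) / 2
  sqrt(max(0, drop(t(d) %*% MASS::ginv(pooled) %*% d)))
}
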