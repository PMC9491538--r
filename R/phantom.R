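#' Specify a synthetic laryngeal high-speed-video phantom
#'
#' The phantom emulates an endoscopic high-speed recording of oscillating
#' vocal folds: a dark elliptical glottal opening over textured tissue inside
#' a circular endoscopic field, imaged at a nominal 4,000 fps. Every phantom
#' carries exact ground truth (binary glottis masks and the glottal area
#' waveform), so the full segmentation and evaluation pipeline can be
#' exercised without clinical data.
#'
#' The glottal area follows a clamped sinusoid (see [gaw_profile()]): the
#' glottis is open for `open_quotient` of each cycle and closed otherwise.
#'
#' @param H,W Frame size in pixels.
#' @param T Number of frames; clinical recordings are at least 1,000 frames.
#' @param fps Frame rate (frames/second).
#' @param f0 Oscillation frequency in Hz; must satisfy `f0 < fps / 2`.
#' @param axis_a Glottis half-length along the anterior-posterior axis (px).
#' @param A_peak Peak glottal area in squared pixels. Defaults to the area of
#'   an ellipse with half-axes `axis_a` and `axis_a / 2`.
#' @param open_quotient Fraction of each cycle with non-zero area, in (0, 1].
#' @param center Glottis midpoint as `c(row, col)` (1-based pixels).
#' @param noise_sigma Additive Gaussian noise scale in intensity levels.
#' @param tier Quality tier: 2 (excellent), 1 (okay, blur and extra noise),
#'   0 (insufficient, heavy fog and occlusion of the glottis).
#' @param shift A [domain_shift()] (or list of them) applied to rendered
#'   frames only; ground truth is never affected. `NULL` for none.
#' @param seed Integer seed; all phantom output is bitwise reproducible given
#'   the spec (which includes the seed).
#'
#' @return An object of class `gk_phantom_spec`.
#' @export
phantom_spec <- function(H = 128, W = 128, T = 1000, fps = 4000, f0 = 150,
                         axis_a = 20, A_peak = pi * axis_a * (axis_a / 2),
                         open_quotient = 0.6, center = c(H / 2, W / 2),
                         noise_sigma = 4, tier = 2, shift = NULL, seed = 1) {
  if (T < 1) stop("`T` must be at least 1", call. = FALSE)
  if (f0 <= 0 || f0 >= fps / 2) {
    stop("aliasing: `f0` must lie in (0, fps/2)", call. = FALSE)
  }
  if (open_quotient <= 0 || open_quotient > 1) {
    stop("`open_quotient` must be in (0, 1]", call. = FALSE)
  }
  if (A_peak > pi * axis_a * (W / 4)) {
    stop("`A_peak` too large for the frame: peak half-width exceeds W/4",
         call. = FALSE)
  }
  if (!is.null(shift) && inherits(shift, "gk_shift")) shift <- list(shift)
  if (!is.null(shift) &&
      !all(vapply(shift, inherits, logical(1), "gk_shift"))) {
    stop("`shift` must be a domain_shift() or a list of them", call. = FALSE)
  }
  structure(
    list(H = as.integer(H), W = as.integer(W), T = as.integer(T), fps = fps,
         f0 = f0, axis_a = axis_a, A_peak = A_peak,
         open_quotient = open_quotient, center = center,
         noise_sigma = noise_sigma, tier = as.integer(tier), shift = shift,
         seed = as.integer(seed)),
    class = "gk_phantom_spec"
  )
}

#' Describe a domain shift for phantom rendering
#'
#' Domain shifts perturb rendered frames while leaving the ground truth
#' untouched; they are the mechanism for provoking segmentation artifacts
#' (spurious components, empty masks) on synthetic data.
#'
#' @param kind One of `"illumination_tint"` (colour cast towards blue-green),
#'   `"brightness_shift"` (global intensity offset) or `"distractor_patches"`
#'   (dark elongated glottis-like patches outside the true glottis).
#' @param magnitude Shift strength in `[0, 1]`; 0 reproduces the unshifted
#'   phantom exactly.
#' @param n_patches Number of patches for `"distractor_patches"`.
#' @return An object of class `gk_shift`.
#' @export
domain_shift <- function(kind = c("illumination_tint", "brightness_shift",
                                  "distractor_patches"),
                         magnitude = 0.5, n_patches = 3L) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown shift kind", call. = FALSE))
  if (magnitude < 0 || magnitude > 1) {
    stop("`magnitude` must be in [0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, magnitude = magnitude,
                 n_patches = as.integer(n_patches)),
            class = "gk_shift")
}

#' Inject a domain shift into a phantom spec
#'
#' Returns a new spec; shifts accumulate if called repeatedly. A shift of
#' magnitude 0 leaves the rendered output bitwise identical.
#'
#' @param spec A [phantom_spec()].
#' @param shift A [domain_shift()].
#' @return The modified `gk_phantom_spec`.
#' @export
inject_shift <- function(spec, shift) {
  stopifnot(inherits(spec, "gk_phantom_spec"))
  if (!inherits(shift, "gk_shift")) {
    stop("`shift` must be created with domain_shift()", call. = FALSE)
  }
  spec$shift <- c(spec$shift, list(shift))
  spec
}

#' Analytic glottal area waveform of a phantom
#'
#' The area follows a clamped sinusoid with closed phase:
#' `A(t) = A_peak * max(0, (sin(2 pi f0 t / fps) - c) / (1 - c))` with
#' `c = cos(pi * open_quotient)`, so the glottis is open for exactly
#' `open_quotient` of each cycle and the waveform is periodic with period
#' `fps / f0` frames.
#'
#' @param spec A [phantom_spec()].
#' @param frames Frame indices (1-based) at which to evaluate; defaults to
#'   the whole recording.
#' @return A `gk_gaw` tibble with columns `frame` and `area_px2`.
#' @export
gaw_profile <- function(spec, frames = seq_len(spec$T)) {
  stopifnot(inherits(spec, "gk_phantom_spec"))
  cc <- cos(pi * spec$open_quotient)
  t0 <- frames - 1
  a <- spec$A_peak * pmax(0, (sin(2 * pi * spec$f0 * t0 / spec$fps) - cc) / (1 - cc))
  out <- tibble::tibble(frame = as.integer(frames), area_px2 = a)
  class(out) <- c("gk_gaw", class(out))
  out
}

# run code under a temporary RNG state; never disturbs the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

mix_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 48271 + as.double(salt) * 8191) %% 2147483563)
}

# recording-level deterministic assets: tissue texture, vignette, distractor
# geometry, tier-0 occlusion geometry
phantom_assets <- function(spec) {
  H <- spec$H; W <- spec$W
  tex <- with_seed(mix_seed(spec$seed, 1L), {
    g <- matrix(stats::rnorm(81), 9, 9)
    # bilinear upsample of a coarse Gaussian field
    xi <- seq(1, 9, length.out = H); yi <- seq(1, 9, length.out = W)
    fi <- floor(xi); fj <- floor(yi)
    fi[fi == 9] <- 8; fj[fj == 9] <- 8
    wi <- xi - fi; wj <- yi - fj
    a <- g[fi, fj] * outer(1 - wi, 1 - wj) + g[fi + 1, fj] * outer(wi, 1 - wj) +
      g[fi, fj + 1] * outer(1 - wi, wj) + g[fi + 1, fj + 1] * outer(wi, wj)
    a / max(abs(a))
  })
  rr <- outer(seq_len(H) - (H + 1) / 2, rep(1, W))
  cc <- outer(rep(1, H), seq_len(W) - (W + 1) / 2)
  r <- sqrt(rr^2 + cc^2)
  vignette <- pmin(1, pmax(0, (0.48 * min(H, W) - r) / 3))

  patches <- NULL
  shifts <- spec$shift %||% list()
  for (s in shifts) {
    if (s$kind == "distractor_patches" && s$n_patches > 0) {
      geo <- with_seed(mix_seed(spec$seed, 7L), {
        n <- s$n_patches
        # para-glottal tissue band: lateral of the glottis, outside the
        # region where it can legitimately appear but still well lit
        side <- sample(c(0, pi), n, replace = TRUE)
        ang <- side + stats::runif(n, -pi / 9, pi / 9)
        rad <- stats::runif(n, 0.32, 0.36) * min(H, W)
        data.frame(
          cy = round((H + 1) / 2 + rad * sin(ang)),
          cx = round((W + 1) / 2 + rad * cos(ang)),
          len = stats::runif(n, 0.7, 1.1) * spec$axis_a,
          wid = stats::runif(n, 4, 6),
          theta = stats::runif(n, -pi / 8, pi / 8),
          mag = s$magnitude
        )
      })
      patches <- rbind(patches, geo)
    }
  }
  occl <- with_seed(mix_seed(spec$seed, 11L), {
    list(dy = stats::runif(1, -4, 4), dx = stats::runif(1, -4, 4),
         rad = 1.6 * spec$axis_a)
  })
  list(tex = tex, vignette = vignette, patches = patches, occl = occl,
       rowg = rr + (H + 1) / 2, colg = cc + (W + 1) / 2)
}

shift_params <- function(spec) {
  tint <- 0; bright <- 0
  for (s in spec$shift %||% list()) {
    if (s$kind == "illumination_tint") tint <- tint + s$magnitude
    if (s$kind == "brightness_shift") bright <- bright + s$magnitude
  }
  list(tint = tint, bright = bright)
}

#' Render a single phantom frame
#'
#' Rasterises the glottis as a filled ellipse of the requested area (half-
#' length `axis_a`, half-width `area / (pi * axis_a)`) at the spec's centre
#' with a seeded integer jitter of at most 2 px, over textured tissue inside
#' a circular endoscopic vignette. Tier 1 adds blur and extra noise; tier 0
#' adds heavy fog and an occluding blob over the glottis. Domain shifts are
#' applied to the frame only -- the returned mask is always the clean
#' geometric ground truth.
#'
#' @param spec A [phantom_spec()].
#' @param area Requested glottal area in squared pixels, in `[0, A_peak]`.
#' @param frame_index 1-based frame index (drives the per-frame jitter and
#'   noise streams).
#' @param assets Internal precomputed per-recording assets; leave `NULL`.
#' @return A list with `frame` (`H x W x 3` integer array) and `mask`
#'   (`H x W` logical matrix).
#' @export
render_frame <- function(spec, area, frame_index = 1L, assets = NULL) {
  stopifnot(inherits(spec, "gk_phantom_spec"))
  if (area < 0 || area > spec$A_peak + 1e-9) {
    stop("`area` must lie in [0, A_peak]", call. = FALSE)
  }
  H <- spec$H; W <- spec$W
  if (is.null(assets)) assets <- phantom_assets(spec)
  fs <- mix_seed(spec$seed, 1000L + frame_index)

  with_seed(fs, {
    jit <- sample(-2:2, 2, replace = TRUE)
    cy <- round(spec$center[1]) + jit[1]
    cx <- round(spec$center[2]) + jit[2]

    mask <- matrix(FALSE, H, W)
    if (area > 0) {
      b <- area / (pi * spec$axis_a)
      mask <- ((assets$rowg - cy) / spec$axis_a)^2 +
        ((assets$colg - cx) / b)^2 <= 1
    }

    tex <- assets$tex
    ch <- list(R = 185 + 28 * tex, G = 105 + 18 * tex, B = 110 + 15 * tex)
    glott <- c(R = 45, G = 22, B = 28)
    for (k in seq_along(ch)) ch[[k]][mask] <- glott[k]

    # distractor patches: dark elongated glottis-like blobs, frame only
    if (!is.null(assets$patches)) {
      for (p in seq_len(nrow(assets$patches))) {
        g <- assets$patches[p, ]
        dy <- assets$rowg - g$cy; dx <- assets$colg - g$cx
        u <- dy * cos(g$theta) + dx * sin(g$theta)
        v <- -dy * sin(g$theta) + dx * cos(g$theta)
        inside <- (u / g$len)^2 + (v / g$wid)^2 <= 1
        f <- 0.9 * g$mag
        for (k in seq_along(ch)) {
          ch[[k]][inside] <- ch[[k]][inside] * (1 - f) + glott[k] * f
        }
      }
    }

    sp <- shift_params(spec)
    if (sp$tint > 0) {
      ch$R <- ch$R * (1 - 0.45 * sp$tint)
      ch$G <- ch$G * (1 + 0.15 * sp$tint)
      ch$B <- ch$B * (1 + 0.45 * sp$tint)
    }
    if (sp$bright > 0) for (k in seq_along(ch)) ch[[k]] <- ch[[k]] + 70 * sp$bright

    if (spec$tier == 0L) {
      # fog plus an occluding blob hiding the glottis
      o <- assets$occl
      blob <- ((assets$rowg - (cy + o$dy))^2 + (assets$colg - (cx + o$dx))^2) <=
        o$rad^2
      for (k in seq_along(ch)) {
        ch[[k]][blob] <- 170
        ch[[k]] <- 0.45 * ch[[k]] + 0.55 * 180
      }
    }

    for (k in seq_along(ch)) ch[[k]] <- ch[[k]] * assets$vignette

    sigma_blur <- switch(as.character(spec$tier), "0" = 3, "1" = 1.2, "2" = 0)
    if (sigma_blur > 0) {
      for (k in seq_along(ch)) {
        ch[[k]] <- EBImage::gblur(ch[[k]], sigma = sigma_blur, boundary = 0)
      }
    }

    sigma_n <- spec$noise_sigma + if (spec$tier == 1L) 4 else 0
    frame <- array(0L, c(H, W, 3))
    for (k in seq_along(ch)) {
      x <- ch[[k]]
      if (sigma_n > 0) x <- x + stats::rnorm(H * W, sd = sigma_n)
      frame[, , k] <- as.integer(pmin(255, pmax(0, round(x))))
    }
    list(frame = frame, mask = mask)
  })
}

#' Generate a phantom recording with ground truth
#'
#' Renders `spec$T` frames along the analytic GAW profile. The ground-truth
#' GAW is recomputed as the rasterised mask's pixel count per frame (not the
#' analytic value), so it is exactly consistent with the masks.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `gk_phantom` with fields `rec`
#'   (a [recording()]), `gt_masks` (a binary [mask_sequence()]), `gt_gaw`
#'   (a `gk_gaw` tibble) and `spec`.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "gk_phantom_spec"))
  H <- spec$H; W <- spec$W; T <- spec$T
  assets <- phantom_assets(spec)
  profile <- gaw_profile(spec)
  frames <- array(0L, c(H, W, 3, T))
  masks <- array(0L, c(H, W, T))
  areas <- numeric(T)
  for (t in seq_len(T)) {
    rf <- render_frame(spec, profile$area_px2[t], t, assets = assets)
    frames[, , , t] <- rf$frame
    masks[, , t] <- 255L * rf$mask
    areas[t] <- sum(rf$mask)
  }
  rec <- recording(frames, fps = spec$fps, mode = "raw",
                   quality_tier = spec$tier)
  structure(
    list(rec = rec, gt_masks = mask_sequence(masks), gt_gaw = gaw(areas),
         spec = spec),
    class = "gk_phantom"
  )
}

#' @export
print.gk_phantom <- function(x, ...) {
  cat(sprintf("<gk_phantom> %d frames %dx%d, tier %d, seed %d, peak GAW %d px^2\n",
              x$spec$T, x$spec$H, x$spec$W, x$spec$tier, x$spec$seed,
              max(x$gt_gaw$area_px2)))
  invisible(x)
}

#' Generate a dated cohort of phantom recordings
#'
#' Emulates a clinical acquisition stream: `n` recordings with per-recording
#' phantom parameters sampled from realistic ranges (oscillation frequency
#' 120--220 Hz, glottis half-length 16--24 px, open quotient 0.5--0.7,
#' centre jitter, mixed quality tiers) and acquisition dates drawn over
#' `date_range`. Everything is reproducible from `seed`.
#'
#' @param n Number of recordings (may be 0).
#' @param date_range Length-2 `Date` (or coercible) vector.
#' @param frames Frames per recording (`T` of each phantom).
#' @param spec_args Named list of [phantom_spec()] arguments overriding the
#'   sampled defaults (applied to every recording).
#' @param shift_fun Optional `function(i, rng_unused)` returning a
#'   [domain_shift()] list (or `NULL`) for recording `i`; used to build
#'   drifted cohorts.
#' @param tier_probs Sampling probabilities for tiers 0, 1, 2.
#' @param materialize If `TRUE`, render each recording now (list-column
#'   `phantom`); if `FALSE`, only specs are stored and recordings can be
#'   rendered on demand with [generate_recording()].
#' @param seed Integer seed.
#' @return A tibble manifest of class `gk_cohort` with columns
#'   `recording_id`, `date`, `tier`, `seed`, `spec` and (if materialised)
#'   `phantom`.
#' @export
generate_cohort <- function(n, date_range, frames = 50, spec_args = list(),
                            shift_fun = NULL, tier_probs = c(0.1, 0.3, 0.6),
                            materialize = TRUE, seed = 1) {
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  empty <- tibble::tibble(recording_id = character(), date = as.Date(character()),
                          tier = integer(), seed = integer(), spec = list())
  class(empty) <- c("gk_cohort", class(empty))
  if (n == 0) return(empty)
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || any(is.na(date_range)) ||
      diff(as.numeric(date_range)) < 0) {
    stop("`date_range` must be two valid dates", call. = FALSE)
  }
  rows <- with_seed(mix_seed(seed, 33L), {
    span <- as.numeric(diff(date_range))
    dates <- sort(date_range[1] + round(stats::runif(n, 0, span)))
    lapply(seq_len(n), function(i) {
      tier <- sample(0:2, 1, prob = tier_probs)
      axis_a <- round(stats::runif(1, 16, 24))
      args <- list(
        T = frames,
        f0 = stats::runif(1, 120, 220),
        axis_a = axis_a,
        A_peak = pi * axis_a * (axis_a / 2),
        open_quotient = stats::runif(1, 0.5, 0.7),
        noise_sigma = stats::runif(1, 2, 6),
        tier = tier,
        seed = mix_seed(seed, 100L + i)
      )
      H0 <- spec_args$H %||% 128; W0 <- spec_args$W %||% 128
      args$center <- c(H0 / 2, W0 / 2) + sample(-8:8, 2, replace = TRUE)
      args[names(spec_args)] <- spec_args
      spec <- do.call(phantom_spec, args)
      if (!is.null(shift_fun)) {
        for (s in shift_fun(i) %||% list()) spec <- inject_shift(spec, s)
      }
      list(id = sprintf("rec%03d", i), date = dates[i], spec = spec)
    })
  })
  out <- tibble::tibble(
    recording_id = vapply(rows, `[[`, character(1), "id"),
    date = as.Date(vapply(rows, function(r) as.character(r$date), character(1))),
    tier = vapply(rows, function(r) r$spec$tier, integer(1)),
    seed = vapply(rows, function(r) r$spec$seed, integer(1)),
    spec = lapply(rows, `[[`, "spec")
  )
  if (materialize) out$phantom <- lapply(out$spec, generate_recording)
  class(out) <- c("gk_cohort", class(out))
  out
}

#' Assemble a phantom training set of luminance frames and masks
#'
#' Draws frames from a small cohort of varied tier-2 phantoms and returns
#' them ready for [train_model()]: luminance-extracted, normalised to
#' `[-1, 1]`, with binary ground-truth masks.
#'
#' @param n_frames Total number of frames to return.
#' @param seed Integer seed.
#' @param frames_per_recording Frames rendered per source phantom.
#' @param spec_args Overrides passed to [generate_cohort()].
#' @return A list with `images` (`H x W x n` array in `[-1, 1]`), `masks`
#'   (`H x W x n` array in `{0, 1}`) and `manifest` (source cohort tibble).
#' @export
phantom_training_set <- function(n_frames, seed = 1, frames_per_recording = 50,
                                 spec_args = list()) {
  n_rec <- ceiling(n_frames / frames_per_recording)
  spec_args$tier <- spec_args$tier %||% 2L
  cohort <- generate_cohort(
    n_rec, date_range = as.Date(c("2019-11-01", "2020-01-31")),
    frames = frames_per_recording, spec_args = spec_args,
    tier_probs = c(0, 0, 1), seed = seed)
  H <- cohort$spec[[1]]$H; W <- cohort$spec[[1]]$W
  images <- array(0, c(H, W, n_frames))
  masks <- array(0, c(H, W, n_frames))
  k <- 0
  for (i in seq_len(nrow(cohort))) {
    ph <- cohort$phantom[[i]]
    take <- min(frames_per_recording, n_frames - k)
    if (take <= 0) break
    for (t in seq_len(take)) {
      images[, , k + t] <- normalize_intensity(to_luminance(ph$rec$frames[, , , t]))
      masks[, , k + t] <- ph$gt_masks$masks[, , t] / 255
    }
    k <- k + take
  }
  list(images = images, masks = masks, manifest = cohort)
}
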