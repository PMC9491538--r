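#' Video compression dialects
#'
#' @section Compression dialects:
#' Recordings are persisted in two dialects mirroring clinical practice of
#' keeping a small lossy working copy next to a bit-exact archival copy:
#'
#' * **lossless** -- a multi-page TIFF with deflate compression (one page per
#'   frame, 8-bit RGB). Decoding recovers every pixel exactly.
#' * **lossy** -- an AV1 bitstream in an IVF container, produced by the
#'   SVT-AV1 encoder and decoded with dav1d. Frames are converted to
#'   full-range BT.601 YCbCr with 4:2:0 chroma subsampling (which requires
#'   even frame dimensions), and rate control uses the encoder's CRF quality
#'   scale via a single integer `quality` knob (default 5; lower is better).
#'
#' Each encoded file gets a JSON sidecar (`<path>.json`) recording the exact
#' dialect, quality knob, frame rate, acquisition date and quality tier, so a
#' decode round trip restores the recording's metadata.
#' @name videoio
NULL

find_tool <- function(name) {
  p <- Sys.which(name)
  if (!nzchar(p)) {
    stop(sprintf("required command-line tool '%s' not found on PATH", name),
         call. = FALSE)
  }
  unname(p)
}

# full-range BT.601 RGB -> YCbCr, 4:2:0 subsampled (chroma = 2x2 block mean)
rgb_to_yuv420 <- function(frame) {
  R <- frame[, , 1]; G <- frame[, , 2]; B <- frame[, , 3]
  Y <- 0.299 * R + 0.587 * G + 0.114 * B
  U <- -0.168736 * R - 0.331264 * G + 0.5 * B + 128
  V <- 0.5 * R - 0.418688 * G - 0.081312 * B + 128
  sub2 <- function(M) {
    (M[seq(1, nrow(M), 2), seq(1, ncol(M), 2)] +
       M[seq(2, nrow(M), 2), seq(1, ncol(M), 2)] +
       M[seq(1, nrow(M), 2), seq(2, ncol(M), 2)] +
       M[seq(2, nrow(M), 2), seq(2, ncol(M), 2)]) / 4
  }
  clip8 <- function(M) {
    M[] <- pmin(pmax(round(M), 0), 255)
    M
  }
  list(Y = clip8(Y), U = clip8(sub2(U)), V = clip8(sub2(V)))
}

yuv420_to_rgb <- function(Y, U, V) {
  up2 <- function(M, H, W) M[rep(seq_len(nrow(M)), each = 2),
                            rep(seq_len(ncol(M)), each = 2)][1:H, 1:W, drop = FALSE]
  H <- nrow(Y); W <- ncol(Y)
  Uf <- up2(U, H, W) - 128; Vf <- up2(V, H, W) - 128
  clip8 <- function(M) as.integer(pmin(pmax(round(M), 0), 255))
  out <- array(0L, c(H, W, 3))
  out[, , 1] <- clip8(Y + 1.402 * Vf)
  out[, , 2] <- clip8(Y - 0.344136 * Uf - 0.714136 * Vf)
  out[, , 3] <- clip8(Y + 1.772 * Uf)
  out
}

write_y4m <- function(rec, path) {
  d <- dim(rec$frames)
  # container timing is capped (high-speed rates exceed what video encoders
  # accept); the true acquisition rate travels in the JSON sidecar
  fps_num <- min(round(rec$fps), 120)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- sprintf("YUV4MPEG2 W%d H%d F%d:1 Ip A1:1 C420jpeg\n", d[2], d[1], fps_num)
  writeBin(charToRaw(hdr), con)
  for (t in seq_len(d[4])) {
    yuv <- rgb_to_yuv420(rec$frames[, , , t])
    writeBin(charToRaw("FRAME\n"), con)
    # y4m planes are row-major
    writeBin(as.raw(as.vector(t(yuv$Y))), con)
    writeBin(as.raw(as.vector(t(yuv$U))), con)
    writeBin(as.raw(as.vector(t(yuv$V))), con)
  }
  invisible(path)
}

read_y4m <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- raw()
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) stop("format error: truncated y4m stream", call. = FALSE)
    if (b == as.raw(10)) break
    hdr_raw <- c(hdr_raw, b)
  }
  hdr <- rawToChar(hdr_raw)
  toks <- strsplit(hdr, " ")[[1]]
  getv <- function(key) {
    v <- toks[startsWith(toks, key)]
    if (!length(v)) return(NA_character_)
    sub(paste0("^", key), "", v[1])
  }
  W <- as.integer(getv("W")); H <- as.integer(getv("H"))
  cfmt <- getv("C")
  if (!is.na(cfmt) && !grepl("^420", cfmt)) {
    stop("format error: unsupported y4m chroma format ", cfmt, call. = FALSE)
  }
  frames <- list()
  repeat {
    line <- raw()
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) break
    while (length(b) && b != as.raw(10)) {
      line <- c(line, b)
      b <- readBin(con, "raw", 1)
    }
    if (!startsWith(rawToChar(line), "FRAME")) {
      stop("format error: bad y4m frame marker", call. = FALSE)
    }
    ysz <- H * W; csz <- (H / 2) * (W / 2)
    buf <- readBin(con, "raw", ysz + 2 * csz)
    if (length(buf) < ysz + 2 * csz) {
      stop("format error: truncated y4m frame payload", call. = FALSE)
    }
    Y <- matrix(as.integer(buf[1:ysz]), H, W, byrow = TRUE)
    U <- matrix(as.integer(buf[ysz + 1:csz]), H / 2, W / 2, byrow = TRUE)
    V <- matrix(as.integer(buf[ysz + csz + 1:csz]), H / 2, W / 2, byrow = TRUE)
    frames[[length(frames) + 1]] <- yuv420_to_rgb(Y, U, V)
  }
  if (!length(frames)) stop("format error: y4m stream contains no frames", call. = FALSE)
  out <- array(0L, c(H, W, 3, length(frames)))
  for (t in seq_along(frames)) out[, , , t] <- frames[[t]]
  out
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(rec, path, mode, quality) {
  d <- dim(rec$frames)
  meta <- list(
    format = if (mode == "lossy") "ivf/av1" else "tiff/deflate",
    mode = mode,
    quality = if (mode == "lossy") quality else 0,
    pixel_format = if (mode == "lossy") "yuv420 full-range bt601" else "rgb24",
    width = d[2], height = d[1], frames = d[4],
    fps = rec$fps, date = format(rec$date), quality_tier = rec$quality_tier
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, pretty = TRUE)
}

#' Encode a recording to disk
#'
#' See the package's compression-dialect documentation: `mode = "lossless"`
#' writes a bit-exact multi-page deflate TIFF; `mode = "lossy"` writes an
#' AV1/IVF bitstream with 4:2:0 chroma subsampling (frame dimensions must be
#' even) controlled by a single integer `quality` knob on the encoder's CRF
#' scale. A JSON metadata sidecar is written next to the file.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @param mode `"lossy"` or `"lossless"`.
#' @param quality Integer CRF-style quality for the lossy dialect (lower is
#'   better fidelity; default 5).
#' @return The output path, invisibly.
#' @export
encode_recording <- function(rec, path, mode = c("lossy", "lossless"),
                             quality = 5L) {
  stopifnot(inherits(rec, "gk_recording"))
  mode <- match.arg(mode)
  d <- dim(rec$frames)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("I/O error: directory does not exist: ", dir, call. = FALSE)
  if (mode == "lossless") {
    pages <- lapply(seq_len(d[4]), function(t) rec$frames[, , , t] / 255)
    ok <- tiff::writeTIFF(pages, path, bits.per.sample = 8L,
                          compression = "deflate")
    if (!ok[1]) stop("I/O error: failed to write TIFF", call. = FALSE)
  } else {
    if (d[1] %% 2 != 0 || d[2] %% 2 != 0) {
      stop("dimension error: lossy mode (4:2:0 chroma subsampling) requires ",
           "even frame dimensions, got ", d[1], "x", d[2], call. = FALSE)
    }
    enc <- find_tool("SvtAv1EncApp")
    y4m <- tempfile(fileext = ".y4m")
    on.exit(unlink(y4m), add = TRUE)
    write_y4m(rec, y4m)
    status <- system2(enc, c("-i", shQuote(y4m), "-b", shQuote(path),
                             "--crf", as.integer(quality), "--preset", "8",
                             "--keyint", "0", "--lp", "1"),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0 || !file.exists(path)) {
      stop("I/O error: AV1 encoding failed (status ", status, ")", call. = FALSE)
    }
  }
  write_sidecar(rec, path, mode, quality)
  invisible(path)
}

#' Decode a recording from disk
#'
#' The container is sniffed from the file's magic bytes (TIFF or IVF); the
#' JSON sidecar written by [encode_recording()], when present, restores frame
#' rate, acquisition date and quality tier.
#'
#' @param path File produced by [encode_recording()].
#' @return A [recording()] whose `mode` records the dialect it came from.
#' @export
decode_recording <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", 4)
  if (length(magic) < 4) stop("format error: file too short", call. = FALSE)
  is_tiff <- identical(magic[1:2], charToRaw("II")) ||
    identical(magic[1:2], charToRaw("MM"))
  is_ivf <- identical(magic, charToRaw("DKIF"))
  if (!is_tiff && !is_ivf) {
    stop("format error: not a recognised recording container", call. = FALSE)
  }
  if (is_tiff) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) stop("format error: ", conditionMessage(e),
                                               call. = FALSE))
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    frames <- array(0L, c(d[1], d[2], 3, length(pages)))
    for (t in seq_along(pages)) {
      frames[, , , t] <- as.integer(round(pages[[t]][, , 1:3] * 255))
    }
    mode <- "lossless"
  } else {
    dec <- find_tool("dav1d")
    y4m <- tempfile(fileext = ".y4m")
    on.exit(unlink(y4m), add = TRUE)
    status <- suppressWarnings(
      system2(dec, c("-i", shQuote(path), "-o", shQuote(y4m)),
              stdout = FALSE, stderr = FALSE))
    if (status != 0 || !file.exists(y4m) || file.size(y4m) == 0) {
      stop("format error: AV1 decoding failed", call. = FALSE)
    }
    frames <- read_y4m(y4m)
    mode <- "lossy"
  }
  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- tryCatch(jsonlite::read_json(sc), error = function(e) list())
  }
  recording(frames,
            fps = meta$fps %||% 4000,
            date = meta$date %||% Sys.Date(),
            mode = meta$mode %||% mode,
            quality_tier = meta$quality_tier %||% 2L)
}

#' Read and write ROI sidecar files
#'
#' ROIs are persisted as a flat JSON object with keys `x0`, `y0`, `width`,
#' `height` (0-based pixels, see [roi_box()]). `read_roi()` validates the
#' sidecar and reports every missing key by name.
#'
#' @param roi A [roi_box()].
#' @param path JSON file path.
#' @return `write_roi()` returns the path invisibly; `read_roi()` returns a
#'   `gk_roi`.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "gk_roi"))
  jsonlite::write_json(unclass(roi), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("parse error: file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("parse error: invalid JSON in ", path,
                                           call. = FALSE))
  need <- c("x0", "y0", "width", "height")
  missing <- setdiff(need, names(obj))
  if (length(missing)) {
    stop("parse error: ROI sidecar missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  roi_box(obj$x0, obj$y0, obj$width, obj$height)
}
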