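test_that("lossless encode/decode round-trips arbitrary 8-bit content exactly", {
  set.seed(101)
  for (rep in 1:3) {
    frames <- array(sample(0:255, 32 * 32 * 3 * 4, replace = TRUE),
                    c(32, 32, 3, 4))
    rec <- recording(frames, fps = 4000, date = as.Date("2020-06-01"),
                     quality_tier = 1L)
    path <- withr::local_tempfile(fileext = ".tif")
    encode_recording(rec, path, "lossless")
    back <- decode_recording(path)
    expect_identical(back$frames, rec$frames)
    expect_identical(back$mode, "lossless")
    expect_identical(back$quality_tier, 1L)
    expect_equal(back$fps, 4000)
    expect_equal(back$date, as.Date("2020-06-01"))
  }
})

test_that("constant-gray stack survives the lossless dialect bit-exactly", {
  frames <- array(128L, c(64, 64, 3, 8))
  rec <- recording(frames)
  path <- withr::local_tempfile(fileext = ".tif")
  encode_recording(rec, path, "lossless")
  expect_identical(decode_recording(path)$frames, frames)
})

test_that("lossy round trip preserves geometry with bounded pixel error", {
  ph <- generate_recording(phantom_spec(T = 16, seed = 11))
  dir <- withr::local_tempdir()
  f_lossy <- file.path(dir, "rec.ivf")
  f_lossless <- file.path(dir, "rec.tif")
  encode_recording(ph$rec, f_lossy, "lossy")
  encode_recording(ph$rec, f_lossless, "lossless")
  back <- decode_recording(f_lossy)
  expect_identical(dim(back$frames), dim(ph$rec$frames))
  expect_identical(back$mode, "lossy")
  mae <- mean(abs(back$frames - ph$rec$frames))
  expect_lt(mae, 10)
  # lossy dialect must undercut the lossless dialect on non-constant content
  expect_lt(file.size(f_lossy), file.size(f_lossless))
})

test_that("lossy mode refuses odd frame dimensions", {
  frames <- array(100L, c(65, 64, 3, 2))
  rec <- recording(frames)
  expect_error(encode_recording(rec, tempfile(fileext = ".ivf"), "lossy"),
               "dimension error")
})

test_that("corrupt and truncated inputs raise format errors", {
  bad <- withr::local_tempfile(fileext = ".ivf")
  writeBin(as.raw(c(1, 2, 3)), bad)
  expect_error(decode_recording(bad), "format error")

  ph <- generate_recording(phantom_spec(T = 4, seed = 5))
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ok.ivf")
  encode_recording(ph$rec, f, "lossy")
  trunc <- file.path(dir, "trunc.ivf")
  writeBin(readBin(f, "raw", 40), trunc)
  expect_error(decode_recording(trunc), "format error")

  expect_error(decode_recording(file.path(dir, "missing.ivf")), "format error")
})

test_that("ROI sidecars are an exact inverse pair with validated keys", {
  roi <- roi_box(3, 5, 224, 160)
  path <- withr::local_tempfile(fileext = ".json")
  write_roi(roi, path)
  back <- read_roi(path)
  expect_identical(unclass(back), unclass(roi))

  jsonlite::write_json(list(x0 = 1, y0 = 2, width = 10), path,
                       auto_unbox = TRUE)
  expect_error(read_roi(path), "height")

  expect_error(roi_box(0, 0, 0, 10), "positive")
  expect_error(roi_box(-1, 0, 5, 5), "non-negative")
})
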