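test_that("dynamic range follows the normalized min-max definition", {
  expect_equal(dynamic_range(matrix(77, 4, 4)), 0)
  img <- matrix(c(0, 255, 100, 30), 2, 2)
  expect_equal(dynamic_range(img), 1)
  expect_equal(dynamic_range(matrix(c(50, 150, 60, 70), 2, 2)), 100 / 255)
})

test_that("MSE and PSNR match brute-force oracles on random images", {
  set.seed(42)
  for (rep in 1:20) {
    I <- matrix(runif(256, 0, 255), 16)
    K <- matrix(runif(256, 0, 255), 16)
    expect_equal(mse(I, K), oracle_mse(I, K), tolerance = 1e-12)
    expect_equal(psnr(I, K), oracle_psnr(I, K), tolerance = 1e-12)
    expect_equal(mse(I, K), mse(K, I))
  }
  expect_equal(mse(matrix(0, 3, 3), matrix(2, 3, 3)), 4)
  expect_error(mse(matrix(0, 3, 3), matrix(0, 4, 4)), "dimension error")
})

test_that("PSNR sentinels and anchors hold", {
  I <- matrix(runif(64, 0, 255), 8)
  expect_identical(psnr(I, I), Inf)
  expect_equal(psnr(matrix(0, 8, 8), matrix(255, 8, 8)), 0)
  # MSE of 1 at 8 bit
  K <- matrix(5, 8, 8); L <- matrix(6, 8, 8)
  expect_equal(psnr(K, L), 10 * log10(255^2), tolerance = 1e-12)
})

test_that("SSIM matches the windowed closed-form oracle", {
  set.seed(7)
  for (rep in 1:10) {
    I <- matrix(runif(256, 0, 255), 16)
    K <- matrix(pmin(255, pmax(0, I + rnorm(256, sd = 20))), 16)
    expect_equal(ssim(I, K), oracle_ssim(I, K), tolerance = 1e-9)
    expect_equal(ssim(I, K), ssim(K, I), tolerance = 1e-12)
  }
  I <- matrix(runif(256, 0, 255), 16)
  expect_equal(ssim(I, I), 1)
  # a single-window image equals the direct window formula
  J <- matrix(runif(49, 0, 255), 7)
  Kk <- matrix(runif(49, 0, 255), 7)
  expect_equal(ssim(J, Kk), oracle_ssim(J, Kk), tolerance = 1e-9)
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 4, 4)), "dimension error")
})

test_that("structured image scores low against its intensity inversion", {
  grad <- outer(seq(30, 220, length.out = 32), seq(30, 220, length.out = 32),
                function(a, b) (a + b) / 2)
  inv <- 255 - grad
  expect_lt(ssim(grad, inv), 0.5)
})

test_that("PSNR decreases with increasing noise variance on average", {
  set.seed(99)
  I <- matrix(runif(1024, 0, 255), 32)
  mean_psnr <- vapply(c(2, 8, 24), function(s) {
    mean(vapply(1:8, function(r) {
      K <- matrix(pmin(255, pmax(0, I + rnorm(1024, sd = s))), 32)
      psnr(I, K)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_psnr) < 0))
})

test_that("quality_report produces per-frame metrics for a recording pair", {
  ph <- generate_recording(phantom_spec(T = 4, seed = 13))
  dir <- withr::local_tempdir()
  f_lossy <- file.path(dir, "a.ivf"); f_lossless <- file.path(dir, "b.tif")
  encode_recording(ph$rec, f_lossy, "lossy")
  encode_recording(ph$rec, f_lossless, "lossless")
  rep <- quality_report(decode_recording(f_lossy), decode_recording(f_lossless))
  expect_equal(nrow(rep), 4)
  expect_true(all(is.finite(rep$psnr_db)))
  expect_true(all(rep$ssim < 1 & rep$ssim > 0))
  expect_true(all(rep$dyn_range_lossless <= 1))
})
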