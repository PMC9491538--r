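test_that("analytic GAW has the stated waveform, clamping and period", {
  spec <- phantom_spec(T = 64, f0 = 250, fps = 4000, open_quotient = 1,
                       axis_a = 20)
  g <- gaw_profile(spec)
  # full-cycle opening: quarter-period frame reaches the peak area
  period <- spec$fps / spec$f0
  expect_equal(period, 16)
  expect_equal(g$area_px2[1 + period / 4], spec$A_peak)
  # periodicity
  expect_equal(g$area_px2[1:16], g$area_px2[17:32], tolerance = 1e-9)

  spec2 <- phantom_spec(T = 64, f0 = 200, open_quotient = 0.5)
  g2 <- gaw_profile(spec2)
  expect_true(all(g2$area_px2 >= 0))
  expect_true(any(g2$area_px2 == 0))  # closed phase exists
  # open for about open_quotient of each cycle
  expect_equal(mean(g2$area_px2 > 0), 0.5, tolerance = 0.1)

  expect_error(phantom_spec(f0 = 2000, fps = 4000), "aliasing")
})

test_that("rendered masks match the requested ellipse area", {
  spec <- phantom_spec(axis_a = 20, seed = 9)
  area <- pi * 20 * 10
  rf <- render_frame(spec, area, frame_index = 3)
  expect_equal(sum(rf$mask), area, tolerance = 0.05 * area)
  # half-width >= 3 px over a range of areas
  for (a in c(pi * 20 * 3, pi * 20 * 6, pi * 20 * 9)) {
    rf <- render_frame(spec, a, frame_index = 1)
    expect_equal(sum(rf$mask), a, tolerance = 0.05 * a)
  }
  # closed glottis
  rf0 <- render_frame(spec, 0, frame_index = 2)
  expect_false(any(rf0$mask))
  expect_error(render_frame(spec, spec$A_peak * 2, 1), "A_peak")
})

test_that("rendering is bitwise deterministic given (spec, seed)", {
  spec <- phantom_spec(T = 5, seed = 77)
  a <- render_frame(spec, 300, frame_index = 4)
  b <- render_frame(spec, 300, frame_index = 4)
  expect_identical(a$frame, b$frame)
  expect_identical(a$mask, b$mask)
  ph1 <- generate_recording(spec)
  ph2 <- generate_recording(spec)
  expect_identical(ph1$rec$frames, ph2$rec$frames)
  expect_identical(ph1$gt_masks$masks, ph2$gt_masks$masks)
})

test_that("recordings carry exactly consistent ground truth", {
  spec <- phantom_spec(T = 40, seed = 3, noise_sigma = 0)
  ph <- generate_recording(spec)
  expect_equal(n_frames(ph$rec), 40)
  expect_equal(dim(ph$gt_masks$masks)[3], 40)
  expect_equal(nrow(ph$gt_gaw), 40)
  # gt GAW is the rasterised pixel count, exactly
  expect_identical(ph$gt_gaw$area_px2,
                   as.numeric(apply(ph$gt_masks$masks > 0, 3, sum)))
  # tier 2, no noise: every open-phase mask is non-empty
  open_phase <- gaw_profile(spec)$area_px2 > 0
  expect_true(all(ph$gt_gaw$area_px2[open_phase] > 0))
})

test_that("different seeds change pixels but not the mask geometry budget", {
  s1 <- phantom_spec(T = 10, seed = 1)
  s2 <- phantom_spec(T = 10, seed = 2)
  ph1 <- generate_recording(s1)
  ph2 <- generate_recording(s2)
  expect_false(identical(ph1$rec$frames, ph2$rec$frames))
  # same analytic profile, so rasterised areas agree within tolerance
  expect_equal(ph1$gt_gaw$area_px2, ph2$gt_gaw$area_px2,
               tolerance = 0.1)
})

test_that("domain shifts at magnitude zero are exact identities", {
  spec <- phantom_spec(T = 4, seed = 21)
  base <- generate_recording(spec)
  for (kind in c("illumination_tint", "brightness_shift",
                 "distractor_patches")) {
    shifted <- inject_shift(spec, domain_shift(kind, magnitude = 0))
    ph <- generate_recording(shifted)
    expect_identical(ph$rec$frames, base$rec$frames, label = kind)
  }
  expect_error(domain_shift("vignette_wobble"), "unknown shift kind")
})

test_that("shifts perturb frames but never the ground truth", {
  spec <- phantom_spec(T = 6, seed = 33)
  base <- generate_recording(spec)
  shifted <- generate_recording(
    inject_shift(spec, domain_shift("distractor_patches", 1, n_patches = 3)))
  expect_identical(shifted$gt_masks$masks, base$gt_masks$masks)
  expect_false(identical(shifted$rec$frames, base$rec$frames))

  brighter <- generate_recording(
    inject_shift(spec, domain_shift("brightness_shift", 1)))
  expect_gt(mean(brighter$rec$frames), mean(base$rec$frames))
})

test_that("cohorts are reproducible, dated within range, and sized right", {
  expect_equal(nrow(generate_cohort(0, c("2020-01-01", "2020-03-01"))), 0)
  c1 <- generate_cohort(25, c("2019-11-01", "2020-01-10"), frames = 2,
                        materialize = FALSE, seed = 5)
  c2 <- generate_cohort(25, c("2019-11-01", "2020-01-10"), frames = 2,
                        materialize = FALSE, seed = 5)
  expect_identical(c1$date, c2$date)
  expect_identical(c1$seed, c2$seed)
  c3 <- generate_cohort(40, c("2020-01-01", "2020-03-11"), frames = 2,
                        materialize = FALSE, seed = 8)
  expect_true(all(c3$date >= as.Date("2020-01-01") &
                    c3$date <= as.Date("2020-03-11")))
  expect_error(generate_cohort(3, as.Date(c(NA, NA))), "date")
})
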