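test_that("overlap metrics match their textbook anchor cases", {
  G <- matrix(FALSE, 20, 20); G[1:10, 1:10] <- TRUE
  P <- matrix(FALSE, 20, 20); P[1:10, 6:15] <- TRUE
  expect_equal(iou(G, P), 1 / 3)       # 50 / 150
  expect_equal(dice_score(G, P), 0.5)  # 2*IoU/(1+IoU)
  expect_equal(iou(G, G), 1)
  expect_equal(dice_score(G, G), 1)
  disjoint <- matrix(FALSE, 20, 20); disjoint[15:20, 15:20] <- TRUE
  expect_equal(iou(G, disjoint), 0)
  expect_equal(dice_score(G, disjoint), 0)
  expect_equal(pixel_accuracy(G, G), 1)
  one_off <- G; one_off[1, 1] <- FALSE
  expect_equal(pixel_accuracy(matrix(G[1:10, 1:10], 10), matrix(one_off[1:10, 1:10], 10)),
               0.99)
  expect_equal(pixel_accuracy(G, !G), 0)
  expect_error(iou(G, matrix(FALSE, 10, 10)), "dimension error")
})

test_that("empty-vs-empty convention is 1 by default and flaggable", {
  e <- matrix(FALSE, 8, 8)
  expect_equal(iou(e, e), 1)
  expect_equal(dice_score(e, e), 1)
  expect_true(is.na(iou(e, e, empty_value = NA)))
})

test_that("metrics agree with exhaustive pixel-count oracles", {
  set.seed(11)
  for (rep in 1:40) {
    G <- random_mask(); P <- random_mask()
    expect_equal(iou(G, P), oracle_iou(G, P), tolerance = 1e-12)
    expect_equal(dice_score(G, P), oracle_dice(G, P), tolerance = 1e-12)
    expect_equal(pixel_accuracy(G, P), oracle_pixel_acc(G, P),
                 tolerance = 1e-12)
    expect_equal(iou(G, P), iou(P, G))
    expect_lte(iou(G, P), dice_score(G, P))
  }
})

test_that("boundary IoU restricts to contour bands and limits to plain IoU", {
  G <- matrix(FALSE, 20, 20); G[5:14, 5:14] <- TRUE
  P <- matrix(FALSE, 20, 20); P[6:15, 5:14] <- TRUE  # 1 px shift
  expect_equal(boundary_iou(G, G, 2), 1)
  expect_equal(boundary_iou(G, P, 2), oracle_boundary_iou(G, P, 2),
               tolerance = 1e-12)
  # band covering the diagonal reduces to plain IoU
  expect_equal(boundary_iou(G, P, 30), iou(G, P), tolerance = 1e-12)
  set.seed(23)
  for (rep in 1:10) {
    A <- random_mask(); B <- random_mask()
    expect_equal(boundary_iou(A, B, 2), oracle_boundary_iou(A, B, 2),
                 tolerance = 1e-12)
    expect_equal(boundary_iou(A, B, 23), iou(A, B), tolerance = 1e-12)
  }
})

test_that("artifact detection flags spurious components and gaps", {
  ph <- generate_recording(phantom_spec(T = 20, seed = 8))
  prior <- roi_box(36, 24, 56, 80)
  clean <- detect_artifacts(ph$gt_masks, prior)
  expect_equal(clean$artifact_count, 0)
  expect_false(clean$video_flag)

  # inject a 100 px blob outside the prior into 5 frames
  tampered <- ph$gt_masks$masks
  for (t in 3:7) tampered[5:14, 110:119, t] <- 255L
  art <- detect_artifacts(mask_sequence(tampered), prior)
  expect_equal(art$spurious_frames, 3:7)
  expect_equal(art$artifact_count, 5)
  expect_true(art$video_flag)  # 5/20 frames > 10%

  # open-open-empty-open-open: the middle frame is empty-while-open
  m <- array(0L, c(16, 16, 5)); m[8, 8, c(1, 2, 4, 5)] <- 255L
  gap <- detect_artifacts(mask_sequence(m), roi_box(0, 0, 16, 16))
  expect_equal(gap$empty_frames, 3L)
})

test_that("GAW agreement statistics behave as correlation and deviation", {
  a <- gaw(c(0, 10, 40, 90, 40, 10, 0, 0))
  expect_equal(gaw_agreement(a, a)$pearson_r, 1)
  expect_equal(gaw_agreement(a, a)$max_abs_deviation, 0)
  doubled <- gaw(2 * a$area_px2)
  agr <- gaw_agreement(a, doubled)
  expect_equal(agr$pearson_r, 1)
  expect_gt(agr$rmse, 0)

  set.seed(3)
  noisy <- gaw(pmax(0, a$area_px2 + rnorm(8, sd = 3)))
  expect_equal(gaw_agreement(a, noisy)$pearson_r,
               cor(a$area_px2, noisy$area_px2))

  const <- gaw(rep(5, 8))
  expect_message(r <- gaw_agreement(const, a)$pearson_r, "constant")
  expect_true(is.na(r))
  expect_error(gaw_agreement(a, gaw(1:3)), "length mismatch")
})

test_that("evaluate_segmentation bundles frames, artifacts and GAW agreement", {
  ph <- generate_recording(phantom_spec(T = 10, seed = 44))
  ev <- evaluate_segmentation(ph$gt_masks, ph$gt_masks,
                              prior = roi_box(36, 24, 56, 80))
  expect_true(all(tidy(ev)$iou == 1))
  gl <- glance(ev)
  expect_equal(gl$median_dice, 1)
  expect_equal(gl$artifact_frames, 0)
  expect_equal(gl$gaw_pearson_r, 1)
})
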