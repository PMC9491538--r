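manifest_on_days <- function(days, start = "2020-01-01") {
  tibble::tibble(
    recording_id = sprintf("r%02d", seq_along(days)),
    date = as.Date(start) + days
  )
}

test_that("fixed-quantity schedules chunk in date order with a pending tail", {
  cohort <- generate_cohort(25, c("2020-01-01", "2020-02-19"), frames = 2,
                            materialize = FALSE, seed = 4)
  s <- make_schedule(cohort, continual_strategy("fixed_quantity",
                                                batch_size = 10))
  expect_length(s$batches, 2)
  expect_equal(vapply(s$batches, nrow, integer(1)), c(10L, 10L))
  expect_equal(nrow(s$pending), 5)
  # chronological: every batch ends no later than the next begins
  expect_lte(max(s$batches[[1]]$date), min(s$batches[[2]]$date))
})

test_that("fixed-time schedules window from the earliest date", {
  man <- manifest_on_days(c(0, 1, 8, 9, 20))
  s <- make_schedule(man, continual_strategy("fixed_time", period_days = 7))
  expect_length(s$batches, 3)
  expect_equal(lapply(s$batches, function(b) b$recording_id),
               list(c("r01", "r02"), c("r03", "r04"), "r05"))
  expect_equal(nrow(s$pending), 0)
})

test_that("schedules partition the cohort with nothing lost or duplicated", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(0:40, 1)
    man <- manifest_on_days(sort(sample(0:120, n, replace = TRUE)))
    man$recording_id <- sprintf("r%03d", seq_len(n))
    for (strat in list(
      continual_strategy("fixed_quantity", batch_size = sample(c(5, 10, 20), 1)),
      continual_strategy("fixed_time", period_days = sample(c(7, 14, 30), 1)))) {
      s <- suppressMessages(make_schedule(man, strat))
      ids <- c(unlist(lapply(s$batches, function(b) b$recording_id)),
               s$pending$recording_id)
      expect_setequal(ids, man$recording_id)
      expect_equal(anyDuplicated(ids), 0)
      if (strat$kind == "fixed_time") expect_equal(nrow(s$pending), 0)
    }
  }
  empty <- make_schedule(manifest_on_days(integer(0)),
                         continual_strategy("fixed_quantity", batch_size = 10))
  expect_length(empty$batches, 0)
})

test_that("strategy construction enforces exactly one active parameter", {
  expect_error(continual_strategy("fixed_quantity"), "batch_size")
  expect_error(continual_strategy("fixed_time", batch_size = 10), "period_days")
  expect_s3_class(continual_strategy("fixed_time", period_days = 14),
                  "gk_strategy")
  expect_error(fine_tune_config(epochs = 0), "epochs")
})

test_that("pseudo-labelling yields pairs from every clean recording", {
  model <- gk_baseline_model()
  prior <- roi_box(36, 24, 56, 80)
  cohort <- generate_cohort(3, c("2020-01-01", "2020-01-20"), frames = 6,
                            tier_probs = c(0, 0, 1), seed = 19)
  pairs <- pseudo_label_batch(model, cohort, prior,
                              frames_per_recording = 3)
  expect_equal(pairs$n_recordings_used, 3)
  expect_equal(dim(pairs$images)[3], 9)
  expect_true(all(pairs$masks %in% c(0, 1)))

  expect_warning(empty <- pseudo_label_batch(model, cohort[0, ], prior),
                 "empty batch")
  expect_equal(empty$n_recordings_used, 0)
})

test_that("the artifact filter excludes flagged recordings from training", {
  model <- gk_baseline_model()
  prior <- roi_box(36, 24, 56, 80)
  clean <- generate_cohort(2, c("2020-01-01", "2020-01-10"), frames = 6,
                           tier_probs = c(0, 0, 1), seed = 23)
  dirty <- generate_cohort(1, c("2020-01-11", "2020-01-20"), frames = 6,
                           tier_probs = c(0, 0, 1), seed = 24,
                           shift_fun = function(i)
                             list(domain_shift("distractor_patches", 1,
                                               n_patches = 3)))
  dirty$recording_id <- "rec999"
  batch <- dplyr::bind_rows(clean, dirty)

  filtered <- pseudo_label_batch(model, batch, prior,
                                 frames_per_recording = 3)
  expect_equal(filtered$n_recordings_used, 2)
  expect_equal(filtered$excluded_ids, "rec999")

  unfiltered <- pseudo_label_batch(model, batch, prior,
                                   artifact_filter = FALSE,
                                   frames_per_recording = 3)
  expect_equal(unfiltered$n_recordings_used, 3)
  expect_length(unfiltered$excluded_ids, 0)
})

test_that("continual steps honour the no-op and fine-tuning contracts", {
  model <- gk_baseline_model()
  prior <- roi_box(36, 24, 56, 80)
  cohort <- generate_cohort(2, c("2020-01-01", "2020-01-10"), frames = 6,
                            tier_probs = c(0, 0, 1), seed = 29)
  pairs <- pseudo_label_batch(model, cohort, prior, frames_per_recording = 3)

  frozen <- continual_step(model, pairs,
                           fine_tune_config(epochs = 2, learning_rate = 0))
  expect_equal(frozen$params, model$params, tolerance = 1e-6)

  expect_warning(noop <- continual_step(model, list(images = NULL)),
                 "no training pairs")
  expect_identical(noop$params, model$params)

  # fine-tuning reduces the loss on its own pseudo-labels
  before <- model_loss(model, pairs$images, pairs$masks)
  tuned <- continual_step(model, pairs,
                          fine_tune_config(epochs = 15, learning_rate = 1e-4,
                                           seed = 2))
  expect_lte(model_loss(tuned, pairs$images, pairs$masks), before)
})

test_that("experiments are bookkept, reproducible and leakage-checked", {
  model <- gk_baseline_model()
  sc <- drift_scenario(seed = 42, n_cohort = 4, frames_per_recording = 6,
                       n_eval = 2, eval_frames = 6)
  strat <- continual_strategy("fixed_quantity", batch_size = 2)
  cfg <- fine_tune_config(epochs = 2, learning_rate = 1e-5, seed = 3)

  res <- run_experiment(sc$cohort, strat, cfg, sc$eval_set, model, sc$prior,
                        eval_frames = 6, frames_per_recording = 2)
  expect_equal(max(res$steps$step), 2)
  expect_equal(nrow(res$steps), 3)  # baseline + 2 steps
  expect_length(res$models, 3)

  res2 <- run_experiment(sc$cohort, strat, cfg, sc$eval_set, model, sc$prior,
                         eval_frames = 6, frames_per_recording = 2)
  expect_identical(res$steps, res2$steps)

  leaky <- sc$eval_set
  leaky$recording_id[1] <- sc$cohort$recording_id[1]
  expect_error(run_experiment(sc$cohort, strat, cfg, leaky, model, sc$prior),
               "configuration error")
})
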