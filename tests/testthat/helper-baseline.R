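# Desk-scale baseline segmenter, trained once per test run and shared by the
# training-recovery and continual-learning checks. Conditions: 500 tier-2
# phantom frames at 128x128, fixed seeds, depth-3/8-channel model, soft Dice
# loss with Adam at the package's from-scratch default rate.
baseline_cache <- new.env(parent = emptyenv())

gk_baseline_model <- function() {
  if (!is.null(baseline_cache$model)) return(baseline_cache$model)
  tr <- phantom_training_set(500, seed = 2024)
  m <- build_model(depth = 3, base_channels = 8, seed = 42)
  m <- train_model(m, tr$images, tr$masks, epochs = 4,
                   learning_rate = 1e-4, seed = 7)
  baseline_cache$model <- m
  m
}

gk_holdout_set <- function() {
  if (is.null(baseline_cache$holdout)) {
    baseline_cache$holdout <- phantom_training_set(100, seed = 4048)
  }
  baseline_cache$holdout
}
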