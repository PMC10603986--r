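# Shared fixtures, built lazily once per test run.  The small dataset uses a
# coarse solver grid to keep forward solves cheap; everything it feeds is
# grid-agnostic logic.

.fixtures <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_dataset(
      n_profiles = 80, seed = 11, solver_grid = 27,
      split = c(0.8, 0.1, 0.1))
  }
  .fixtures$small
}

# A quickly trained low-capacity fit on the small dataset.
small_fit <- function() {
  if (is.null(.fixtures$fit)) {
    .fixtures$fit <- train_model(
      small_dataset(),
      model_config(base_channels = 2L),
      train_config(batch_size = 16L, max_epochs = 4L, patience = 3L, seed = 5L))
  }
  .fixtures$fit
}

# Tiny architecture for fast exact checks (gradient, shapes).
tiny_config <- function() {
  model_config(depth = 3L, convs_per_block = 2L, base_channels = 2L,
               input_size = 8L, in_channels = 2L, out_pixels = 4L)
}
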