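# One reduced-scale training run of the canonical architecture, shared
# by the delineation-recovery and end-to-end screening tests (training
# dominates the suite's runtime, so it happens once per session).
.shared_models <- new.env(parent = emptyenv())

canonical_trained_model <- function() {
  if (is.null(.shared_models$canonical)) {
    tw <- synth_training_windows(500L, seed = 1001L)
    m <- build_model(seed = 1L)
    cfg <- train_config(learning_rate = 1e-3, epochs = 6L,
                        batch_size = 16L, seed = 1L,
                        validation_fraction = 0)
    .shared_models$canonical <- train_delineator(m, tw$windows, cfg)
  }
  .shared_models$canonical
}
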