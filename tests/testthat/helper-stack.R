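# The full desk-scale stack (corpus + trained emulator), built once per
# test run and shared by the end-to-end tests.

acceptance_stack <- function() memo("acceptance_stack", {
  dataset <- build_training_set(4000, seed = 1)
  dataset <- train_val_split(dataset, 0.2, seed = 1)
  weights <- train_emulator(dataset, desk_training_config(seed = 1))
  list(dataset = dataset, weights = weights, log = attr(weights, "log"))
})
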