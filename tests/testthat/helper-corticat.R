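# shared fixtures: small parameter sets and quick experiment configs

# parameters with pooling disabled -- convenient for closed-form checks
params_nopool <- function(...) {
  model_params(pool_l2 = pool_spec("none", gain = 0),
               pool_l3 = pool_spec("none", gain = 0), ...)
}

# a short, cheap training run (random faces, default dynamics)
quick_fit <- function(n_steps = 12, seed = 42, n_cells = 4, ...) {
  run_experiment(training_config(categories = "A", schedule = "random",
                                 n_cells = n_cells, n_steps = n_steps,
                                 seed = seed, ...))
}

expect_same_matrix <- function(a, b) {
  expect_identical(dim(a), dim(b))
  expect_identical(as.vector(a), as.vector(b))
}
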