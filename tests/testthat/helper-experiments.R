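# Full-scale study-condition runs shared by several accuracy tests
# (computed once per test session).

default_half_x_experiment <- function() cached("half_x_experiment", {
  run_imputation_experiment(config = sim_config(seed = 1L), n_targets = 20L,
                            coverage = 0.5, seed = 1L)
})
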