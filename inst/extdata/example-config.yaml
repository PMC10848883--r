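# Example experiment configuration: two scenarios at a reduced grid.
# Run with:
#   cfg <- read_experiment_config(system.file("extdata", "example-config.yaml",
#                                             package = "finlife"))
#   run_experiment(cfg, out_dir = "results")
grid:
  n_lengths: 100
  n_stores: 26
  n_alloc: 11
params:
  spectrum:
    h: 8.0
scenarios:
  - name: temperate_baseline
    environment:
      type: constant
      tau_C: 16.85
      kappa: 1.0
  - name: seasonal_spawner
    environment:
      type: seasonal
      winter_tau_C: 11.85
      summer_tau_C: 20.85
      winter_kappa: 3.0
      summer_kappa: 1.0
      warm_months: 3
    overrides:
      spectrum:
        h: 12.0
seed: 1
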