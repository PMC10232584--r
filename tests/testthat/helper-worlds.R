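# small simulation worlds shared across test files

tiny_config <- function(seed = 1, ...) {
  simulation_config(n_participants = 3, n_epochs_per_condition = 4,
                    n_events = 5, random_seed = seed, ...)
}

# single-pair coupling world with quiet background, for envelope-recovery
# oracles
coupled_config <- function(rho, seed = 7, n_epochs = 45, ...) {
  simulation_config(n_participants = 1, n_epochs_per_condition = n_epochs,
                    random_seed = seed,
                    baseline_coupling = c("precuneus_L|precuneus_R.alpha" = rho),
                    coupling_effects = c("precuneus_L|precuneus_R.alpha" = 0),
                    band_effects = c("precuneus_R.alpha" = 0),
                    bg_sd = 1, sensor_noise_sd = 0.1, ...)
}

roi_signals <- function(sim, key, region) {
  es <- sim$roi_sets[[key]]
  es$data[, match(region, es$channel_labels), , drop = TRUE]
}
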