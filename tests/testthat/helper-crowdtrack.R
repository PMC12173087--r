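# Shared fixtures: built in code, small enough for fast tests.

default_cfg <- function(...) paradigm_config(...)

# An observer with no noise, no latency and no crowding penalty: the
# response should reproduce the stimulus exactly outside reacquisition.
ideal_observer <- function(...) {
  args <- list(motor_latency_ms = 0, tracking_time_constant_ms = 0,
               baseline_noise_sd_deg = 0, crowding_slope_deg_per_deg = 0,
               recovery_rate_flanked_per_s = 1e6,
               recovery_rate_isolated_per_s = 1e6,
               noise_time_constant_ms = 0)
  args[names(list(...))] <- list(...)
  do.call(observer_config, args)
}

# Small two-observer dataset reused across I/O and pipeline tests.
tiny_dataset <- function(seed = 42) {
  observers <- list(observer_config(seed = 1), observer_config(seed = 2))
  generate_dataset(paradigm_config(), observers, n_runs = 1, seed = seed)
}
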