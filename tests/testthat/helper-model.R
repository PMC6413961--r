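# Shared fixtures: small stimuli and a cached default model configuration.
# Simulations in unit tests use shortened stimuli so the whole suite stays
# fast; the acceptance tests use the full study conditions.

default_grid <- lag_grid()

# build connectivity once per test run (it is deterministic)
.test_env <- new.env()
test_config <- function(params = cortical_params(), sacf = sacf_params()) {
  if (is.null(.test_env$conn)) {
    .test_env$conn <- build_connectivity(default_grid, cortical_params())
  }
  model_config(params = params, sacf = sacf, grid = default_grid,
               conn = .test_env$conn)
}

# short noise-preceded IRN sequence
short_irn_sequence <- function(T_s = 8e-3, iterations = 16L,
                               band = c(800, 3200), noise_dur = 0.4,
                               pitch_dur = 0.5, seed = 42L, fade = 10e-3) {
  spec <- stimulus_spec(kind = "irn", delay_T0 = T_s,
                        iterations = iterations, band_low = band[1],
                        band_high = band[2], duration = pitch_dur,
                        seed = seed)
  irn <- generate_irn(spec)
  make_noise_pitch_sequence(noise_dur, irn, fade = fade, band_low = band[1],
                            band_high = band[2], level = 80,
                            noise_seed = seed + 1L)
}

# cache a full short pipeline run shared across test files within a file
cached_pitch_run <- function() {
  if (is.null(.test_env$run)) {
    wave <- short_irn_sequence()
    .test_env$run <- run_pitch_model(wave, test_config(), mode = "single",
                                     seed = 7L)
  }
  .test_env$run
}
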