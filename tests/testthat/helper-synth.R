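# Small fixtures shared across test files; everything is generated in code.

# 20-trial protocol over the full 10-tone grid (2 repeats each)
tiny_protocol <- function(seed = 2, repeats = 2) {
  make_tone_protocol(2, 45, 2, repeats = repeats, seed = seed)
}

# Noiseless 4-neuron session with known best frequencies
tiny_experiment <- function(seed = 3, trial_noise_sd = 0, rho = 0,
                            gain = c(Pre = 1)) {
  proto <- tiny_protocol()
  cfg <- synth_neural_config(
    n_neurons = 4, bf_khz = c(8, 16, 4, 32), base_amplitude = rep(0.4, 4),
    condition_gain = gain, trial_noise_sd = trial_noise_sd,
    shared_noise_rho = rho, seed = seed
  )
  list(proto = proto, cfg = cfg,
       exper = simulate_experiment(cfg, proto, 1L))
}

# Movement trace object wrapped around a given envelope (for template tests)
fake_movement_trace <- function(M, fps = 1) {
  structure(list(M = M, D = M, fps = fps, t_s = seq_along(M) / fps,
                 duration_s = length(M) / fps),
            class = "movement_trace")
}

expect_all_equal <- function(x, y, tol = 1e-12) {
  expect_lt(max(abs(x - y)), tol)
}
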