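# Shared fixtures, computed lazily and cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the standard biased two-minima motor: wells at 45 deg to the field axis
ratchet_landscape <- function(offset = pi / 4) {
  rotor_landscape(2, minima_offset = offset)
}

square_drive <- function(duration, period = 0.2) {
  field_protocol(data.frame(duration = duration, waveform = "square",
                            period = period))
}

ratchet_config <- function(seed, theta_init = pi / 4, ...) {
  sim_config(seed = seed, theta_init = theta_init, ...)
}

# one 64 s (320 field cycles) driven trajectory, reused across files
ratchet_traj <- function(seed = 1) {
  fixture(paste0("ratchet_traj_", seed), simulate_motor(
    ratchet_landscape(), square_drive(64), ratchet_config(seed)
  ))
}

# long synthetic drift-diffusion track with known omega and D (rad units),
# sampled at 250 frames/s so lags at multiples of the 0.2 s drive line up
dd_reference <- function() {
  fixture("dd_reference", list(
    omega = 1, D = 0.5,
    traj = simulate_drift_diffusion(omega = 1, D = 0.5, duration = 4000,
                                    dt = 4e-3, seed = 42)
  ))
}
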