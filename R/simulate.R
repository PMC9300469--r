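#' Simulation settings
#'
#' Integrator settings for the overdamped Langevin equation
#' `lambda * dtheta/dt = -dU/dtheta + eta(t)` with white noise satisfying the
#' fluctuation-dissipation relation `<eta(t) eta(t')> = 2 kT lambda delta(t - t')`.
#'
#' @param damping rotational damping `lambda` (k_B T s / rad^2).
#' @param thermal_energy thermal energy in k_B T units (default 1; set 0 for
#'   the deterministic gradient-descent limit).
#' @param dt integration step (s). Checked against the stiffness of the
#'   landscape at simulation time: `dt < 0.1 * lambda / max|U''|`.
#' @param record_stride record every `record_stride`-th step (integer >= 1).
#' @param seed RNG seed used by [simulate_motor()] (integer).
#' @param theta_init initial rotor angle (rad).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(damping = 0.1, thermal_energy = 1, dt = 2e-5,
                       record_stride = 200L, seed = 1L, theta_init = 0) {
  stopifnot(damping > 0, thermal_energy >= 0, dt > 0, record_stride >= 1)
  structure(
    list(damping = damping, thermal_energy = thermal_energy, dt = dt,
         record_stride = as.integer(record_stride), seed = as.integer(seed),
         theta_init = theta_init),
    class = "sim_config"
  )
}

# conservative curvature bound: well curvature 2bc at the well centre plus the
# field term's peak curvature (4a/pi) * max amplitude scale, plus the spring
.stability_check <- function(landscape, protocol, config, kappa = 0) {
  max_amp <- max(abs(protocol$segments$amplitude_scale))
  curv <- 2 * landscape$well_depth * landscape$well_inverse_width +
    (4 * landscape$field_strength / pi) * max_amp + kappa
  if (curv > 0 && config$dt >= 0.1 * config$damping / curv) {
    stop(sprintf(
      "dt = %g too large for landscape stiffness; need dt < %g",
      config$dt, 0.1 * config$damping / curv
    ))
  }
  invisible(TRUE)
}

.new_trajectory <- function(times, theta, metadata) {
  structure(list(times = times, theta = theta, metadata = metadata),
            class = "angular_trajectory")
}

#' @export
print.angular_trajectory <- function(x, ...) {
  cat(sprintf(
    "Angular trajectory: %d samples over %.3g s (dt = %.3g s), net displacement %.1f deg\n",
    length(x$times), max(x$times), x$times[2] - x$times[1],
    rad2deg(x$theta[length(x$theta)] - x$theta[1])
  ))
  invisible(x)
}

#' Simulate the rotor by overdamped Langevin dynamics
#'
#' Integrates the rotor angle with the Euler-Maruyama scheme
#' `theta_{k+1} = theta_k - (dU/dtheta / lambda) dt + sqrt(2 kT dt / lambda) xi_k`
#' in the time-dependent landscape defined by `landscape` and `protocol`.
#' The returned angle is cumulative (never wrapped), so full rotations
#' accumulate. With the same seed, configuration, landscape and protocol the
#' trajectory is bit-identical across runs.
#'
#' @param landscape a [rotor_landscape()].
#' @param protocol a [field_protocol()].
#' @param config a [sim_config()].
#' @param spring optional [spring_config()] adding a linear torsional
#'   restoring torque `-kappa * (theta - anchor_angle)`.
#' @return an `angular_trajectory` with uniformly spaced `times` (s),
#'   unwrapped `theta` (rad) and metadata (config, protocol, seed).
#' @examples
#' ls2 <- rotor_landscape(2, minima_offset = pi / 4)
#' pr <- field_protocol(data.frame(duration = 2, waveform = "square", period = 0.2))
#' tr <- simulate_motor(ls2, pr, sim_config(seed = 7))
#' @export
simulate_motor <- function(landscape, protocol, config, spring = NULL) {
  stopifnot(inherits(landscape, "rotor_landscape"),
            inherits(protocol, "field_protocol"),
            inherits(config, "sim_config"))
  kappa <- 0
  anchor <- 0
  engaged <- FALSE
  if (!is.null(spring)) {
    stopifnot(inherits(spring, "spring_config"))
    if (spring$engaged && spring$stiffness > 0) {
      kappa <- spring$stiffness
      anchor <- spring$anchor_angle
      engaged <- TRUE
    }
  }
  .stability_check(landscape, protocol, config, kappa)
  n_steps <- floor(protocol$duration / config$dt + 1e-9)
  seg <- protocol$segments
  wave_code <- .waveform_codes[seg$waveform]
  set.seed(config$seed)
  theta <- simulate_em_cpp(
    seg$t_start, seg$t_end, as.integer(wave_code), seg$period,
    seg$amplitude_scale, seg$axis_angle, as.integer(seg$fourier_order),
    landscape$field_strength, landscape$well_depth,
    landscape$well_inverse_width, landscape$minima_offset,
    landscape$minima_spacing, landscape$n_images,
    config$damping, config$thermal_energy, config$dt, config$record_stride,
    config$theta_init, as.integer(n_steps), kappa, anchor
  )
  times <- seq(0, by = config$dt * config$record_stride, length.out = length(theta))
  .new_trajectory(times, theta, list(
    landscape = landscape, protocol = protocol, config = config,
    seed = config$seed, ground_truth = TRUE,
    spring = if (engaged) spring else NULL
  ))
}

#' Torsional spring settings
#'
#' A linear torsional spring at the rotor pivot, modelling a single-stranded
#' DNA loop that winds up as the motor turns. While engaged it contributes a
#' restoring torque `-stiffness * (theta - anchor_angle)`; a wound-up spring
#' stalls the motor and, once the drive stops, unwinds it in the opposite
#' direction.
#'
#' @param stiffness spring constant kappa (k_B T / rad^2), `>= 0`.
#' @param anchor_angle relaxed angle of the spring (rad).
#' @param engaged logical; an unengaged spring exerts no torque.
#' @return an object of class `spring_config`.
#' @export
spring_config <- function(stiffness = 0.5, anchor_angle = 0, engaged = TRUE) {
  stopifnot(stiffness >= 0)
  structure(list(stiffness = stiffness, anchor_angle = anchor_angle,
                 engaged = isTRUE(engaged)),
            class = "spring_config")
}

#' Simulate a spring-loaded motor
#'
#' Convenience wrapper around [simulate_motor()] with an engaged torsional
#' spring. A typical wind-up experiment uses a three-phase protocol (field
#' off, field on, field off): the motor winds the spring until the spring
#' torque balances the motor torque (stall), then unwinds in the opposite
#' direction once the drive stops.
#'
#' @inheritParams simulate_motor
#' @export
simulate_with_spring <- function(landscape, protocol, config, spring) {
  simulate_motor(landscape, protocol, config, spring = spring)
}

#' Map drive voltage to field amplitude scale
#'
#' Linear mapping of the applied peak voltage to the dimensionless amplitude
#' multiplier applied to the landscape's field coupling; `V_ref` volts map to
#' a scale of 1.
#'
#' @param volts applied voltage, `>= 0` (vectorized).
#' @param v_ref reference voltage (default 20 V).
#' @return dimensionless amplitude scale `volts / v_ref`.
#' @export
voltage_to_amplitude <- function(volts, v_ref = 20) {
  if (any(volts < 0)) stop("volts must be >= 0")
  if (v_ref <= 0) stop("v_ref must be > 0")
  volts / v_ref
}

#' Sweep protocol builders
#'
#' Construct [field_protocol()] objects for the standard single-motor
#' experiments: stepwise rotation of the AC field axis, a drive-frequency
#' sweep, a drive-amplitude (voltage) sweep, a DC segment, or field off.
#'
#' @param step_deg axis increment per segment (degrees).
#' @param dwell_s time spent at each axis angle / frequency / voltage (s).
#' @param range_deg total axis range swept (degrees; end-exclusive).
#' @param period drive period within each segment (s).
#' @param amplitude_scale drive amplitude multiplier.
#' @param freqs_hz drive frequencies visited, in order (Hz).
#' @param volts voltages visited, in order.
#' @param v_ref reference voltage mapping to amplitude scale 1.
#' @param duration segment duration for the single-segment protocols (s).
#' @return a `field_protocol`.
#' @name sweep_protocols
NULL

#' @rdname sweep_protocols
#' @export
axis_sweep_protocol <- function(step_deg = 5, dwell_s = 1.6, range_deg = 180,
                                period = 0.2, amplitude_scale = 1) {
  if (step_deg <= 0 || step_deg > range_deg) stop("empty axis sweep")
  axes <- seq(0, range_deg - step_deg, by = step_deg)
  field_protocol(data.frame(
    duration = dwell_s, waveform = "square", period = period,
    amplitude_scale = amplitude_scale, axis_angle = deg2rad(axes)
  ))
}

#' @rdname sweep_protocols
#' @export
frequency_sweep_protocol <- function(freqs_hz = c(100, 10, 5, 1), dwell_s = 10,
                                     amplitude_scale = 1) {
  if (!length(freqs_hz)) stop("empty frequency sweep")
  if (any(freqs_hz <= 0)) stop("frequencies must be > 0")
  field_protocol(data.frame(
    duration = dwell_s, waveform = "square", period = 1 / freqs_hz,
    amplitude_scale = amplitude_scale
  ))
}

#' @rdname sweep_protocols
#' @export
amplitude_sweep_protocol <- function(volts = seq(0, 60, by = 10), v_ref = 20,
                                     dwell_s = 10, period = 0.2) {
  if (!length(volts)) stop("empty amplitude sweep")
  scale <- voltage_to_amplitude(volts, v_ref)
  wf <- ifelse(scale == 0, "off", "square")
  field_protocol(data.frame(
    duration = dwell_s, waveform = wf, period = period, amplitude_scale = scale
  ))
}

#' @rdname sweep_protocols
#' @export
dc_protocol <- function(duration = 10, amplitude_scale = 1) {
  field_protocol(data.frame(duration = duration, waveform = "dc",
                            amplitude_scale = amplitude_scale))
}

#' @rdname sweep_protocols
#' @export
off_protocol <- function(duration = 10) {
  field_protocol(data.frame(duration = duration, waveform = "off"))
}

#' Simulate a sweep experiment
#'
#' Builds the requested sweep protocol and runs [simulate_motor()]; segment
#' boundaries and per-segment labels (axis angle, frequency, voltage) are kept
#' in the trajectory metadata for per-segment analysis.
#'
#' @param landscape a [rotor_landscape()].
#' @param sweep one of the protocols from [sweep_protocols] (or any
#'   `field_protocol`).
#' @param config a [sim_config()].
#' @return an `angular_trajectory`.
#' @export
simulate_protocol <- function(landscape, sweep, config) {
  stopifnot(inherits(sweep, "field_protocol"))
  tr <- simulate_motor(landscape, sweep, config)
  tr$metadata$segments <- sweep$segments
  tr
}

#' Synthetic drift-diffusion trajectory
#'
#' Generates an angular random walk with exact Gaussian increments
#' `dtheta ~ N(omega * dt, 2 D dt)`. This is the closed-form reference
#' process for the irreversibility analysis: its transition density is
#' Gaussian, so the entropy-production slope is exactly `omega / D`.
#'
#' @param omega drift velocity (rad/s).
#' @param D diffusion coefficient (rad^2/s).
#' @param duration total time (s).
#' @param dt sampling interval (s).
#' @param seed RNG seed.
#' @param theta_init initial angle (rad).
#' @return an `angular_trajectory`.
#' @export
simulate_drift_diffusion <- function(omega, D, duration, dt = 4e-3,
                                     seed = 1L, theta_init = 0) {
  stopifnot(D >= 0, duration > 0, dt > 0)
  n <- floor(duration / dt)
  set.seed(seed)
  inc <- rnorm(n, mean = omega * dt, sd = sqrt(2 * D * dt))
  theta <- c(theta_init, theta_init + cumsum(inc))
  .new_trajectory(seq(0, by = dt, length.out = n + 1), theta,
                  list(omega = omega, D = D, seed = seed, ground_truth = TRUE))
}
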