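make_tips <- function(x, y, fps = 250, center = c(0, 0)) {
  structure(list(
    frames = data.frame(frame = seq_along(x) - 1L,
                        time_s = (seq_along(x) - 1L) / fps,
                        x_nm = x, y_nm = y),
    center_x_nm = center[1], center_y_nm = center[2],
    frame_rate_hz = fps, rotor_radius_nm = NA, localization_sigma_nm = NA
  ), class = "tip_positions")
}

make_traj <- function(theta, dt = 4e-3) {
  structure(list(times = seq(0, by = dt, length.out = length(theta)),
                 theta = theta, metadata = list()),
            class = "angular_trajectory")
}

test_that("angles follow the atan2 convention, CCW positive", {
  tp <- make_tips(c(275, 0, -275), c(0, 275, 0))
  expect_equal(angles_from_positions(tp), c(0, pi / 2, pi))
  bad <- make_tips(c(275, 0), c(0, 0))
  expect_error(angles_from_positions(bad), "frame 1")
})

test_that("unwrapping uses the shortest arc and preserves the start", {
  w <- deg <- c(350, 10) * pi / 180
  u <- unwrap_angles(w)
  expect_equal(u[2] - u[1], 20 * pi / 180)
  expect_equal(u[1], w[1])
  expect_equal(unwrap_angles(rep(1.2, 5)), rep(1.2, 5))
  # a jump of exactly half a turn resolves toward +180
  u2 <- unwrap_angles(c(0, pi))
  expect_equal(u2[2], pi)
  # faithful whenever per-frame steps stay below half a turn
  tr <- ratchet_traj(1)
  if (max(abs(diff(tr$theta))) < pi) {
    wrapped <- atan2(sin(tr$theta), cos(tr$theta))
    rec <- unwrap_angles(wrapped)
    expect_lt(max(abs(rec - (tr$theta - tr$theta[1] + rec[1]))), 1e-9)
  }
})

test_that("endpoint angular velocity matches its definition", {
  th <- (90 * pi / 180) * seq(0, 4, by = 4e-3)
  tr <- make_traj(th)
  expect_equal(angular_velocity(tr), 90, tolerance = 1e-9)
  # time reversal flips the sign
  trr <- make_traj(rev(th))
  expect_equal(angular_velocity(trr), -90, tolerance = 1e-9)
  # 250 turns per minute is 1500 deg/s
  th2 <- (250 * 2 * pi / 60) * seq(0, 1, by = 4e-3)
  expect_equal(angular_velocity(make_traj(th2)), 1500, tolerance = 1e-9)
  expect_error(angular_velocity(tr, c(2, 2.0001)), "fewer than two")
})

test_that("angular velocity is additive with duration weights", {
  tr <- ratchet_traj(1)
  w_all <- angular_velocity(tr, c(0, 40))
  w1 <- angular_velocity(tr, c(0, 15))
  w2 <- angular_velocity(tr, c(15, 40))
  expect_equal(w_all, (15 * w1 + 25 * w2) / 40, tolerance = 1e-9)
})

test_that("turns per field cycle follows the definition and flags DC", {
  expect_equal(turns_per_cycle(360, 5), 0.2)
  expect_true(is.na(turns_per_cycle(100, NA)))
  expect_true(is.na(turns_per_cycle(100, 0)))
})

test_that("speed histograms report the CW/CCW split", {
  h <- speed_histogram(c(-10, 20, 30), bin_width = 30)
  expect_equal(sum(h$counts), 3)
  expect_equal(h$frac_ccw, 2 / 3)
  h1 <- speed_histogram(5, bin_width = 10)
  expect_equal(sum(h1$counts > 0), 1)
  expect_error(speed_histogram(numeric(0)), "no speeds")
})

test_that("motors with random orientations split evenly between CW and CCW", {
  set.seed(10)
  offs <- runif(16, 0, 2 * pi)
  om <- vapply(seq_along(offs), function(i) {
    angular_velocity(simulate_motor(ratchet_landscape(offs[i]),
                                    square_drive(20),
                                    ratchet_config(i, theta_init = offs[i])))
  }, numeric(1))
  h <- speed_histogram(om)
  n_cw <- round(h$frac_cw * h$n)
  # binomial 3 sigma around an even split
  expect_lt(abs(n_cw - h$n / 2), 3 * sqrt(h$n) / 2)
})

test_that("sinusoid fit identifies amplitude and phase exactly on clean data", {
  ax <- seq(0, 175, by = 5)
  om <- 120 * sin(2 * (ax - 30) * pi / 180) + 15
  fit <- speed_vs_axis(axis_deg = ax, omega_deg_s = om)
  expect_equal(fit$amplitude, 120, tolerance = 1e-6)
  d_phase <- (fit$phase_deg - 30) %% 180
  expect_lt(min(d_phase, 180 - d_phase), 1e-6)
  expect_equal(fit$offset, 15, tolerance = 1e-6)
  expect_gt(fit$r_squared, 0.999)
  expect_error(speed_vs_axis(axis_deg = c(0, 10, 20), omega_deg_s = 1:3),
               "at least 4")
})

test_that("axis sweeps of a biased motor show a significant sinusoidal response", {
  tr <- fixture("axis_sweep_1", simulate_protocol(
    ratchet_landscape(), axis_sweep_protocol(), ratchet_config(1)
  ))
  fit <- speed_vs_axis(tr)
  expect_gt(fit$amplitude, 0)
  expect_lt(fit$p_value, 0.01)
})

test_that("phase correction aligns motors with different orientations", {
  mean_speeds <- function(offset, seeds) {
    rowMeans(vapply(seeds, function(s) {
      segment_speeds(simulate_protocol(
        ratchet_landscape(offset), axis_sweep_protocol(),
        ratchet_config(s, theta_init = offset)
      ))$omega_deg_s
    }, numeric(36)))
  }
  ax <- seq(0, 175, by = 5)
  omA <- mean_speeds(pi / 4, 1:16)
  omB <- mean_speeds(pi / 4 + pi / 3, 21:36)
  fitA <- speed_vs_axis(axis_deg = ax, omega_deg_s = omA)
  fitB <- speed_vs_axis(axis_deg = ax, omega_deg_s = omB)
  shift <- function(om, phase_deg) {
    k <- round((phase_deg %% 180) / 5)
    if (k == 0) om else c(om[-seq_len(k)], om[seq_len(k)])
  }
  r <- cor(shift(omA, fitA$phase_deg), shift(omB, fitB$phase_deg))
  expect_gt(r, 0.8)
})

test_that("dwell detection counts the preferred rotor positions", {
  # six shallow wells that mix within the run
  ls6 <- rotor_landscape(6, well_depth = 2.5, well_inverse_width = 10,
                         field_strength = 0)
  tr6 <- simulate_motor(ls6, off_protocol(200),
                        sim_config(dt = 1e-4, record_stride = 10, seed = 4))
  pk6 <- dwell_positions(tr6)
  expect_equal(nrow(pk6), 6)
  well_centers <- (seq(0, 300, by = 60)) %% 360
  for (a in pk6$angle_deg) {
    d <- min(abs(((a - well_centers + 180) %% 360) - 180))
    expect_lt(d, 5)
  }
  # two wells
  ls2 <- rotor_landscape(2, well_depth = 2.5, well_inverse_width = 5,
                         field_strength = 0)
  tr2 <- simulate_motor(ls2, off_protocol(200),
                        sim_config(dt = 1e-4, record_stride = 10, seed = 5))
  expect_equal(nrow(dwell_positions(tr2)), 2)
  # free diffusion has no dwell structure
  flat <- rotor_landscape(1, well_depth = 0, field_strength = 0)
  trf <- simulate_motor(flat, off_protocol(1200),
                        sim_config(dt = 1e-3, record_stride = 1, seed = 6))
  expect_equal(nrow(dwell_positions(trf)), 0)
})

test_that("segment speeds carry drive descriptors and bias efficiency", {
  tr <- fixture("freq_sweep_1", simulate_protocol(
    ratchet_landscape(), frequency_sweep_protocol(c(10, 5), dwell_s = 4),
    ratchet_config(2)
  ))
  ss <- segment_speeds(tr)
  expect_equal(ss$freq_hz, c(10, 5))
  expect_equal(ss$turns_per_cycle, ss$omega_deg_s / (360 * ss$freq_hz))
})
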