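test_that("deterministic limit stays at a well centre with the field off", {
  ls2 <- ratchet_landscape()
  tr <- simulate_motor(ls2, off_protocol(1),
                       sim_config(thermal_energy = 0, seed = 1,
                                  theta_init = pi / 4))
  expect_lt(max(abs(tr$theta - pi / 4)), 1e-9)
})

test_that("fixed seed gives bit-identical trajectories; null spring is inert", {
  ls2 <- ratchet_landscape()
  pr <- square_drive(2)
  t1 <- simulate_motor(ls2, pr, ratchet_config(7))
  t2 <- simulate_motor(ls2, pr, ratchet_config(7))
  expect_identical(t1$theta, t2$theta)
  t3 <- simulate_motor(ls2, pr, ratchet_config(8))
  expect_false(identical(t1$theta, t3$theta))
  # kappa = 0 spring leaves the path bit-identical
  t4 <- simulate_with_spring(ls2, pr, ratchet_config(7),
                             spring_config(stiffness = 0))
  expect_identical(t4$theta, t1$theta)
})

test_that("trajectory grid and stability validation behave as documented", {
  ls2 <- ratchet_landscape()
  tr <- simulate_motor(ls2, square_drive(2), ratchet_config(1))
  expect_equal(length(tr$theta), floor(2 / (2e-5 * 200)) + 1)
  expect_equal(diff(tr$times), rep(2e-5 * 200, length(tr$times) - 1))
  expect_true(all(is.finite(tr$theta)))
  expect_error(
    simulate_motor(ls2, square_drive(1), sim_config(dt = 1e-3)),
    "too large"
  )
})

test_that("free diffusion follows the fluctuation-dissipation relation", {
  flat <- rotor_landscape(1, well_depth = 0, field_strength = 0)
  lam <- 0.1
  # D = kT / lambda; estimate from endpoint displacements of replicate seeds
  Dhat <- vapply(1:50, function(s) {
    tr <- simulate_motor(flat, off_protocol(1),
                         sim_config(damping = lam, dt = 1e-3,
                                    record_stride = 10, seed = 100 + s))
    (tr$theta[length(tr$theta)] - tr$theta[1])^2 / (2 * 1)
  }, numeric(1))
  se <- sd(Dhat) / sqrt(length(Dhat))
  expect_lt(abs(mean(Dhat) - 1 / lam), 3 * se)
})

test_that("field-off sampling follows the Boltzmann distribution", {
  # shallow wells so the rotor crosses barriers and mixes within the run
  lsb <- rotor_landscape(2, well_depth = 2.5, well_inverse_width = 5,
                         field_strength = 0)
  tr <- simulate_motor(lsb, off_protocol(400),
                       sim_config(dt = 1e-4, record_stride = 10, seed = 3))
  sub <- tr$theta[seq(1, length(tr$theta), by = 2000)]  # ~2 s apart
  breaks <- seq(0, 2 * pi, length.out = 37)
  counts <- hist(sub %% (2 * pi), breaks = breaks, plot = FALSE)$counts
  thf <- seq(0, 2 * pi, length.out = 36001)
  dens <- exp(-intrinsic_potential(thf, lsb))
  pbin <- vapply(1:36, function(i) {
    sum(dens[thf >= breaks[i] & thf < breaks[i + 1]])
  }, numeric(1))
  p <- suppressWarnings(chisq.test(counts, p = pbin / sum(pbin))$p.value)
  expect_gt(p, 0.01)
})

test_that("45-degree motors drift, 0-degree motors do not", {
  pr <- square_drive(20)
  om45 <- vapply(1:10, function(s) {
    angular_velocity(simulate_motor(ratchet_landscape(), pr, ratchet_config(s)))
  }, numeric(1))
  om0 <- vapply(1:10, function(s) {
    angular_velocity(simulate_motor(ratchet_landscape(offset = 0), pr,
                                    ratchet_config(s, theta_init = 0)))
  }, numeric(1))
  expect_gt(abs(mean(om45)) / (sd(om45) / sqrt(10)), 3)
  expect_lt(abs(mean(om0)) / (sd(om0) / sqrt(10)), 3)
})

test_that("mirrored landscapes drift in opposite directions", {
  pr <- square_drive(20)
  omp <- vapply(1:10, function(s) {
    angular_velocity(simulate_motor(ratchet_landscape(pi / 4), pr,
                                    ratchet_config(s)))
  }, numeric(1))
  omm <- vapply(1:10, function(s) {
    angular_velocity(simulate_motor(ratchet_landscape(-pi / 4), pr,
                                    ratchet_config(20 + s, theta_init = -pi / 4)))
  }, numeric(1))
  se <- sqrt(var(omp) / 10 + var(omm) / 10)
  expect_lt(abs(mean(omp) + mean(omm)), 3 * se)
  expect_gt(mean(omp), 0)
  expect_lt(mean(omm), 0)
})

test_that("halving the time step leaves the mean drift unchanged", {
  pr <- square_drive(20)  # 100 field cycles
  om1 <- vapply(1:10, function(s) {
    angular_velocity(simulate_motor(ratchet_landscape(), pr, ratchet_config(s)))
  }, numeric(1))
  om2 <- vapply(1:10, function(s) {
    angular_velocity(simulate_motor(ratchet_landscape(), pr,
                                    ratchet_config(s, dt = 1e-5,
                                                   record_stride = 400)))
  }, numeric(1))
  se <- sqrt(var(om1) / 10 + var(om2) / 10)
  expect_lt(abs(mean(om1) - mean(om2)), se)
})

test_that("sweep protocols build the advertised segment schedules", {
  ax <- axis_sweep_protocol()
  expect_equal(nrow(ax$segments), 36)
  expect_equal(ax$segments$duration, rep(1.6, 36))
  expect_equal(ax$segments$axis_angle, seq(0, 175, by = 5) * pi / 180)
  fs <- frequency_sweep_protocol(c(100, 10, 5, 1), dwell_s = 2)
  expect_equal(fs$segments$period, 1 / c(100, 10, 5, 1))
  am <- amplitude_sweep_protocol(volts = c(0, 20, 60), v_ref = 20, dwell_s = 1)
  expect_equal(am$segments$amplitude_scale, c(0, 1, 3))
  expect_equal(am$segments$waveform, c("off", "square", "square"))
  expect_error(frequency_sweep_protocol(numeric(0)), "empty")
  expect_error(axis_sweep_protocol(step_deg = 200), "empty")
  expect_equal(voltage_to_amplitude(20), 1)
  expect_equal(voltage_to_amplitude(0), 0)
  expect_equal(voltage_to_amplitude(60, 20), 3)
  expect_error(voltage_to_amplitude(-1))
})

test_that("DC drive gives no steady drift once the initial transient passed", {
  om <- vapply(1:10, function(s) {
    angular_velocity(simulate_motor(ratchet_landscape(), dc_protocol(20),
                                    ratchet_config(s)), c(5, 20))
  }, numeric(1))
  expect_lt(abs(mean(om)) / (sd(om) / sqrt(10)), 3)
})

test_that("angular speed peaks at an interior drive frequency", {
  # scan the drive period across three decades; the speed maximum must not
  # sit on either end (bias vanishes both at high frequency and toward DC)
  periods <- c(0.01, 0.1, 1, 10)
  speed <- vapply(periods, function(T_f) {
    dur <- max(20, 10 * T_f)
    om <- vapply(1:4, function(s) {
      angular_velocity(simulate_motor(ratchet_landscape(),
                                      square_drive(dur, T_f),
                                      ratchet_config(s)), c(T_f, dur))
    }, numeric(1))
    abs(mean(om))
  }, numeric(1))
  expect_gt(which.max(speed), 1)
  expect_lt(which.max(speed), length(periods))
})

test_that("spring motor winds up, stalls, and reverses when the field stops", {
  ls2 <- ratchet_landscape()
  pr3 <- field_protocol(data.frame(duration = c(5, 20, 20),
                                   waveform = c("off", "square", "off"),
                                   period = 0.2))
  sp <- spring_config(stiffness = 0.5, anchor_angle = pi / 4)
  res <- vapply(1:12, function(s) {
    tr <- simulate_with_spring(ls2, pr3, ratchet_config(s), sp)
    c(w2 = angular_velocity(tr, c(5, 25)),
      w3 = angular_velocity(tr, c(25, 45)),
      wind = max(abs(tr$theta - pi / 4)))
  }, numeric(3))
  # reversal in the large majority of runs
  expect_gte(mean(sign(res["w2", ]) != sign(res["w3", ])), 0.75)
  # stall: winding stays bounded well below the free-running displacement
  free_disp <- abs(mean(vapply(1:3, function(s) {
    tr <- simulate_motor(ls2, square_drive(20), ratchet_config(s))
    tr$theta[length(tr$theta)] - tr$theta[1]
  }, numeric(1))))
  expect_lt(max(res["wind", ]), 0.5 * free_disp)
})
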