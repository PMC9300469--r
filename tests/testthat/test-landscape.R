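test_that("square wave switches sign at half period and averages to zero", {
  T_f <- 0.2
  expect_equal(square_wave(0.1 * T_f, T_f), 1)
  expect_equal(square_wave(0.6 * T_f, T_f), -1)
  # zero mean on any uniform grid of even size over one period
  tgrid <- seq(0, T_f, length.out = 1001)[-1001]
  expect_equal(mean(square_wave(tgrid, T_f)), 0)
  # periodic
  set.seed(1)
  t <- runif(1000, 0, 50)
  expect_equal(square_wave(t + T_f, T_f), square_wave(t, T_f))
  expect_error(square_wave(1, 0), "positive")
})

test_that("smoothed square wave dialects behave as documented", {
  T_f <- 0.3
  t <- seq(0, 1, by = 0.01)
  expect_equal(smoothed_square_wave(t, T_f, 1, "printed"), sin(t / T_f))
  # independent partial-sum oracle for the standard dialect
  brute <- 0
  for (n in seq(1, 199, by = 2)) brute <- brute + sin(2 * pi * n * (T_f / 4) / T_f) / n
  brute <- brute * 4 / pi
  expect_equal(smoothed_square_wave(T_f / 4, T_f, 199, "standard"), brute)
  expect_lt(abs(smoothed_square_wave(T_f / 4, T_f, 199, "standard") - 1), 0.01)
  expect_equal(smoothed_square_wave(0, T_f, 50, "standard"), 0)
  expect_equal(smoothed_square_wave(0, T_f, 50, "printed"), 0)
  expect_error(smoothed_square_wave(0.1, T_f, 50, "sawtooth"))
})

test_that("intrinsic potential has correct minima, symmetry and periodicity", {
  # isolated single well: value at the centre is -b up to image-well tails
  ls1 <- rotor_landscape(1, well_depth = 5, well_inverse_width = 30,
                         minima_offset = 0.3)
  expect_equal(intrinsic_potential(0.3, ls1), -5, tolerance = 1e-12)
  # even symmetry about a well centre
  ls6 <- rotor_landscape(6, minima_offset = 0.5)
  set.seed(2)
  x <- runif(100, -4, 4)
  expect_equal(intrinsic_potential(0.5 + x, ls6),
               intrinsic_potential(0.5 - x, ls6))
  # minima sit at theta0 + k * spacing, found by numerical minimization
  for (k in 0:5) {
    ctr <- 0.5 + k * pi / 3
    opt <- optimize(function(th) intrinsic_potential(th, ls6),
                    interval = c(ctr - 0.4, ctr + 0.4), tol = 1e-10)
    expect_lt(abs(opt$minimum - ctr), 1e-6)
  }
  # 2*pi periodicity
  th <- runif(50, -10, 10)
  expect_lt(max(abs(intrinsic_potential(th + 2 * pi, ls6) -
                      intrinsic_potential(th, ls6))), 1e-10)
  # constructor enforces spacing = 2*pi / n and parameter domains
  expect_equal(rotor_landscape(5)$minima_spacing, 2 * pi / 5)
  expect_error(rotor_landscape(2, well_depth = -1))
  expect_error(rotor_landscape(2, well_inverse_width = 0))
})

test_that("total potential combines field and wells as specified", {
  ls2 <- ratchet_landscape()
  pr <- square_drive(10)
  # field term vanishes where cos(theta - axis) = 0, at any time
  for (t in c(0.03, 0.12, 3.17)) {
    expect_lt(abs(total_potential(pi / 2, t, ls2, pr) -
                    intrinsic_potential(pi / 2, ls2)), 1e-12)
  }
  # field contribution flips sign exactly between the two half-cycles
  th <- 0.7
  f1 <- total_potential(th, 0.05, ls2, pr) - intrinsic_potential(th, ls2)
  f2 <- total_potential(th, 0.15, ls2, pr) - intrinsic_potential(th, ls2)
  expect_equal(f1, -f2)
  expect_equal(f1, (4 * ls2$field_strength / pi) * cos(th))
  # 2*pi periodicity in angle
  set.seed(3)
  th <- runif(50, -5, 5); tt <- runif(50, 0, 10)
  expect_lt(max(abs(total_potential(th + 2 * pi, tt, ls2, pr) -
                      total_potential(th, tt, ls2, pr))), 1e-10)
  # mirror symmetry: negating both the offset and the angle leaves U unchanged
  lsm <- rotor_landscape(2, minima_offset = -pi / 4)
  expect_equal(total_potential(-th, tt, lsm, pr),
               total_potential(th, tt, ls2, pr))
  # zero time-averaged drive at fixed angle over one full period
  tq <- seq(0, 0.2, length.out = 2001)[-2001]
  drive <- total_potential(0.7, tq, ls2, pr) - intrinsic_potential(0.7, ls2)
  expect_lt(abs(mean(drive)), 1e-10)
  expect_error(total_potential(0, 11, ls2, pr), "duration")
})

test_that("analytic gradient matches finite differences and known zeros", {
  ls2 <- ratchet_landscape()
  pr <- square_drive(10)
  set.seed(4)
  th <- runif(100, -5, 5); tt <- runif(100, 0.001, 9.99)
  h <- 1e-6
  fd <- (total_potential(th + h, tt, ls2, pr) -
           total_potential(th - h, tt, ls2, pr)) / (2 * h)
  expect_lt(max(abs(fd - grad_potential(th, tt, ls2, pr))), 1e-5)
  # stationary at a well centre with the field off
  off <- off_protocol(1)
  expect_lt(abs(grad_potential(pi / 4, 0.5, ls2, off)), 1e-10)
  # field-term gradient vanishes at the axis (cos extremum): isolate with b = 0
  flat <- rotor_landscape(2, well_depth = 0, field_strength = 8)
  expect_lt(abs(grad_potential(0, 0.05, flat, pr)), 1e-12)
})

test_that("compiled gradient agrees with the R reference", {
  ls2 <- rotor_landscape(2, minima_offset = 0.4)
  pr <- square_drive(10)
  set.seed(5)
  th <- runif(50, -8, 8); tt <- runif(50, 0, 10)
  f <- field_at(pr, tt)
  g_cpp <- vapply(seq_along(th), function(i) {
    rotaratchet:::grad_potential_cpp(th[i], f$E[i], f$axis_angle[i],
                                     f$amplitude_scale[i],
                                     ls2$field_strength, ls2$well_depth,
                                     ls2$well_inverse_width, ls2$minima_offset,
                                     ls2$minima_spacing, ls2$n_images)
  }, numeric(1))
  expect_equal(g_cpp, grad_potential(th, tt, ls2, pr), tolerance = 1e-12)
})

test_that("field protocols validate segments and report drive state", {
  expect_error(field_protocol(data.frame(duration = 1, waveform = "triangle")),
               "unknown waveform")
  expect_error(field_protocol(data.frame(duration = -1, waveform = "off")),
               "> 0")
  pr <- field_protocol(data.frame(
    duration = c(2, 3), waveform = c("off", "square"), period = c(NA, 0.5)
  ))
  expect_equal(pr$duration, 5)
  expect_equal(pr$segments$t_start, c(0, 2))
  f <- field_at(pr, c(1, 2.1, 2.3))
  expect_equal(f$E, c(0, 1, -1))
  expect_error(field_at(pr, 5.5), "duration")
})
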