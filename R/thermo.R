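#' Jump pairs at a multiple of the field period
#'
#' From a uniformly sampled cumulative trajectory, collects all overlapping
#' pairs `(theta_i mod 360, theta_{i+L} - theta_i)` at lag `n * T_field`.
#' The starting angle is wrapped to `[0, 360)` degrees; the jump is left
#' unreduced, so full rotations count.
#'
#' @param traj an `angular_trajectory`.
#' @param n lag as an integer multiple of the field period.
#' @param T_field field period (s); `n * T_field` must be an integer multiple
#'   of the sampling interval.
#' @return an object of class `jump_distribution`: `theta0_deg`, `dtheta_deg`,
#'   `n`, `T_field`, `lag_s`, `lag_frames`.
#' @export
jump_pairs <- function(traj, n, T_field) {
  tt <- .traj_theta(traj)
  dt <- tt$times[2] - tt$times[1]
  lag_frames <- n * T_field / dt
  if (abs(lag_frames - round(lag_frames)) > 1e-6) {
    stop("lag n * T_field is not a multiple of the sampling interval")
  }
  lag_frames <- as.integer(round(lag_frames))
  N <- length(tt$theta)
  if (lag_frames >= N) stop("lag exceeds the trajectory span")
  theta_deg <- rad2deg(tt$theta)
  i <- seq_len(N - lag_frames)
  structure(
    list(theta0_deg = theta_deg[i] %% 360,
         dtheta_deg = theta_deg[i + lag_frames] - theta_deg[i],
         n = n, T_field = T_field, lag_s = n * T_field,
         lag_frames = lag_frames),
    class = "jump_distribution"
  )
}

#' Transition density estimate for jump pairs
#'
#' Bivariate kernel density estimate of `p(theta0 mod 360, dtheta)` with
#' Gaussian product kernels. Periodicity in the starting angle is enforced by
#' replicating the sample at `theta0 +/- 360`; bandwidths default to
#' Silverman's rule per dimension. For large samples the pairs are pre-binned
#' on a fine grid (bin width one fifth of the bandwidth) before evaluation,
#' which changes the density by far less than the kernel scale.
#'
#' @param jumps a [jump_pairs()] result.
#' @param bw optional length-2 bandwidth override `c(bw_theta0, bw_dtheta)`
#'   in degrees.
#' @param bin_threshold sample size above which pre-binning is used.
#' @return an object of class `transition_density`, callable through
#'   [density_at()].
#' @export
transition_density <- function(jumps, bw = NULL, bin_threshold = 5e4) {
  stopifnot(inherits(jumps, "jump_distribution"))
  x <- jumps$theta0_deg
  y <- jumps$dtheta_deg
  if (length(x) < 100) stop("need at least 100 jump pairs")
  if (sd(x) == 0 && sd(y) == 0) stop("degenerate jump distribution (all pairs identical)")
  if (is.null(bw)) {
    bw <- c(bw.nrd0(x), bw.nrd0(y))
    bw[bw <= 0] <- 1e-6
  }
  n_orig <- length(x)
  if (n_orig > bin_threshold) {
    hx <- bw[1] / 5
    hy <- bw[2] / 5
    ix <- as.integer(round(x / hx))
    iy <- as.integer(round(y / hy))
    key <- as.numeric(iy - min(iy)) * (diff(range(ix)) + 1) + (ix - min(ix))
    first <- which(!duplicated(key))
    idx <- match(key, key[first])
    w <- tabulate(idx, nbins = length(first))
    x <- ix[first] * hx
    y <- iy[first] * hy
  } else {
    w <- rep(1, n_orig)
  }
  # periodic replication of theta0
  x3 <- c(x - 360, x, x + 360)
  y3 <- rep(y, 3)
  w3 <- rep(w, 3)
  structure(
    list(x = x3, y = y3, w = w3, bw = bw, total_weight = n_orig),
    class = "transition_density"
  )
}

#' Evaluate a transition density
#'
#' @param dens a [transition_density()].
#' @param theta0_deg,dtheta_deg evaluation coordinates (degrees), equal
#'   length.
#' @return density values (per square degree).
#' @export
density_at <- function(dens, theta0_deg, dtheta_deg) {
  stopifnot(inherits(dens, "transition_density"),
            length(theta0_deg) == length(dtheta_deg))
  kde2_eval_cpp(dens$x, dens$y, dens$w, dens$bw[1], dens$bw[2],
                theta0_deg %% 360, dtheta_deg, dens$total_weight)
}

#' Entropy production versus angular displacement
#'
#' The irreversibility statistic of driven rotary motion. For each lag
#' `n * T_field` the transition density `p(theta0, dtheta)` is estimated from
#' all jump pairs, and the entropy production (in units of k_B) at each
#' displacement on a symmetric grid is the log-ratio of forward to
#' time-reversed transition probability, averaged uniformly over starting
#' angles:
#' `ds(dtheta) = < log[ p(theta0, dtheta) / p(theta0 + dtheta mod 360, -dtheta) ] >_theta0`.
#' For a stochastically ratcheting motor this curve is linear with slope
#' `omega_eff / D_eff`, independently of the lag. A through-origin
#' least-squares slope is fitted per lag; densities below `floor_frac` of the
#' maximum are floored and the affected grid cells dropped from the average
#' (displacements where more than half the cells are dropped are flagged).
#'
#' @param traj an `angular_trajectory` of a driven motor.
#' @param T_field field period (s).
#' @param lags integer multiples of the field period to analyse.
#' @param dtheta_grid displacement grid (degrees); default symmetric, spanning
#'   the central 90% of observed jumps at the longest lag.
#' @param n_theta0 number of starting-angle grid points in `[0, 360)`.
#' @param bw optional KDE bandwidth override (degrees, length 2), applied to
#'   every lag.
#' @param floor_frac density floor as a fraction of the evaluated maximum.
#' @return an object of class `entropy_curve`: `dtheta_deg`, matrix `ds_kB`
#'   (lag x displacement), per-lag `slopes` (per degree), a pooled
#'   `slope` across lags, `omega_eff` (deg/s), `D_eff` (deg^2/s),
#'   `low_confidence` flags.
#' @export
entropy_production <- function(traj, T_field, lags = c(2, 4, 6),
                               dtheta_grid = NULL, n_theta0 = 36,
                               bw = NULL, floor_frac = 1e-12) {
  stopifnot(length(lags) >= 1)
  jump_sets <- lapply(lags, function(n) jump_pairs(traj, n, T_field))
  for (js in jump_sets) {
    if (length(js$theta0_deg) < 500) {
      stop("trajectory too short: fewer than 500 pairs at lag ", js$n, " periods")
    }
  }
  if (is.null(dtheta_grid)) {
    # span where forward and reversed densities are both populated at every
    # lag: a few standard deviations of the shortest-lag jump distribution
    span <- 2.5 * sd(jump_sets[[1]]$dtheta_deg)
    span <- max(span, 5)
    dtheta_grid <- seq(-span, span, length.out = 41)
  }
  theta0_grid <- seq(0, 360 - 360 / n_theta0, length.out = n_theta0)
  nd <- length(dtheta_grid)
  ds <- matrix(NA_real_, nrow = length(lags), ncol = nd,
               dimnames = list(paste0("lag", lags), NULL))
  low_conf <- matrix(FALSE, nrow = length(lags), ncol = nd)
  for (li in seq_along(lags)) {
    dens <- transition_density(jump_sets[[li]], bw = bw)
    g <- expand.grid(theta0 = theta0_grid, dtheta = dtheta_grid)
    fwd <- density_at(dens, g$theta0, g$dtheta)
    bwd <- density_at(dens, g$theta0 + g$dtheta, -g$dtheta)
    floor_val <- floor_frac * max(fwd, bwd)
    ok <- fwd > floor_val & bwd > floor_val
    lr <- log(pmax(fwd, floor_val) / pmax(bwd, floor_val))
    lr_m <- matrix(lr, nrow = n_theta0)
    ok_m <- matrix(ok, nrow = n_theta0)
    for (di in seq_len(nd)) {
      valid <- ok_m[, di]
      if (any(valid)) ds[li, di] <- mean(lr_m[valid, di])
      low_conf[li, di] <- mean(valid) < 0.5
    }
  }
  slopes <- apply(ds, 1, function(y) {
    v <- is.finite(y)
    sum(dtheta_grid[v] * y[v]) / sum(dtheta_grid[v]^2)
  })
  all_y <- as.vector(t(ds))
  all_x <- rep(dtheta_grid, length(lags))
  v <- is.finite(all_y)
  pooled <- sum(all_x[v] * all_y[v]) / sum(all_x[v]^2)
  eff <- effective_coefficients(traj, T_field, lags = lags)
  structure(
    list(dtheta_deg = dtheta_grid, ds_kB = ds, lags = lags,
         slopes = slopes, slope = pooled,
         omega_eff = eff$omega_eff, D_eff = eff$D_eff,
         low_confidence = low_conf, T_field = T_field),
    class = "entropy_curve"
  )
}

#' @export
print.entropy_curve <- function(x, ...) {
  cat(sprintf(
    "Entropy-production curve: lags {%s} periods, slope %.4g /deg (omega_eff/D_eff = %.4g /deg)\n",
    paste(x$lags, collapse = ", "), x$slope, x$omega_eff / x$D_eff
  ))
  invisible(x)
}

#' Renormalize entropy-production curves to unit slope and pool
#'
#' Divides each motor's curve by its own fitted slope so that all biased
#' motors collapse onto the unit-slope line, then fits a pooled
#' through-origin slope to the collapsed ensemble. Motors whose slope is not
#' distinguishable from zero are excluded (the rescaling is ill-defined for
#' them): by default a block bootstrap of the shortest-lag jump pairs decides
#' significance; alternatively a numeric `|slope|` threshold can be given.
#'
#' @param curves list of [entropy_production()] results.
#' @param trajs optional list of the corresponding trajectories (required for
#'   the bootstrap exclusion test).
#' @param bias_threshold `NULL` (bootstrap test at `alpha`) or a numeric
#'   minimum `|slope|` in per-degree units.
#' @param alpha significance level of the bootstrap exclusion test.
#' @param n_boot bootstrap resamples.
#' @return list with `pooled_slope`, `collapsed` (list of rescaled curves),
#'   `excluded` (indices), `slopes` (original per-motor slopes).
#' @export
renormalize_slopes <- function(curves, trajs = NULL, bias_threshold = NULL,
                               alpha = 0.05, n_boot = 100) {
  stopifnot(length(curves) >= 2)
  slopes <- vapply(curves, function(cv) cv$slope, numeric(1))
  if (is.numeric(bias_threshold)) {
    excluded <- which(abs(slopes) < bias_threshold)
  } else {
    if (is.null(trajs)) stop("bootstrap exclusion needs the trajectories")
    excluded <- which(!vapply(seq_along(curves), function(k) {
      slope_significant(trajs[[k]], curves[[k]], alpha = alpha, n_boot = n_boot)
    }, logical(1)))
  }
  keep <- setdiff(seq_along(curves), excluded)
  if (!length(keep)) stop("all motors excluded as unbiased")
  collapsed <- lapply(keep, function(k) {
    cv <- curves[[k]]
    cv$ds_kB <- cv$ds_kB / slopes[k]
    cv$slopes <- cv$slopes / slopes[k]
    cv$slope <- 1
    cv
  })
  x <- unlist(lapply(collapsed, function(cv) rep(cv$dtheta_deg, length(cv$lags))))
  y <- unlist(lapply(collapsed, function(cv) as.vector(t(cv$ds_kB))))
  v <- is.finite(y)
  list(pooled_slope = sum(x[v] * y[v]) / sum(x[v]^2),
       collapsed = collapsed, excluded = excluded, slopes = slopes)
}

#' Bootstrap significance of an entropy-production slope
#'
#' Block bootstrap over contiguous stretches of the trajectory: the
#' shortest-lag jump pairs are resampled in blocks of ~10 field periods, the
#' through-origin slope of the entropy-production curve is recomputed from
#' the resampled pairs (with the original bandwidths), and the motor is
#' called biased if the bootstrap `1 - alpha` interval excludes zero.
#'
#' @param traj the motor's trajectory.
#' @param curve its [entropy_production()] result.
#' @param alpha significance level.
#' @param n_boot number of resamples.
#' @return logical: is the slope significantly nonzero?
#' @export
slope_significant <- function(traj, curve, alpha = 0.05, n_boot = 100) {
  n1 <- min(curve$lags)
  jumps <- jump_pairs(traj, n1, curve$T_field)
  m <- length(jumps$theta0_deg)
  block <- max(1L, as.integer(round(10 * curve$T_field /
                                      (jumps$lag_s / jumps$lag_frames))))
  n_blocks <- ceiling(m / block)
  starts <- seq(1L, m - block + 1L)
  dens0 <- transition_density(jumps)
  grid <- curve$dtheta_deg
  theta0_grid <- seq(0, 350, by = 10)
  boot_slope <- function(idx) {
    js <- jumps
    js$theta0_deg <- jumps$theta0_deg[idx]
    js$dtheta_deg <- jumps$dtheta_deg[idx]
    # resamples are pre-binned aggressively: the bootstrap needs slope
    # variability, not tail accuracy
    dens <- transition_density(js, bw = dens0$bw, bin_threshold = 2000)
    g <- expand.grid(theta0 = theta0_grid, dtheta = grid)
    fwd <- density_at(dens, g$theta0, g$dtheta)
    bwd <- density_at(dens, g$theta0 + g$dtheta, -g$dtheta)
    fl <- 1e-12 * max(fwd, bwd)
    ok <- fwd > fl & bwd > fl
    lr <- log(fwd[ok] / bwd[ok])
    x <- g$dtheta[ok]
    sum(x * lr) / sum(x^2)
  }
  sl <- vapply(seq_len(n_boot), function(b) {
    s0 <- sample(starts, n_blocks, replace = TRUE)
    idx <- as.vector(outer(0:(block - 1L), s0, `+`))
    idx <- idx[idx <= m]
    boot_slope(idx)
  }, numeric(1))
  ci <- quantile(sl, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
  ci[1] > 0 || ci[2] < 0
}

#' Effective drift and diffusion of a driven motor
#'
#' Stroboscopic estimates at multiples of the field period, which remove the
#' deterministic intra-cycle wiggle of the drive: `omega_eff` is the mean
#' displacement over one field period divided by the period; `D_eff` comes
#' from the growth of the displacement variance over `n` periods,
#' `var(dtheta; nT) = 2 D_eff nT`, fitted through the origin by weighted
#' least squares over the requested lags.
#'
#' @param traj an `angular_trajectory`.
#' @param T_field field period (s).
#' @param lags lag multiples used for the variance growth fit.
#' @return list with `omega_eff` (deg/s) and `D_eff` (deg^2/s).
#' @export
effective_coefficients <- function(traj, T_field, lags = c(2, 4, 6)) {
  tt <- .traj_theta(traj)
  span <- tt$times[length(tt$times)] - tt$times[1]
  if (span < 100 * T_field) stop("need at least 100 field cycles")
  j1 <- jump_pairs(traj, 1, T_field)
  omega_eff <- mean(j1$dtheta_deg) / T_field
  vars <- t(vapply(lags, function(n) {
    jp <- jump_pairs(traj, n, T_field)
    c(v = var(jp$dtheta_deg), m = length(jp$dtheta_deg))
  }, numeric(2)))
  tau <- lags * T_field
  w <- vars[, "m"]
  D_eff <- sum(w * vars[, "v"] * 2 * tau) / sum(w * (2 * tau)^2)
  list(omega_eff = omega_eff, D_eff = D_eff)
}

#' Mean-squared displacement and the diffusive-to-ballistic crossover
#'
#' Computes `MSD(tau) = <(theta(t + tau) - theta(t))^2>` over log-spaced lags
#' (restricted to multiples of the field period when one is given) and fits
#' the drift-diffusion form `MSD = 2 D tau + (omega tau)^2`. A biased motor
#' shows a crossover from diffusive (log-log slope 1) to ballistic (slope 2)
#' behaviour at `t_c = 2 D / omega^2`; for an unbiased motor the quadratic
#' term pins near zero and the crossover is flagged absent.
#'
#' @param traj an `angular_trajectory`.
#' @param T_field optional field period for stroboscopic lags (s).
#' @param n_lags number of lags.
#' @return list with `tau_s`, `msd_deg2`, fitted `D` (deg^2/s), `omega`
#'   (deg/s, magnitude), `crossover_s` (`NA` when absent), `loglog_slope`
#'   (local slopes between successive lags).
#' @export
msd_crossover <- function(traj, T_field = NULL, n_lags = 20) {
  tt <- .traj_theta(traj)
  dt <- tt$times[2] - tt$times[1]
  N <- length(tt$theta)
  max_lag <- floor((N - 1) / 4)
  if (!is.null(T_field)) {
    per <- round(T_field / dt)
    lag_frames <- unique(pmax(per, round(exp(seq(log(per), log(max_lag),
                                                 length.out = n_lags)) / per) * per))
    lag_frames <- lag_frames[lag_frames <= max_lag]
  } else {
    lag_frames <- unique(round(exp(seq(log(1), log(max_lag), length.out = n_lags))))
  }
  theta_deg <- rad2deg(tt$theta)
  msd <- vapply(lag_frames, function(L) {
    d <- theta_deg[(1 + L):N] - theta_deg[1:(N - L)]
    mean(d^2)
  }, numeric(1))
  tau <- lag_frames * dt
  # relative-error weighting: MSD spans orders of magnitude over the lags
  fit <- lm(msd ~ 0 + tau + I(tau^2), weights = 1 / msd^2)
  cf <- coef(fit)
  D <- max(cf[1], 0) / 2
  omega2 <- cf[2]
  se_omega2 <- summary(fit)$coefficients[2, 2]
  has_drift <- is.finite(omega2) && omega2 > 2 * se_omega2
  omega <- if (has_drift) sqrt(omega2) else 0
  crossover <- if (has_drift) 2 * D / omega^2 else NA_real_
  ll <- diff(log(msd)) / diff(log(tau))
  list(tau_s = tau, msd_deg2 = msd, D = D, omega = omega,
       crossover_s = crossover, loglog_slope = ll)
}
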