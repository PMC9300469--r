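#' Angles from tracked tip positions
#'
#' Per frame, the rotor angle relative to the platform centre:
#' `atan2(y - center_y, x - center_x)`, in `(-pi, pi]`. Counterclockwise is
#' positive (mathematical convention, x right, y up).
#'
#' @param series a `tip_positions` object.
#' @return wrapped angles (rad), one per frame.
#' @export
angles_from_positions <- function(series) {
  stopifnot(inherits(series, "tip_positions"))
  dx <- series$frames$x_nm - series$center_x_nm
  dy <- series$frames$y_nm - series$center_y_nm
  bad <- which(dx == 0 & dy == 0)
  if (length(bad)) {
    stop("tip coincides with the rotation centre at frame ", series$frames$frame[bad[1]])
  }
  a <- atan2(dy, dx)
  # atan2 returns [-pi, pi]; map -pi to +pi for the (-pi, pi] convention
  a[a == -pi] <- pi
  a
}

#' Unwrap wrapped angles into cumulative angular displacement
#'
#' Successive differences are mapped to the shortest arc `(-pi, pi]` (a jump
#' of exactly 180 degrees resolves toward +180) and cumulatively summed; the
#' first value equals the first wrapped angle. Faithful whenever the true
#' per-frame motion stays below half a turn.
#'
#' @param wrapped wrapped angles (rad).
#' @return cumulative (unwrapped) angles (rad).
#' @export
unwrap_angles <- function(wrapped) {
  if (length(wrapped) < 2) return(wrapped)
  d <- diff(wrapped)
  d <- pi - ((pi - d) %% (2 * pi))  # maps to (-pi, pi], ties to +pi
  cumsum(c(wrapped[1], d))
}

.traj_theta <- function(traj) {
  if (inherits(traj, "angular_trajectory")) {
    list(times = traj$times, theta = traj$theta)
  } else if (inherits(traj, "tip_positions")) {
    list(times = traj$frames$time_s,
         theta = unwrap_angles(angles_from_positions(traj)))
  } else {
    stop("need an angular_trajectory or tip_positions object")
  }
}

#' Angular velocity by the endpoint formula
#'
#' `Omega = (theta_last - theta_first) / dt` over the requested window, where
#' the endpoints are the first and last sample inside the window. This is the
#' standard per-segment speed of rotary single-particle assays, not a
#' regression slope. Counterclockwise positive.
#'
#' @param traj an `angular_trajectory` or `tip_positions`.
#' @param window `c(t_first, t_last)` in seconds; default is the full
#'   trajectory.
#' @return signed angular velocity in degrees per second.
#' @export
angular_velocity <- function(traj, window = NULL) {
  tt <- .traj_theta(traj)
  if (is.null(window)) window <- range(tt$times)
  stopifnot(length(window) == 2, window[2] > window[1])
  i <- which(tt$times >= window[1] - 1e-12 & tt$times <= window[2] + 1e-12)
  if (length(i) < 2) stop("window contains fewer than two samples")
  i1 <- i[1]; i2 <- i[length(i)]
  rad2deg(tt$theta[i2] - tt$theta[i1]) / (tt$times[i2] - tt$times[i1])
}

#' Per-segment speed records
#'
#' Computes the endpoint angular velocity within each protocol segment of a
#' sweep trajectory and derives the per-segment drive descriptors (field
#' state, axis angle, frequency) and, where a frequency is defined, the
#' directional bias efficiency in turns per field cycle.
#'
#' @param traj an `angular_trajectory` produced by [simulate_protocol()] (its
#'   metadata carries the segment table), or any trajectory plus an explicit
#'   `segments` table.
#' @param segments optional segment data frame overriding the metadata.
#' @return data frame with one row per segment: `segment`, `waveform`,
#'   `axis_deg`, `freq_hz`, `omega_deg_s`, `turns_per_cycle`.
#' @export
segment_speeds <- function(traj, segments = NULL) {
  if (is.null(segments)) segments <- traj$metadata$segments
  if (is.null(segments)) stop("no segment table available")
  omega <- vapply(seq_len(nrow(segments)), function(k) {
    angular_velocity(traj, c(segments$t_start[k], segments$t_end[k]))
  }, numeric(1))
  freq <- ifelse(segments$waveform %in% c("square", "smoothed_standard", "smoothed_printed"),
                 1 / segments$period, NA_real_)
  data.frame(
    segment = seq_len(nrow(segments)),
    waveform = segments$waveform,
    axis_deg = rad2deg(segments$axis_angle),
    freq_hz = freq,
    omega_deg_s = omega,
    turns_per_cycle = ifelse(is.na(freq), NA_real_, omega / (360 * freq))
  )
}

#' Directional bias efficiency
#'
#' Net full turns completed per period of the AC drive:
#' `Omega / (360 * frequency)`. Undefined for DC or field-off segments
#' (frequency zero or absent), flagged as `NA`.
#'
#' @param omega_deg_s signed angular velocity (deg/s).
#' @param freq_hz drive frequency (Hz); `NA` or 0 yields `NA`.
#' @return signed turns per field cycle.
#' @export
turns_per_cycle <- function(omega_deg_s, freq_hz) {
  ifelse(is.na(freq_hz) | freq_hz == 0, NA_real_, omega_deg_s / (360 * freq_hz))
}

#' Histogram of angular speeds
#'
#' Bins signed per-particle angular velocities and reports the
#' clockwise/counterclockwise split.
#'
#' @param omega_deg_s signed angular velocities (deg/s).
#' @param bin_width bin width (deg/s).
#' @return list with `counts`, `breaks`, `mids`, `n`, `frac_ccw`, `frac_cw`.
#' @export
speed_histogram <- function(omega_deg_s, bin_width = 30) {
  if (!length(omega_deg_s)) stop("no speeds supplied")
  lim <- max(abs(omega_deg_s), bin_width)
  breaks <- seq(-ceiling(lim / bin_width) * bin_width,
                ceiling(lim / bin_width) * bin_width, by = bin_width)
  h <- hist(omega_deg_s, breaks = breaks, plot = FALSE)
  list(counts = h$counts, breaks = h$breaks, mids = h$mids,
       n = length(omega_deg_s),
       frac_ccw = mean(omega_deg_s > 0), frac_cw = mean(omega_deg_s < 0))
}

#' Speed versus field-axis orientation
#'
#' For an axis-sweep trajectory, computes the per-segment endpoint speed and
#' fits the sinusoidal response `Omega(phi) = A * sin(k * (phi - phi0)) + m`
#' by least squares. The default angular period of the response is 180
#' degrees (`k = 2`): reversing the field polarity is equivalent to rotating
#' the axis by 180 degrees, so the speed response repeats twice per turn.
#' "Phase correction" for ensemble aggregation subtracts each motor's fitted
#' `phi0`.
#'
#' @param traj an axis-sweep `angular_trajectory` (metadata segment table
#'   present), or `NULL` if `axis_deg`/`omega_deg_s` are given directly.
#' @param axis_deg,omega_deg_s optional explicit per-segment axis angles and
#'   speeds (degrees, deg/s).
#' @param k harmonic of the response (2 means 180-degree period).
#' @return list with `axis_deg`, `omega_deg_s`, fitted `amplitude`,
#'   `phase_deg` (phi0), `offset`, `r_squared`, `p_value` (F-test against a
#'   constant), `residuals` and the fit function `predict(phi_deg)`.
#' @export
speed_vs_axis <- function(traj = NULL, axis_deg = NULL, omega_deg_s = NULL, k = 2) {
  if (is.null(axis_deg)) {
    ss <- segment_speeds(traj)
    axis_deg <- ss$axis_deg
    omega_deg_s <- ss$omega_deg_s
  }
  if (length(axis_deg) < 4) stop("need at least 4 segments for a sinusoid fit")
  phi <- deg2rad(axis_deg)
  S <- sin(k * phi); C <- cos(k * phi)
  fit <- lm(omega_deg_s ~ S + C)
  cf <- coef(fit)
  A <- sqrt(cf["S"]^2 + cf["C"]^2)
  # A*sin(k(phi - phi0)) = A cos(k phi0) sin(k phi) - A sin(k phi0) cos(k phi)
  phi0 <- atan2(-cf["C"], cf["S"]) / k
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(
    axis_deg = axis_deg, omega_deg_s = omega_deg_s,
    amplitude = unname(A), phase_deg = unname(rad2deg(phi0)),
    offset = unname(cf["(Intercept)"]),
    r_squared = sm$r.squared,
    p_value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    residuals = unname(fit$residuals),
    predict = function(phi_deg) {
      unname(cf["(Intercept)"] + cf["S"] * sin(k * deg2rad(phi_deg)) +
               cf["C"] * cos(k * deg2rad(phi_deg)))
    }
  )
}

#' Preferred dwell positions of the rotor
#'
#' Histograms the wrapped rotor angle of a field-off trajectory and returns
#' the circularly detected peaks: local maxima whose prominence (height above
#' the higher of the two flanking minima) is at least `prominence` times the
#' tallest bin. The number of peaks is the number of dwell positions.
#'
#' @param traj an `angular_trajectory` or `tip_positions`.
#' @param bin_deg histogram bin width (degrees).
#' @param prominence relative prominence threshold in (0, 1].
#' @return data frame with `angle_deg` (peak centre in `[0, 360)`) and
#'   `count`; zero rows if no peak passes the threshold.
#' @export
dwell_positions <- function(traj, bin_deg = 5, prominence = 0.2) {
  tt <- .traj_theta(traj)
  ang <- rad2deg(tt$theta) %% 360
  breaks <- seq(0, 360, by = bin_deg)
  counts <- hist(ang, breaks = breaks, plot = FALSE)$counts
  n <- length(counts)
  if (max(counts) == 0 || all(counts == counts[1])) {
    return(data.frame(angle_deg = numeric(0), count = numeric(0)))
  }
  mids <- breaks[-1] - bin_deg / 2
  nxt <- function(i) (i %% n) + 1L
  prv <- function(i) ((i - 2L) %% n) + 1L
  peaks <- integer(0)
  for (i in seq_len(n)) {
    # circular local maximum (strictly above one neighbour, not below the other)
    if (counts[i] >= counts[prv(i)] && counts[i] >= counts[nxt(i)] &&
        (counts[i] > counts[prv(i)] || counts[i] > counts[nxt(i)])) {
      # walk to the flanking minima on the circle
      lo_l <- counts[i]; j <- i
      repeat {
        j <- prv(j)
        if (j == i) break
        lo_l <- min(lo_l, counts[j])
        if (counts[j] > counts[i]) break
      }
      lo_r <- counts[i]; j <- i
      repeat {
        j <- nxt(j)
        if (j == i) break
        lo_r <- min(lo_r, counts[j])
        if (counts[j] > counts[i]) break
      }
      prom <- counts[i] - max(lo_l, lo_r)
      if (prom >= prominence * max(counts)) peaks <- c(peaks, i)
    }
  }
  # merge flat-top plateaus: keep one peak per run of adjacent bins
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) > 1)
    if (peaks[1] == 1 && peaks[length(peaks)] == n) keep[1] <- FALSE
    peaks <- peaks[keep]
  }
  data.frame(angle_deg = mids[peaks], count = counts[peaks])
}
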