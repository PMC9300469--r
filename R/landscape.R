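#' Rotor energy landscape
#'
#' Constructs the intrinsic energy landscape of a rotary Brownian-ratchet
#' motor together with its coupling to an external AC field. The landscape is
#' a sum of `n_minima` Gaussian wells of depth `well_depth` placed every
#' `2*pi/n_minima` radians (so the well spacing is always a simple fraction of
#' a full turn), plus a field term `(4a/pi) * cos(theta - axis) * E(t)` whose
#' sign switches with the drive waveform.
#'
#' All energies are in thermal units (k_B T); angles are radians internally.
#'
#' @param n_minima number of energy minima per full turn (positive integer).
#' @param well_depth well depth `b` in k_B T; `b >= 0`.
#' @param well_inverse_width inverse squared width `c` of each Gaussian well,
#'   in rad^-2; `c > 0`.
#' @param field_strength field coupling `a` in k_B T; `a >= 0`. The field term
#'   has peak amplitude `4a/pi`.
#' @param minima_offset angular offset `theta0` of the well centres (rad).
#'   This is the angle between the motor's well pattern and the laboratory
#'   frame, i.e. the motor's orientation relative to a 0-degree field axis.
#' @return an object of class `rotor_landscape`.
#' @examples
#' ls2 <- rotor_landscape(n_minima = 2, minima_offset = pi / 4)
#' intrinsic_potential(ls2$minima_offset, ls2)  # approximately -well_depth
#' @export
rotor_landscape <- function(n_minima,
                            well_depth = 8,
                            well_inverse_width = 20,
                            field_strength = 8,
                            minima_offset = 0) {
  n_minima <- as.integer(n_minima)
  stopifnot(length(n_minima) == 1L, n_minima >= 1L)
  if (well_depth < 0) stop("well_depth must be >= 0")
  if (well_inverse_width <= 0) stop("well_inverse_width must be > 0")
  if (field_strength < 0) stop("field_strength must be >= 0")
  spacing <- 2 * pi / n_minima
  # number of image wells on each side so that truncated Gaussian tails < 1e-12
  n_images <- ceiling(6 / (sqrt(well_inverse_width) * spacing)) + 1L
  structure(
    list(
      field_strength = field_strength,
      well_depth = well_depth,
      well_inverse_width = well_inverse_width,
      minima_offset = minima_offset,
      minima_spacing = spacing,
      n_minima = n_minima,
      n_images = as.integer(n_images)
    ),
    class = "rotor_landscape"
  )
}

#' @export
print.rotor_landscape <- function(x, ...) {
  cat(sprintf(
    "Rotor landscape: %d minima every %.1f deg, b = %g kT, c = %g rad^-2, a = %g kT, theta0 = %.1f deg\n",
    x$n_minima, rad2deg(x$minima_spacing), x$well_depth,
    x$well_inverse_width, x$field_strength, rad2deg(x$minima_offset)
  ))
  invisible(x)
}

#' Square-wave drive
#'
#' The AC drive waveform: +1 during the first half of each period, -1 during
#' the second half. Its time average over any whole number of periods is zero,
#' so the drive exerts no net time-averaged force.
#'
#' @param t time (s), vectorized.
#' @param period field period (s), `> 0`.
#' @return +1 or -1 per element of `t`.
#' @export
square_wave <- function(t, period) {
  if (!is.numeric(period) || length(period) != 1L || period <= 0) {
    stop("period must be a single positive number")
  }
  ifelse((t %% period) < period / 2, 1, -1)
}

#' Fourier-smoothed square wave
#'
#' Differentiable approximations to [square_wave()], offered in two dialects.
#' `"standard"` is the conventional square-wave Fourier partial sum
#' `(4/pi) * sum over odd n <= N of sin(2*pi*n*t/period)/n`, which converges
#' to the square wave away from its discontinuities. `"printed"` is the raw
#' partial sum `sum_{n=1}^{N} sin(n*t/period)/n` (the Fourier series of a
#' sawtooth, kept available for comparison with legacy conventions).
#'
#' @param t time (s), vectorized.
#' @param period field period (s).
#' @param n_terms number of Fourier terms `N >= 1`.
#' @param dialect `"standard"` (default) or `"printed"`.
#' @return dimensionless waveform values.
#' @export
smoothed_square_wave <- function(t, period, n_terms, dialect = c("standard", "printed")) {
  dialect <- match.arg(dialect)
  n_terms <- as.integer(n_terms)
  stopifnot(n_terms >= 1L, period > 0)
  out <- numeric(length(t))
  if (dialect == "standard") {
    for (n in seq(1L, n_terms, by = 2L)) {
      out <- out + sin(2 * pi * n * t / period) / n
    }
    out <- out * 4 / pi
  } else {
    for (n in seq_len(n_terms)) {
      out <- out + sin(n * t / period) / n
    }
  }
  out
}

#' Intrinsic (field-off) rotor potential
#'
#' Evaluates `-b * sum_k exp(-c * (theta - theta0 - k*spacing)^2)` with the
#' well sum made 2*pi-periodic by including enough image wells that the
#' truncation error is below 1e-12.
#'
#' @param theta rotor angle (rad), vectorized; any real value.
#' @param landscape a [rotor_landscape()].
#' @return potential energy in k_B T.
#' @export
intrinsic_potential <- function(theta, landscape) {
  stopifnot(inherits(landscape, "rotor_landscape"))
  b <- landscape$well_depth
  cc <- landscape$well_inverse_width
  sp <- landscape$minima_spacing
  k0 <- round((theta - landscape$minima_offset) / sp)
  out <- numeric(length(theta))
  for (j in -landscape$n_images:landscape$n_images) {
    x <- theta - landscape$minima_offset - (k0 + j) * sp
    out <- out - b * exp(-cc * x^2)
  }
  out
}

.waveform_codes <- c(off = 0L, square = 1L, smoothed_standard = 2L,
                     smoothed_printed = 3L, dc = 4L)

#' Field drive protocol
#'
#' A piecewise schedule of drive segments. Each segment has a duration, a
#' waveform (`"square"`, `"smoothed_square"` in either dialect, `"dc"` or
#' `"off"`), a period where applicable, a dimensionless amplitude scale
#' multiplying the landscape's field coupling, and the orientation of the
#' field axis in the laboratory frame.
#'
#' @param segments a data frame (or list coercible to one) with columns
#'   `duration` (s), `waveform` (character), and optionally `period` (s),
#'   `amplitude_scale`, `axis_angle` (rad) and `fourier_order`. Missing
#'   optional columns get defaults: period 0.2 s, amplitude scale 1, axis 0,
#'   fourier order 199.
#' @return an object of class `field_protocol` with the completed segment
#'   table and cumulative start/end times.
#' @examples
#' field_protocol(data.frame(duration = 10, waveform = "square", period = 0.2))
#' @export
field_protocol <- function(segments) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (nrow(segments) == 0L) stop("protocol needs at least one segment")
  if (!all(c("duration", "waveform") %in% names(segments))) {
    stop("segments need columns 'duration' and 'waveform'")
  }
  if (is.null(segments$period)) segments$period <- 0.2
  if (is.null(segments$amplitude_scale)) segments$amplitude_scale <- 1
  if (is.null(segments$axis_angle)) segments$axis_angle <- 0
  if (is.null(segments$fourier_order)) segments$fourier_order <- 199L
  segments$period[is.na(segments$period)] <- 0.2
  segments$amplitude_scale[is.na(segments$amplitude_scale)] <- 1
  segments$axis_angle[is.na(segments$axis_angle)] <- 0
  segments$fourier_order[is.na(segments$fourier_order)] <- 199L
  bad <- setdiff(unique(segments$waveform),
                 c("square", "smoothed_standard", "smoothed_printed", "dc", "off"))
  if (length(bad)) stop("unknown waveform(s): ", paste(bad, collapse = ", "))
  if (any(segments$duration <= 0)) stop("segment durations must be > 0")
  needs_period <- segments$waveform %in% c("square", "smoothed_standard", "smoothed_printed")
  if (any(needs_period & segments$period <= 0)) stop("field period must be > 0")
  segments$t_end <- cumsum(segments$duration)
  segments$t_start <- segments$t_end - segments$duration
  structure(
    list(segments = segments, duration = sum(segments$duration)),
    class = "field_protocol"
  )
}

#' @export
print.field_protocol <- function(x, ...) {
  cat(sprintf("Field protocol: %d segment(s), total %.3g s\n", nrow(x$segments), x$duration))
  print(x$segments[, c("t_start", "t_end", "waveform", "period", "amplitude_scale", "axis_angle")])
  invisible(x)
}

# segment index for each time point; errors outside the protocol
.segment_at <- function(protocol, t) {
  if (any(t < 0 | t > protocol$duration)) {
    stop("time outside protocol duration")
  }
  idx <- findInterval(t, protocol$segments$t_start, rightmost.closed = FALSE)
  idx[idx > nrow(protocol$segments)] <- nrow(protocol$segments)
  idx
}

#' Instantaneous drive state
#'
#' Looks up the protocol segment active at each time and evaluates the
#' waveform, returning the dimensionless drive value `E(t)`, the effective
#' amplitude scale and the field-axis angle.
#'
#' @param protocol a [field_protocol()].
#' @param t time(s) within the protocol (s).
#' @return data frame with columns `E`, `amplitude_scale`, `axis_angle`.
#' @export
field_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "field_protocol"))
  idx <- .segment_at(protocol, t)
  seg <- protocol$segments[idx, , drop = FALSE]
  tl <- t - seg$t_start  # waveform phase restarts at each segment
  E <- numeric(length(t))
  i <- seg$waveform == "dc"
  E[i] <- 1
  i <- seg$waveform == "square"
  E[i] <- ifelse((tl[i] %% seg$period[i]) < seg$period[i] / 2, 1, -1)
  for (w in c("smoothed_standard", "smoothed_printed")) {
    for (k in which(seg$waveform == w)) {
      E[k] <- smoothed_square_wave(tl[k], seg$period[k], seg$fourier_order[k],
                                   sub("smoothed_", "", w))
    }
  }
  data.frame(E = E, amplitude_scale = seg$amplitude_scale, axis_angle = seg$axis_angle)
}

#' Total time-dependent potential
#'
#' `U(theta, t) = (4a/pi) * cos(theta - axis) * E(t) * amplitude_scale +
#' U_intrinsic(theta)`. With the field axis at zero this is the switching
#' two-term ratchet landscape; the field term vanishes in `"off"` segments.
#'
#' @param theta rotor angle (rad), vectorized (recycled against `t`).
#' @param t time (s), vectorized.
#' @param landscape a [rotor_landscape()].
#' @param protocol a [field_protocol()].
#' @return potential energy in k_B T.
#' @export
total_potential <- function(theta, t, landscape, protocol) {
  f <- field_at(protocol, t)
  (4 * landscape$field_strength / pi) * cos(theta - f$axis_angle) * f$E * f$amplitude_scale +
    intrinsic_potential(theta, landscape)
}

#' Angular gradient of the total potential
#'
#' Analytic derivative of [total_potential()] with respect to the rotor
#' angle; its negative is the generalized torque entering the Langevin drift.
#'
#' @inheritParams total_potential
#' @return dU/dtheta in k_B T per rad.
#' @export
grad_potential <- function(theta, t, landscape, protocol) {
  f <- field_at(protocol, t)
  g <- -(4 * landscape$field_strength / pi) * sin(theta - f$axis_angle) * f$E * f$amplitude_scale
  b <- landscape$well_depth
  cc <- landscape$well_inverse_width
  sp <- landscape$minima_spacing
  k0 <- round((theta - landscape$minima_offset) / sp)
  for (j in -landscape$n_images:landscape$n_images) {
    x <- theta - landscape$minima_offset - (k0 + j) * sp
    g <- g + 2 * b * cc * x * exp(-cc * x^2)
  }
  g
}
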