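#' Render an angular trajectory as tracked tip positions
#'
#' Converts a ground-truth rotor trajectory into the kind of per-frame tip
#' position table that centroid tracking of TIRF videos produces. Each frame
#' averages the tip position (not the angle) over its exposure window -- the
#' centroid of a moving emitter -- so fast rotation shortens the apparent
#' radius, as in real data. Independent Gaussian localization noise of scale
#' `localization_sigma_nm` is then added to x and y.
#'
#' @param traj an `angular_trajectory` sampled at an integer multiple of the
#'   frame rate.
#' @param rotor_radius_nm distance of the tracked tip from the rotation
#'   centre (nm); default 275 (half of a 550 nm rotor arm).
#' @param localization_sigma_nm per-axis localization noise (nm).
#' @param frame_rate_hz camera frame rate (default 250 frames/s).
#' @param seed RNG seed for the localization noise.
#' @param center platform centre `c(x, y)` in nm.
#' @return an object of class `tip_positions`: data frame columns `frame`,
#'   `time_s`, `x_nm`, `y_nm` plus acquisition metadata.
#' @export
render_tip_positions <- function(traj, rotor_radius_nm = 275,
                                 localization_sigma_nm = 20,
                                 frame_rate_hz = 250, seed = 1L,
                                 center = c(0, 0)) {
  stopifnot(inherits(traj, "angular_trajectory"))
  dt <- traj$times[2] - traj$times[1]
  sub <- round(1 / (frame_rate_hz * dt))
  if (sub < 1 || abs(sub * frame_rate_hz * dt - 1) > 1e-8) {
    stop("trajectory sampling rate must be an integer multiple of the frame rate")
  }
  duration <- traj$times[length(traj$times)]
  n_frames <- floor(duration * frame_rate_hz)
  if (n_frames < 1) stop("trajectory shorter than one frame")
  if (length(traj$theta) < n_frames * sub) {
    n_frames <- length(traj$theta) %/% sub
  }
  # centroid over each exposure window: mean of (cos, sin) over sub substeps
  idx <- seq_len(n_frames * sub)
  cx <- colMeans(matrix(cos(traj$theta[idx]), nrow = sub))
  sy <- colMeans(matrix(sin(traj$theta[idx]), nrow = sub))
  set.seed(seed)
  x <- center[1] + rotor_radius_nm * cx + rnorm(n_frames, 0, localization_sigma_nm)
  y <- center[2] + rotor_radius_nm * sy + rnorm(n_frames, 0, localization_sigma_nm)
  structure(
    list(
      frames = data.frame(
        frame = seq_len(n_frames) - 1L,
        time_s = (seq_len(n_frames) - 1L) / frame_rate_hz,
        x_nm = x, y_nm = y
      ),
      center_x_nm = center[1], center_y_nm = center[2],
      frame_rate_hz = frame_rate_hz, rotor_radius_nm = rotor_radius_nm,
      localization_sigma_nm = localization_sigma_nm
    ),
    class = "tip_positions"
  )
}

#' @export
print.tip_positions <- function(x, ...) {
  cat(sprintf("Tip positions: %d frames at %g fps, radius %g nm, sigma %g nm\n",
              nrow(x$frames), x$frame_rate_hz, x$rotor_radius_nm,
              x$localization_sigma_nm))
  invisible(x)
}

#' Write / read tracked tip positions
#'
#' Positions go to a CSV with header `frame,time_s,x_nm,y_nm`; the platform
#' centre and acquisition metadata go to a JSON sidecar `<path>.meta.json`.
#' Reading restores the full object; the round trip is exact to full float
#' precision. Reading checks the header and that frames are uniformly spaced,
#' naming the first offending row otherwise; a blank trailing line is
#' tolerated.
#'
#' @param series a `tip_positions` object.
#' @param path CSV file path.
#' @return `read_positions` returns a `tip_positions`; `write_positions`
#'   returns `path` invisibly.
#' @export
write_positions <- function(series, path) {
  stopifnot(inherits(series, "tip_positions"))
  df <- series$frames
  # full-precision text so that read(write(x)) == x exactly
  lines <- c("frame,time_s,x_nm,y_nm",
             sprintf("%d,%.17g,%.17g,%.17g", df$frame, df$time_s, df$x_nm, df$y_nm))
  writeLines(lines, path)
  meta <- series[setdiff(names(series), "frames")]
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_positions
#' @export
read_positions <- function(path) {
  header <- readLines(path, n = 1L)
  if (!identical(header, "frame,time_s,x_nm,y_nm")) {
    stop("expected header 'frame,time_s,x_nm,y_nm', found: ", header)
  }
  df <- read.csv(path, colClasses = c("integer", rep("numeric", 3)))
  if (!nrow(df)) stop("empty position file")
  if (any(df$frame != seq_len(nrow(df)) - 1L)) {
    bad <- which(df$frame != seq_len(nrow(df)) - 1L)[1]
    stop("non-consecutive frame index at row ", bad)
  }
  if (nrow(df) > 2) {
    dt <- diff(df$time_s)
    bad <- which(abs(dt - dt[1]) > 1e-9 * max(1, abs(dt[1])))
    if (length(bad)) stop("non-uniform frame spacing at row ", bad[1] + 1L)
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(center_x_nm = 0, center_y_nm = 0,
         frame_rate_hz = 1 / (df$time_s[2] - df$time_s[1]),
         rotor_radius_nm = NA_real_, localization_sigma_nm = NA_real_)
  }
  structure(
    list(frames = df,
         center_x_nm = meta$center_x_nm, center_y_nm = meta$center_y_nm,
         frame_rate_hz = meta$frame_rate_hz,
         rotor_radius_nm = meta$rotor_radius_nm,
         localization_sigma_nm = meta$localization_sigma_nm),
    class = "tip_positions"
  )
}
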