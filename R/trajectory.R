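#' Construct and validate a marker trajectory
#'
#' A trajectory is a data frame of synchronous 3-D samples of the thumb and
#' index-finger markers during one reach-to-grasp movement, with columns
#' `t_s`, `thumb_x_cm`, `thumb_y_cm`, `thumb_z_cm`, `finger_x_cm`,
#' `finger_y_cm`, `finger_z_cm`. Coordinates: `x` is the transport axis (the
#' start position at `x = +30`, target at `x = 0`), `z` is vertical.
#' Timestamps must be strictly increasing and uniformly spaced to within 1%.
#'
#' @param df A data frame with the columns above, at least 10 rows.
#' @return The validated data frame with class `trajectory` and an attribute
#'   `sampling_rate_hz`.
#' @export
as_trajectory <- function(df) {
  required <- c("t_s", "thumb_x_cm", "thumb_y_cm", "thumb_z_cm",
                "finger_x_cm", "finger_y_cm", "finger_z_cm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("trajectory is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) < 10) stop("trajectory needs at least 10 samples", call. = FALSE)
  dt <- diff(df$t_s)
  if (any(dt <= 0)) stop("trajectory timestamps must be strictly increasing",
                         call. = FALSE)
  if (max(dt) - min(dt) > 0.01 * mean(dt)) {
    stop("trajectory sampling must be uniform to within 1%", call. = FALSE)
  }
  out <- df[required]
  attr(out, "sampling_rate_hz") <- 1 / mean(dt)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Synthesise a noise-free reach-to-grasp trajectory
#'
#' Generates thumb and finger marker samples for a single grasp with a
#' prescribed maximum grip aperture. Lateral transport follows a minimum-jerk
#' (bell-velocity) profile from the start position to the target; the grip
#' aperture opens from the starting aperture along a half-cosine ramp to
#' exactly `mga_target_cm` at `aperture_peak_frac` of movement time (snapped to
#' a sample, so the peak is represented exactly) and then closes to
#' `contact_separation_cm`; thumb height rises to a single peak at mid-movement
#' and descends essentially to table level before the end, so the near-target
#' event detector fires after the aperture maximum.
#'
#' @param mga_target_cm Peak grip aperture to embed (cm); must exceed both the
#'   contact separation and the starting aperture.
#' @param contact_separation_cm Aperture at contact, normally the bar length (cm).
#' @param config A [generator_config()] supplying duration, sampling rate,
#'   start offset and starting aperture.
#' @param peak_height_cm Maximum thumb height above its initial value (cm).
#' @param aperture_peak_frac Fraction of movement time at which the aperture
#'   peaks (the stereotypical 60--75% window).
#' @return A [as_trajectory()] object.
#' @examples
#' tr <- synth_trajectory(6.5, 4.0, generator_config())
#' nrow(tr)  # 121 samples: 0.6 s at 200 Hz, endpoints included
#' @export
synth_trajectory <- function(mga_target_cm, contact_separation_cm,
                             config = generator_config(),
                             peak_height_cm = 5,
                             aperture_peak_frac = 0.65) {
  a0 <- config$start_aperture_cm
  if (!is.finite(mga_target_cm) || mga_target_cm <= a0) {
    stop("'mga_target_cm' must exceed the starting aperture (", a0, " cm)",
         call. = FALSE)
  }
  if (mga_target_cm < contact_separation_cm) {
    stop("'mga_target_cm' (", mga_target_cm,
         ") must be at least the contact separation (", contact_separation_cm,
         ")", call. = FALSE)
  }
  if (aperture_peak_frac <= 0 || aperture_peak_frac >= 1) {
    stop("'aperture_peak_frac' must lie strictly inside (0, 1)", call. = FALSE)
  }
  dur <- config$movement_duration_s
  n <- round(dur * config$sampling_rate_hz) + 1L
  t <- seq(0, dur, length.out = n)
  tau <- t / dur

  # minimum-jerk transport from x = start offset to x = 0
  mj <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  x <- config$start_offset_cm * (1 - mj)

  # aperture profile, peak snapped onto a sample index
  i_peak <- round(aperture_peak_frac * (n - 1)) + 1L
  t_peak <- t[i_peak]
  ap <- numeric(n)
  up <- seq_len(i_peak)
  ap[up] <- a0 + (mga_target_cm - a0) * 0.5 * (1 - cos(pi * t[up] / t_peak))
  down <- seq.int(i_peak + 1L, n)
  ap[down] <- contact_separation_cm + (mga_target_cm - contact_separation_cm) *
    0.5 * (1 + cos(pi * (t[down] - t_peak) / (dur - t_peak)))

  # single-peaked vertical lift, back near table level at the end
  z <- peak_height_cm * sin(pi * tau)^2

  as_trajectory(data.frame(
    t_s = t,
    thumb_x_cm = x, thumb_y_cm = -ap / 2, thumb_z_cm = z,
    finger_x_cm = x, finger_y_cm = ap / 2, finger_z_cm = z
  ))
}

#' Read or write a trajectory CSV file
#'
#' @param traj A [as_trajectory()] object.
#' @param path File path.
#' @return `read_trajectory()` returns a `trajectory`; `write_trajectory()`
#'   returns `path` invisibly.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path, call. = FALSE)
  as_trajectory(read.csv(path))
}

#' @rdname read_trajectory
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
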