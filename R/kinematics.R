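#' Per-sample grip aperture
#'
#' The grip aperture at each sample is the 3-D Euclidean distance between the
#' thumb and finger markers.
#'
#' @param traj A [as_trajectory()] object.
#' @return Numeric vector of apertures (cm), one per sample.
#' @export
grip_aperture <- function(traj) {
  sqrt((traj$thumb_x_cm - traj$finger_x_cm)^2 +
         (traj$thumb_y_cm - traj$finger_y_cm)^2 +
         (traj$thumb_z_cm - traj$finger_z_cm)^2)
}

#' Thumb speed by central differences
#'
#' 3-D thumb speed, differentiated by central differences (forward/backward at
#' the two ends). Positions can optionally be low-pass filtered first (2nd
#' order Butterworth at `lowpass_hz`, zero-phase) for real, noisy marker data;
#' this requires the `signal` package.
#'
#' @param traj A [as_trajectory()] object.
#' @param lowpass_hz Optional cutoff frequency (Hz); `NULL` disables filtering.
#' @return Numeric vector of speeds (cm/s).
#' @export
thumb_speed <- function(traj, lowpass_hz = NULL) {
  pos <- cbind(traj$thumb_x_cm, traj$thumb_y_cm, traj$thumb_z_cm)
  if (!is.null(lowpass_hz)) {
    if (!requireNamespace("signal", quietly = TRUE)) {
      stop("low-pass filtering requires the 'signal' package", call. = FALSE)
    }
    fs <- attr(traj, "sampling_rate_hz")
    bf <- signal::butter(2, lowpass_hz / (fs / 2), type = "low")
    pos <- apply(pos, 2, function(p) signal::filtfilt(bf, p))
  }
  t <- traj$t_s
  n <- nrow(pos)
  vel <- matrix(0, n, 3)
  vel[1, ] <- (pos[2, ] - pos[1, ]) / (t[2] - t[1])
  vel[n, ] <- (pos[n, ] - pos[n - 1, ]) / (t[n] - t[n - 1])
  idx <- 2:(n - 1)
  vel[idx, ] <- (pos[idx + 1, ] - pos[idx - 1, ]) / (t[idx + 1] - t[idx - 1])
  sqrt(rowSums(vel^2))
}

#' Detect movement onset
#'
#' Movement onset is the first sample at which the thumb speed exceeds
#' `speed_threshold` and stays above it for at least `min_samples` consecutive
#' samples (25 ms at 200 Hz by default), a standard kinematic criterion.
#'
#' @param traj A [as_trajectory()] object.
#' @param speed_threshold Speed threshold (cm/s).
#' @param min_samples Minimum run length above threshold.
#' @param lowpass_hz Optional low-pass cutoff passed to [thumb_speed()].
#' @return Sample index (1-based) of onset.
#' @export
detect_onset <- function(traj, speed_threshold = 2, min_samples = 5L,
                         lowpass_hz = NULL) {
  sp <- thumb_speed(traj, lowpass_hz = lowpass_hz)
  above <- sp > speed_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_samples)
  if (length(ok) == 0) {
    stop("no movement onset: thumb speed never exceeds ", speed_threshold,
         " cm/s for ", min_samples, " consecutive samples", call. = FALSE)
  }
  starts[ok[1]]
}

#' Detect the moment the thumb comes close to the target
#'
#' After the thumb has reached its peak height, the first sample at which it
#' has descended to less than `height_margin` above its initial height marks
#' the end of the analysis window: beyond it the digits may be in contact with
#' the object, so the grip-aperture maximum is only searched before it.
#'
#' @param traj A [as_trajectory()] object.
#' @param height_margin Height margin above the initial thumb height (cm).
#' @return Sample index (1-based) of the near-target moment.
#' @export
detect_near_target <- function(traj, height_margin = 1.0) {
  h <- traj$thumb_z_cm
  h0 <- h[1]
  i_peak <- which.max(h)
  if (h[i_peak] <= h0 + height_margin) {
    stop("thumb height never rises more than ", height_margin,
         " cm above its initial value; trial flagged for exclusion",
         call. = FALSE)
  }
  after <- which(h < h0 + height_margin)
  after <- after[after > i_peak]
  if (length(after) == 0) {
    stop("thumb never descends to within ", height_margin,
         " cm of its initial height; trial flagged for exclusion",
         call. = FALSE)
  }
  after[1]
}

#' Detect all grasp events and extract the maximum grip aperture
#'
#' `grasp_events()` combines onset detection, near-target detection and the MGA
#' search; `extract_mga()` finds the aperture maximum in the window between
#' movement onset and the near-target moment (inclusive), ties broken by the
#' earliest sample.
#'
#' @param traj A [as_trajectory()] object.
#' @param speed_threshold,min_samples,lowpass_hz Passed to [detect_onset()].
#' @param height_margin Passed to [detect_near_target()].
#' @return `grasp_events()` returns a list with `onset_index`,
#'   `peak_thumb_height_index`, `near_target_index`, `mga_index`, `mga_cm`;
#'   `extract_mga()` returns a list with `mga_cm` and `mga_index`.
#' @examples
#' tr <- synth_trajectory(6.5, 4.0, generator_config())
#' grasp_events(tr)$mga_cm
#' @export
grasp_events <- function(traj, speed_threshold = 2, min_samples = 5L,
                         height_margin = 1.0, lowpass_hz = NULL) {
  onset <- detect_onset(traj, speed_threshold, min_samples, lowpass_hz)
  near <- detect_near_target(traj, height_margin)
  if (onset >= near) {
    stop("movement onset (", onset, ") does not precede the near-target moment (",
         near, ")", call. = FALSE)
  }
  mga <- extract_mga(traj, list(onset_index = onset, near_target_index = near))
  list(
    onset_index = onset,
    peak_thumb_height_index = which.max(traj$thumb_z_cm),
    near_target_index = near,
    mga_index = mga$mga_index,
    mga_cm = mga$mga_cm
  )
}

#' @rdname grasp_events
#' @param events A list with `onset_index` and `near_target_index`.
#' @export
extract_mga <- function(traj, events) {
  onset <- events$onset_index
  near <- events$near_target_index
  if (is.null(onset) || is.null(near) || onset > near) {
    stop("empty MGA search window: onset must not come after the near-target moment",
         call. = FALSE)
  }
  ap <- grip_aperture(traj)
  window <- onset:near
  i <- window[which.max(ap[window])]  # which.max keeps the earliest tie
  list(mga_cm = ap[i], mga_index = i)
}

#' Grip aperture at a fixed transport distance
#'
#' Aperture at the first sample where the thumb has travelled at least
#' `distance_cm` along the transport axis from its starting position. Used as
#' a mid-movement checkpoint (20 cm, about two-thirds of the reach) to test
#' whether an illusion effect is present before visual feedback of the hand
#' becomes available.
#'
#' @param traj A [as_trajectory()] object.
#' @param distance_cm Transport displacement (cm).
#' @return A list with `aperture_cm` and `index`.
#' @export
aperture_at_distance <- function(traj, distance_cm = 20) {
  disp <- abs(traj$thumb_x_cm - traj$thumb_x_cm[1])
  idx <- which(disp >= distance_cm)
  if (length(idx) == 0) {
    stop("thumb transport displacement never reaches ", distance_cm, " cm",
         call. = FALSE)
  }
  list(aperture_cm = grip_aperture(traj)[idx[1]], index = idx[1])
}
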