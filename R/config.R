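#' Simulation settings for a grasping-illusion cohort
#'
#' Bundles every parameter of the synthetic-data generator: the study design
#' (participants, bar lengths, repetitions), the illusion model (perceptual and
#' positional illusion strengths, between-participant susceptibility spread),
#' the response models for size matching and for maximum grip aperture (MGA),
#' the grip-control hypothesis, and the trajectory geometry.
#'
#' The defaults emulate the reference study conditions: 19 participants grasp
#' 4 mm thick bars of 1.5, 2.5, 4.0 and 5.0 cm shown in two illusion-inducing
#' contexts (10 repetitions each, 80 trials), matching each bar's length before
#' grasping it. Matched length follows an affine size law with gain 1.10 and
#' multiplicative (Weber) noise of 8%; MGA follows an affine law with slope
#' 0.92 and, under position-based control, additive noise growing mildly with
#' object size (3.2 mm + 0.03 per mm of size, about 4.2 mm on average).
#'
#' @param n_participants Number of simulated participants.
#' @param bar_lengths_cm Physical bar lengths (cm).
#' @param n_reps Repetitions of each stimulus (bar length x configuration).
#' @param perceptual_illusion Difference in perceived size between the two
#'   illusion configurations, as a fraction of object size (population mean).
#' @param position_illusion Difference in perceived edge positions between
#'   configurations, as a fraction of size. Zero for an illusion that leaves
#'   positions untouched; set it positive to emulate an Ebbinghaus-like figure.
#' @param matching_gain Slope of matched length on object size.
#' @param matching_intercept Intercept of the matching size law (cm).
#' @param weber_fraction Multiplicative noise SD of matching (and of the
#'   size-based grip rule), as a fraction of the perceived size.
#' @param mga_slope Slope of MGA on object size.
#' @param mga_intercept Intercept of the MGA size law (cm), the safety-margin
#'   opening of the hand.
#' @param mga_sd_base_mm Additive MGA noise SD at zero size (mm), used by the
#'   position-based rule.
#' @param mga_sd_slope Increase of additive MGA noise SD per unit size
#'   (mm per mm, i.e. dimensionless).
#' @param susceptibility_sd Between-participant SD of illusion susceptibility
#'   (fraction of size). Drawn once per participant and task, which is what
#'   produces across-participant correlations of effects.
#' @param control_hypothesis How the grip is controlled: `"position"` (digits
#'   steered to contact positions; perceived size irrelevant), `"size"` (grip
#'   scaled to perceived size), or `"optimal"` (size rule below `switch_size_cm`,
#'   position rule above it).
#' @param switch_size_cm Crossover size for the `"optimal"` rule (cm).
#' @param movement_duration_s Reach duration (s).
#' @param sampling_rate_hz Marker sampling rate (Hz).
#' @param start_offset_cm Lateral distance from start position to target (cm).
#' @param start_aperture_cm Grip aperture on the starting rod (cm).
#' @param seed Integer seed making a cohort reproducible; `NULL` uses the
#'   current RNG state.
#'
#' @return An object of class `generator_config` (a validated named list).
#' @seealso [simulate_cohort()], [read_config()], [write_config()]
#' @examples
#' cfg <- generator_config(n_participants = 4, n_reps = 3, seed = 7)
#' cfg$bar_lengths_cm
#' @export
generator_config <- function(n_participants = 19,
                             bar_lengths_cm = c(1.5, 2.5, 4.0, 5.0),
                             n_reps = 10,
                             perceptual_illusion = 0.10,
                             position_illusion = 0.0,
                             matching_gain = 1.10,
                             matching_intercept = -0.43,
                             weber_fraction = 0.08,
                             mga_slope = 0.92,
                             mga_intercept = 3.43,
                             mga_sd_base_mm = 3.2,
                             mga_sd_slope = 0.03,
                             susceptibility_sd = 0.03,
                             control_hypothesis = c("position", "size", "optimal"),
                             switch_size_cm = 3.0,
                             movement_duration_s = 0.6,
                             sampling_rate_hz = 200,
                             start_offset_cm = 30,
                             start_aperture_cm = 0.4,
                             seed = NULL) {
  control_hypothesis <- match.arg(control_hypothesis)
  cfg <- list(
    n_participants = n_participants,
    bar_lengths_cm = bar_lengths_cm,
    n_reps = n_reps,
    perceptual_illusion = perceptual_illusion,
    position_illusion = position_illusion,
    matching_gain = matching_gain,
    matching_intercept = matching_intercept,
    weber_fraction = weber_fraction,
    mga_slope = mga_slope,
    mga_intercept = mga_intercept,
    mga_sd_base_mm = mga_sd_base_mm,
    mga_sd_slope = mga_sd_slope,
    susceptibility_sd = susceptibility_sd,
    control_hypothesis = control_hypothesis,
    switch_size_cm = switch_size_cm,
    movement_duration_s = movement_duration_s,
    sampling_rate_hz = sampling_rate_hz,
    start_offset_cm = start_offset_cm,
    start_aperture_cm = start_aperture_cm,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  stop_if(!num1(cfg$n_participants) || cfg$n_participants < 1 ||
            cfg$n_participants != round(cfg$n_participants),
          "'n_participants' must be a positive integer")
  stop_if(!is.numeric(cfg$bar_lengths_cm) || length(cfg$bar_lengths_cm) < 1 ||
            any(!is.finite(cfg$bar_lengths_cm)) || any(cfg$bar_lengths_cm <= 0),
          "'bar_lengths_cm' must be strictly positive lengths")
  stop_if(!num1(cfg$n_reps) || cfg$n_reps < 1 || cfg$n_reps != round(cfg$n_reps),
          "'n_reps' must be a positive integer")
  stop_if(!num1(cfg$perceptual_illusion) || cfg$perceptual_illusion < 0 ||
            cfg$perceptual_illusion >= 1,
          "'perceptual_illusion' must lie in [0, 1)")
  stop_if(!num1(cfg$position_illusion) || cfg$position_illusion < 0 ||
            cfg$position_illusion >= 1,
          "'position_illusion' must lie in [0, 1)")
  stop_if(!num1(cfg$weber_fraction) || cfg$weber_fraction < 0 ||
            cfg$weber_fraction >= 1,
          "'weber_fraction' must lie in [0, 1)")
  for (f in c("matching_gain", "mga_slope", "switch_size_cm",
              "movement_duration_s", "sampling_rate_hz", "start_offset_cm",
              "start_aperture_cm")) {
    stop_if(!num1(cfg[[f]]) || cfg[[f]] <= 0,
            sprintf("'%s' must be strictly positive", f))
  }
  for (f in c("mga_sd_base_mm", "mga_sd_slope", "susceptibility_sd")) {
    stop_if(!num1(cfg[[f]]) || cfg[[f]] < 0,
            sprintf("'%s' must be non-negative", f))
  }
  for (f in c("matching_intercept", "mga_intercept")) {
    stop_if(!num1(cfg[[f]]), sprintf("'%s' must be a finite number", f))
  }
  stop_if(!cfg$control_hypothesis %in% c("position", "size", "optimal"),
          "'control_hypothesis' must be one of 'position', 'size', 'optimal'")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Grasping-illusion generator configuration\n")
  cat(sprintf("  design      : %d participants x %d stimuli x %d reps (%d trials)\n",
              x$n_participants, 2L * length(x$bar_lengths_cm), x$n_reps,
              x$n_participants * 2L * length(x$bar_lengths_cm) * x$n_reps))
  cat(sprintf("  bar lengths : %s cm\n", paste(x$bar_lengths_cm, collapse = ", ")))
  cat(sprintf("  illusion    : perceptual %.3f, positional %.3f (susceptibility SD %.3f)\n",
              x$perceptual_illusion, x$position_illusion, x$susceptibility_sd))
  cat(sprintf("  matching    : %.2f + %.2f s, Weber noise %.2f\n",
              x$matching_intercept, x$matching_gain, x$weber_fraction))
  cat(sprintf("  grasping    : %.2f + %.2f s, control '%s' (switch %.1f cm)\n",
              x$mga_intercept, x$mga_slope, x$control_hypothesis, x$switch_size_cm))
  cat(sprintf("  trajectory  : %.0f cm reach, %.2f s at %.0f Hz\n",
              x$start_offset_cm, x$movement_duration_s, x$sampling_rate_hz))
  if (!is.null(x$seed)) cat(sprintf("  seed        : %d\n", x$seed))
  invisible(x)
}

#' Read or write a generator configuration file
#'
#' Configurations round-trip through a plain YAML key-value file. Every field
#' of [generator_config()] is addressable by name; unknown keys are rejected so
#' that typos do not silently fall back to defaults.
#'
#' @param path File path.
#' @param config A `generator_config` object.
#' @return `read_config()` returns a validated `generator_config`;
#'   `write_config()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_config(generator_config(n_participants = 3), f)
#' read_config(f)$n_participants
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(vals$bar_lengths_cm)) {
    vals$bar_lengths_cm <- as.numeric(unlist(vals$bar_lengths_cm))
  }
  do.call(generator_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  writeLines(yaml::as.yaml(vals, precision = 12L), path)
  invisible(path)
}
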