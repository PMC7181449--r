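#' Perceived size of a bar under the illusion
#'
#' The two illusion-inducing contexts shift perceived length symmetrically
#' around the physical length: the expanding context (several dots, long
#' diagonal) by `+susceptibility/2`, the contracting context (single dot, short
#' diagonal) by `-susceptibility/2`, so the between-configuration difference is
#' exactly `susceptibility * size_cm`.
#'
#' @param size_cm Physical bar length (cm), positive.
#' @param configuration `"expanding"` or `"contracting"` (vectorised).
#' @param susceptibility Illusion susceptibility as a fraction of size.
#' @return Perceived length in cm.
#' @examples
#' perceived_size(2, "expanding", 0.10)    # 2.1
#' perceived_size(2, "contracting", 0.10)  # 1.9
#' @export
perceived_size <- function(size_cm, configuration, susceptibility) {
  if (any(!is.finite(size_cm)) || any(size_cm <= 0)) {
    stop("'size_cm' must be strictly positive", call. = FALSE)
  }
  sgn <- configuration_sign(configuration)
  size_cm * (1 + sgn * susceptibility / 2)
}

configuration_sign <- function(configuration) {
  bad <- !configuration %in% c("expanding", "contracting")
  if (any(bad)) {
    stop("unknown illusion configuration: ",
         paste(unique(configuration[bad]), collapse = ", "),
         " (expected 'expanding' or 'contracting')", call. = FALSE)
  }
  ifelse(configuration == "expanding", 1, -1)
}

#' Draw a cohort of participants with stable illusion susceptibilities
#'
#' Each participant gets three susceptibilities, drawn once and reused for all
#' sizes and repetitions: one for the matching task, one for the size-based
#' grip rule (both centred on `perceptual_illusion`) and one for the positional
#' illusion (centred on `position_illusion`). Keeping them fixed within a
#' participant is what makes illusion effects on small and large objects
#' correlate across participants, while drawing the matching and grasping
#' susceptibilities independently makes cross-task correlations null under
#' position-based control.
#'
#' @param config A [generator_config()].
#' @return A data frame with columns `participant`, `susc_matching`,
#'   `susc_grasp`, `susc_position`.
#' @export
draw_participants <- function(config) {
  n <- config$n_participants
  data.frame(
    participant = sprintf("P%02d", seq_len(n)),
    susc_matching = rnorm(n, config$perceptual_illusion, config$susceptibility_sd),
    susc_grasp = rnorm(n, config$perceptual_illusion, config$susceptibility_sd),
    susc_position = rnorm(n, config$position_illusion, config$susceptibility_sd),
    stringsAsFactors = FALSE
  )
}

#' Simulate matched-length responses
#'
#' A matching response is an affine function of the perceived size with
#' multiplicative (Weber) noise on the size-dependent term:
#' `intercept + gain * perceived * (1 + e)`, `e ~ N(0, weber_fraction)`.
#' Response SD therefore grows in proportion to the perceived size, the
#' signature of Weber's law for length reproduction.
#'
#' @param size_cm Bar length(s), cm.
#' @param configuration Illusion configuration(s).
#' @param susceptibility Matching susceptibility (fraction of size).
#' @param config A [generator_config()].
#' @return Simulated matched length(s) in cm.
#' @examples
#' cfg <- generator_config(weber_fraction = 0, susceptibility_sd = 0)
#' sample_matching(5, "expanding", susceptibility = 0, cfg)  # -0.43 + 1.10*5
#' @export
sample_matching <- function(size_cm, configuration, susceptibility, config) {
  perc <- perceived_size(size_cm, configuration, susceptibility)
  n <- length(perc)
  eps <- if (config$weber_fraction > 0) rnorm(n, 0, config$weber_fraction) else 0
  config$matching_intercept + config$matching_gain * perc * (1 + eps)
}

#' Simulate maximum grip apertures under a control hypothesis
#'
#' Under `"position"` control the digits are steered to the bar's edges, so MGA
#' depends on the physical size and the positional illusion only:
#' `M + k * s * (1 + q_i/2 * sign)` plus additive noise with SD
#' `mga_sd_base_mm/10 + mga_sd_slope * s` (cm). The perceptual size illusion
#' plays no role. Under `"size"` control the grip is scaled to the perceived
#' size with multiplicative Weber noise: `M + k * perceived * (1 + e)`,
#' `e ~ N(0, weber_fraction)`. Under `"optimal"` the size rule is used below
#' `switch_size_cm` and the position rule above it.
#'
#' @param size_cm Bar length(s), cm.
#' @param configuration Illusion configuration(s).
#' @param susceptibility_size Participant's grasp susceptibility to the size
#'   illusion (fraction), used by the size rule.
#' @param susceptibility_position Participant's susceptibility to the
#'   positional illusion (fraction), used by the position rule.
#' @param config A [generator_config()].
#' @param hypothesis Control hypothesis; defaults to `config$control_hypothesis`.
#' @return Simulated MGA(s) in cm.
#' @examples
#' cfg <- generator_config(mga_sd_base_mm = 0, mga_sd_slope = 0)
#' sample_mga(1.5, "expanding", 0, 0, cfg, "position")  # 3.43 + 0.92*1.5
#' @export
sample_mga <- function(size_cm, configuration, susceptibility_size,
                       susceptibility_position, config,
                       hypothesis = config$control_hypothesis) {
  if (length(hypothesis) != 1L ||
      !hypothesis %in% c("position", "size", "optimal")) {
    stop("unknown control hypothesis: ", paste(hypothesis, collapse = ", "),
         call. = FALSE)
  }
  sgn <- configuration_sign(configuration)
  n <- max(length(size_cm), length(sgn))
  size_cm <- rep_len(size_cm, n)
  sgn <- rep_len(sgn, n)

  mga_position <- function(s, sg) {
    sd_cm <- config$mga_sd_base_mm / 10 + config$mga_sd_slope * s
    noise <- if (any(sd_cm > 0)) rnorm(length(s), 0, sd_cm) else 0
    config$mga_intercept +
      config$mga_slope * s * (1 + sg * susceptibility_position / 2) + noise
  }
  mga_size <- function(s, sg) {
    perc <- s * (1 + sg * susceptibility_size / 2)
    eps <- if (config$weber_fraction > 0) {
      rnorm(length(s), 0, config$weber_fraction)
    } else 0
    config$mga_intercept + config$mga_slope * perc * (1 + eps)
  }

  switch(hypothesis,
    position = mga_position(size_cm, sgn),
    size = mga_size(size_cm, sgn),
    optimal = {
      out <- numeric(n)
      small <- size_cm < config$switch_size_cm
      # draw per-branch so the noise model follows the rule actually in force
      if (any(small)) out[small] <- mga_size(size_cm[small], sgn[small])
      if (any(!small)) out[!small] <- mga_position(size_cm[!small], sgn[!small])
      out
    }
  )
}
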