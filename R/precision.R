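#' Precision model for size- versus position-based grip control
#'
#' The model behind the competing predictions. If the grip is scaled to the
#' object's judged size, its precision follows Weber's law: the SD of the
#' aperture grows in proportion to object size. If the digits are steered to
#' judged positions on the object's edges, the SD is independent of size. Both
#' channels may share a size-independent baseline (motor) noise, combined in
#' quadrature:
#' \deqn{SD_{size}(s) = \sqrt{a^2 + (w \cdot s)^2}, \qquad
#'       SD_{pos} = \sqrt{a^2 + c^2}.}
#' The two curves cross at \eqn{s^* = c / w}; an ideal observer using the more
#' precise channel at each size switches from size- to position-based control
#' there. With the default Weber fraction 0.06 and positional noise 1.8 mm the
#' crossover is at 3 cm, the boundary used to define small and large objects.
#'
#' @param weber_fraction Weber fraction of the size channel (dimensionless).
#' @param position_noise_mm Positional noise SD (mm). Defaults to
#'   `weber_fraction * switch_size_cm * 10`, keeping the crossover consistent.
#' @param baseline_mm Size-independent baseline noise (mm), entering both
#'   channels identically; it fattens both curves without moving the crossover.
#' @param switch_size_cm Crossover size (cm); only used to derive
#'   `position_noise_mm` when that is not given.
#' @return An object of class `precision_model`.
#' @examples
#' m <- precision_model()
#' sd_size(3, m)      # 1.8 mm: at the crossover the channels are equally precise
#' sd_position(m)
#' @export
precision_model <- function(weber_fraction = 0.06, position_noise_mm = NULL,
                            baseline_mm = 0, switch_size_cm = 3.0) {
  if (weber_fraction < 0 || baseline_mm < 0) {
    stop("'weber_fraction' and 'baseline_mm' must be non-negative", call. = FALSE)
  }
  if (is.null(position_noise_mm)) {
    position_noise_mm <- weber_fraction * switch_size_cm * 10
  }
  if (position_noise_mm < 0) {
    stop("'position_noise_mm' must be non-negative", call. = FALSE)
  }
  if (weber_fraction > 0) {
    switch_size_cm <- position_noise_mm / weber_fraction / 10
  }
  structure(list(weber_fraction = weber_fraction,
                 position_noise_mm = position_noise_mm,
                 baseline_mm = baseline_mm,
                 switch_size_cm = switch_size_cm),
            class = "precision_model")
}

#' Predicted grip-aperture SD under each control strategy
#'
#' @param size_cm Object size(s), cm (non-negative).
#' @param model A [precision_model()].
#' @return SD in mm.
#' @export
sd_size <- function(size_cm, model = precision_model()) {
  if (any(size_cm < 0)) stop("'size_cm' must be non-negative", call. = FALSE)
  sqrt(model$baseline_mm^2 + (model$weber_fraction * size_cm * 10)^2)
}

#' @rdname sd_size
#' @export
sd_position <- function(model = precision_model()) {
  sqrt(model$baseline_mm^2 + model$position_noise_mm^2)
}

#' @rdname sd_size
#' @export
optimal_sd <- function(size_cm, model = precision_model()) {
  pmin(sd_size(size_cm, model), sd_position(model))
}

#' Predicted illusion effect on maximum grip aperture
#'
#' Assuming the illusion distorts perceived size by `perceptual_effect_pct`
#' (and leaves perceived positions untouched): size-based control transmits the
#' full perceptual effect at every size; position-based control transmits none;
#' optimal switching transmits it only below the crossover size — a step
#' function with its discontinuity exactly at `model$switch_size_cm`.
#'
#' @param size_cm Object size(s), cm.
#' @param hypothesis `"size"`, `"position"` or `"optimal"`.
#' @param perceptual_effect_pct Illusion effect on perceived size (%).
#' @param model A [precision_model()] (supplies the crossover size).
#' @return Predicted effect(s) in percent.
#' @examples
#' predicted_effect(2, "optimal")  # 10: below the 3 cm crossover
#' predicted_effect(4, "optimal")  # 0
#' @export
predicted_effect <- function(size_cm, hypothesis = c("size", "position", "optimal"),
                             perceptual_effect_pct = 10,
                             model = precision_model()) {
  hypothesis <- match.arg(hypothesis)
  switch(hypothesis,
    size = rep_len(perceptual_effect_pct, length(size_cm)),
    position = rep_len(0, length(size_cm)),
    optimal = ifelse(size_cm < model$switch_size_cm, perceptual_effect_pct, 0)
  )
}

#' @export
print.precision_model <- function(x, ...) {
  cat("Grip-precision model\n")
  cat(sprintf("  Weber fraction (size channel) : %.3f\n", x$weber_fraction))
  cat(sprintf("  positional noise              : %.2f mm\n", x$position_noise_mm))
  cat(sprintf("  baseline noise                : %.2f mm\n", x$baseline_mm))
  cat(sprintf("  crossover size                : %.2f cm\n", x$switch_size_cm))
  invisible(x)
}

#' Predict SD curves or illusion-effect curves from a precision model
#'
#' @param object A [precision_model()].
#' @param size_cm Object sizes (cm).
#' @param what `"sd"` for predicted SDs, `"effect"` for predicted illusion
#'   effects.
#' @param perceptual_effect_pct Perceptual illusion effect (%), for
#'   `what = "effect"`.
#' @param ... Unused.
#' @return A data frame with one row per size and one column per strategy.
#' @export
predict.precision_model <- function(object, size_cm = seq(0.5, 8, by = 0.1),
                                    what = c("sd", "effect"),
                                    perceptual_effect_pct = 10, ...) {
  what <- match.arg(what)
  if (what == "sd") {
    data.frame(size_cm = size_cm,
               size = sd_size(size_cm, object),
               position = rep_len(sd_position(object), length(size_cm)),
               optimal = optimal_sd(size_cm, object))
  } else {
    data.frame(size_cm = size_cm,
               size = predicted_effect(size_cm, "size", perceptual_effect_pct, object),
               position = predicted_effect(size_cm, "position", perceptual_effect_pct, object),
               optimal = predicted_effect(size_cm, "optimal", perceptual_effect_pct, object))
  }
}

#' @export
plot.precision_model <- function(x, size_cm = seq(0, 8, by = 0.05), ...) {
  pr <- predict(x, size_cm = size_cm, what = "sd")
  plot(pr$size_cm, pr$size, type = "l", lty = 3, col = "darkgreen", lwd = 2,
       xlab = "object size (cm)", ylab = "predicted SD of grip aperture (mm)",
       ylim = range(0, pr$size, pr$position), ...)
  lines(pr$size_cm, pr$position, lty = 2, col = "cyan4", lwd = 2)
  lines(pr$size_cm, pr$optimal, lty = 1, col = "purple", lwd = 2)
  abline(v = x$switch_size_cm, col = "grey70", lty = 1)
  legend("topleft", legend = c("size", "position", "optimal"),
         lty = c(3, 2, 1), col = c("darkgreen", "cyan4", "purple"),
         lwd = 2, bty = "n")
  invisible(x)
}
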