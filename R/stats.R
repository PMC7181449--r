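#' Squared Pearson correlation with its p value
#'
#' @param x,y Numeric vectors of per-participant values (same length, n >= 3,
#'   no missing values).
#' @return A list with `r2`, `r`, `p` (two-sided, from the t transform) and `n`.
#' @examples
#' pearson_r2(c(1, 2, 3, 4), c(1, 3, 2, 4))$r2  # 0.64
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length",
                                   call. = FALSE)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in 'x' or 'y': correlation undefined", call. = FALSE)
  }
  ct <- cor.test(x, y)
  r <- unname(ct$estimate)
  list(r2 = r^2, r = r, p = ct$p.value, n = length(x))
}

#' Weber-fraction fit: SD against mean
#'
#' Through-origin least-squares slope of within-participant SDs on the
#' corresponding cell means, `sum(m * sd) / sum(m^2)`: the Weber fraction
#' implied by the variability data. Proportionality is the model (a fraction is
#' a line through the origin); an affine variant with a free intercept is
#' available for exploring a size-independent noise floor.
#'
#' @param mean_cm Cell means (positive).
#' @param sd_cm Cell SDs, same length.
#' @param origin Force the fit through the origin (default) or fit an affine
#'   line.
#' @return An object of class `weber_fit`: a list with `fraction`,
#'   `intercept` (0 for the through-origin fit), `r_squared` (of the fitted
#'   line around the mean of `sd_cm`) and `n`.
#' @examples
#' weber_fit(c(1, 2, 4), 0.08 * c(1, 2, 4))$fraction  # 0.08
#' @export
weber_fit <- function(mean_cm, sd_cm, origin = TRUE) {
  keep <- complete.cases(mean_cm, sd_cm)
  m <- mean_cm[keep]; s <- sd_cm[keep]
  if (length(m) < 2) stop("need at least 2 (mean, sd) pairs", call. = FALSE)
  if (all(m == 0)) stop("all means are zero: slope undefined", call. = FALSE)
  if (any(m < 0)) stop("means must be non-negative", call. = FALSE)
  if (origin) {
    fraction <- sum(m * s) / sum(m^2)
    fitted <- fraction * m
    intercept <- 0
  } else {
    fit <- lm(s ~ m)
    fraction <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    fitted <- fitted(fit)
  }
  ss_tot <- sum((s - mean(s))^2)
  r2 <- if (ss_tot > 0) 1 - sum((s - fitted)^2) / ss_tot else NA_real_
  structure(list(fraction = fraction, intercept = intercept,
                 r_squared = r2, n = length(m)),
            class = "weber_fit")
}

#' @export
print.weber_fit <- function(x, ...) {
  cat(sprintf("Weber fit: SD = %s%.4f x mean (%d cells, R^2 = %.3f)\n",
              if (x$intercept != 0) sprintf("%.4f + ", x$intercept) else "",
              x$fraction, x$n, x$r_squared))
  invisible(x)
}

#' Power of a one-sample t test via the noncentral t distribution
#'
#' Power to detect a true mean effect of `effect_mm` (against zero) with
#' between-participant SD `sd_mm` and `n` participants, computed exactly from
#' the noncentral t distribution with noncentrality
#' `effect_mm / sd_mm * sqrt(n)`. Both sidednesses are reported; `alternative`
#' selects which one `power` refers to.
#'
#' @param effect_mm True mean effect (mm, or any unit shared with `sd_mm`).
#' @param sd_mm Between-participant SD of the effect.
#' @param n Number of participants (>= 2).
#' @param alpha Significance level.
#' @param alternative `"two.sided"` (default) or `"one.sided"`.
#' @return A list with `power`, `power_two_sided`, `power_one_sided`, `ncp`,
#'   `df`, `alpha`, `alternative`.
#' @examples
#' power_one_sample_t(effect_mm = 1.5, sd_mm = 1.8, n = 19)$power_two_sided
#' @export
power_one_sample_t <- function(effect_mm, sd_mm, n, alpha = 0.05,
                               alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  if (n < 2 || n != round(n)) stop("'n' must be an integer >= 2", call. = FALSE)
  if (sd_mm <= 0) stop("'sd_mm' must be positive", call. = FALSE)
  df <- n - 1
  ncp <- effect_mm / sd_mm * sqrt(n)
  crit2 <- qt(1 - alpha / 2, df)
  p2 <- pt(crit2, df, ncp = ncp, lower.tail = FALSE) + pt(-crit2, df, ncp = ncp)
  crit1 <- qt(1 - alpha, df)
  p1 <- pt(crit1, df, ncp = ncp, lower.tail = FALSE)
  list(power = if (alternative == "two.sided") p2 else p1,
       power_two_sided = p2, power_one_sided = p1,
       ncp = ncp, df = df, alpha = alpha, alternative = alternative)
}

# mean with a t-based 95% confidence interval across participants
ci_mean <- function(x, level = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  sem <- sd(x) / sqrt(n)
  half <- qt(1 - (1 - level) / 2, n - 1) * sem
  c(mean = m, lower = m - half, upper = m + half, sem = sem, n = n)
}
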