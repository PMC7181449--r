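#' Per-cell central tendency of responses
#'
#' Collapses the trial table to one value per participant x task x bar length x
#' configuration cell. The median is the default central tendency: it is robust
#' to outliers and to the skew of the MGA distribution (an MGA cannot be
#' smaller than the object on a successful grasp, so the mean is biased).
#' Means are available as a robustness option.
#'
#' @param trials A trial data frame (see [simulate_cohort()]) or `grasp_cohort`.
#' @param use_means Use cell means instead of medians.
#' @return A data frame with columns `participant`, `task`, `bar_length_cm`,
#'   `configuration`, `response_cm` (the cell's central value) and `n_trials`.
#'   Cells with no usable response are absent (missing, never zero).
#' @export
median_table <- function(trials, use_means = FALSE) {
  trials <- as_trial_frame(trials)
  trials <- trials[!is.na(trials$response_cm), , drop = FALSE]
  if (nrow(trials) == 0) stop("no usable responses", call. = FALSE)
  centre <- if (use_means) mean else median
  agg <- aggregate(
    response_cm ~ participant + task + bar_length_cm + configuration,
    data = trials, FUN = centre
  )
  n <- aggregate(
    response_cm ~ participant + task + bar_length_cm + configuration,
    data = trials, FUN = length
  )
  agg$n_trials <- n$response_cm
  agg <- agg[order(agg$participant, agg$task, agg$bar_length_cm,
                   agg$configuration), ]
  rownames(agg) <- NULL
  agg
}

as_trial_frame <- function(trials) {
  if (inherits(trials, "grasp_cohort")) trials <- trials$trials
  required <- c("participant", "task", "bar_length_cm", "configuration",
                "response_cm")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trials
}

#' Response-on-size regression slopes
#'
#' For each participant x task, the ordinary least-squares slope (intercept
#' free) of the cell central values on the actual object sizes, across all
#' eight cells. This slope converts raw illusion effects (cm of response) into
#' object-size units. With `per_category = TRUE` separate slopes are fitted for
#' the small and large size categories (the per-size robustness variant).
#'
#' @param medians Output of [median_table()].
#' @param per_category Fit separate slopes per size category.
#' @param category_threshold_cm Boundary between small and large objects (cm).
#' @return A data frame with `participant`, `task`, (optionally `category`,)
#'   `slope` and `intercept`.
#' @export
response_slope <- function(medians, per_category = FALSE,
                           category_threshold_cm = 3.0) {
  if (per_category) {
    medians$category <- size_category(medians$bar_length_cm,
                                      category_threshold_cm)
    groups <- split(medians,
                    list(medians$participant, medians$task, medians$category),
                    drop = TRUE)
  } else {
    groups <- split(medians, list(medians$participant, medians$task),
                    drop = TRUE)
  }
  rows <- lapply(groups, function(g) {
    if (length(unique(g$bar_length_cm)) < 2) {
      stop("cannot fit a response slope for participant ", g$participant[1],
           ", task ", g$task[1], ": fewer than 2 distinct sizes",
           call. = FALSE)
    }
    fit <- lm(response_cm ~ bar_length_cm, data = g)
    out <- data.frame(participant = g$participant[1], task = g$task[1],
                      slope = unname(coef(fit)[2]),
                      intercept = unname(coef(fit)[1]),
                      stringsAsFactors = FALSE)
    if (per_category) out$category <- as.character(g$category[1])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant, out$task), , drop = FALSE]
}

size_category <- function(size_cm, threshold = 3.0) {
  factor(ifelse(size_cm < threshold, "small", "large"),
         levels = c("small", "large"))
}

#' Slope-scaled illusion effects with percentage normalisation
#'
#' For every participant x task x size, the raw illusion effect is the
#' difference between the expanding- and contracting-configuration cell values.
#' It is converted to object-size units by dividing by the participant's
#' response-on-size slope, and then expressed as a percentage. The percentage
#' base is selectable:
#' \describe{
#'   \item{`"size"` (default)}{`100 * (raw/slope) / size`: the slope-scaled
#'     effect relative to the actual object size. Because the slope-scaled
#'     effect is in object-size units, this base recovers the true fractional
#'     size distortion exactly, for matching and grasping alike, regardless of
#'     the (large) intercepts of the two response laws.}
#'   \item{`"response"`}{`100 * (raw/slope) / mean(cell values)`: the
#'     slope-scaled effect relative to the mean response at that size
#'     (the literal textbook normalisation; understates grasping effects
#'     because MGA carries a ~3.4 cm safety-margin intercept).}
#'   \item{`"raw"`}{`100 * raw / mean(cell values)`: no slope scaling at all.}
#' }
#' Percentages are finally averaged over the two sizes within each category
#' (small/large) per participant and task by [category_effects()].
#'
#' @param medians Output of [median_table()].
#' @param slopes Output of [response_slope()]; recomputed if `NULL`.
#' @param percent_base One of `"size"`, `"response"`, `"raw"`.
#' @param per_size_scaling Use per-category slopes (robustness variant).
#' @param category_threshold_cm Boundary between small and large objects (cm).
#' @return A data frame with one row per participant x task x size:
#'   `raw_cm`, `scaled_cm` (object-size units), `percent`, `category`.
#'   Participant x task groups with slope <= 0 are excluded with a warning.
#' @examples
#' cfg <- generator_config(weber_fraction = 0, susceptibility_sd = 0,
#'                         mga_sd_base_mm = 0, mga_sd_slope = 0, seed = 1)
#' m <- median_table(simulate_cohort(cfg))
#' e <- percent_effects(m)
#' subset(e, task == "matching")$percent  # 10 at every size
#' @export
percent_effects <- function(medians, slopes = NULL,
                            percent_base = c("size", "response", "raw"),
                            per_size_scaling = FALSE,
                            category_threshold_cm = 3.0) {
  percent_base <- match.arg(percent_base)
  if (is.null(slopes)) {
    slopes <- response_slope(medians, per_category = per_size_scaling,
                             category_threshold_cm = category_threshold_cm)
  }

  wide <- reshape_configurations(medians)
  wide$category <- size_category(wide$bar_length_cm, category_threshold_cm)

  key <- if (per_size_scaling) {
    paste(wide$participant, wide$task, wide$category)
  } else {
    paste(wide$participant, wide$task)
  }
  slope_key <- if (per_size_scaling) {
    paste(slopes$participant, slopes$task, slopes$category)
  } else {
    paste(slopes$participant, slopes$task)
  }
  wide$slope <- slopes$slope[match(key, slope_key)]

  bad <- !is.na(wide$slope) & wide$slope <= 0
  if (any(bad)) {
    bad_groups <- unique(paste0(wide$participant[bad], "/", wide$task[bad]))
    warning("non-positive response slope; excluding: ",
            paste(bad_groups, collapse = ", "), call. = FALSE)
    wide <- wide[!bad, , drop = FALSE]
  }

  wide$raw_cm <- wide$expanding - wide$contracting
  wide$scaled_cm <- wide$raw_cm / wide$slope
  mean_resp <- (wide$expanding + wide$contracting) / 2
  wide$percent <- switch(percent_base,
    size = 100 * wide$scaled_cm / wide$bar_length_cm,
    response = 100 * wide$scaled_cm / mean_resp,
    raw = 100 * wide$raw_cm / mean_resp
  )
  out <- wide[c("participant", "task", "bar_length_cm", "category",
                "raw_cm", "slope", "scaled_cm", "percent")]
  rownames(out) <- NULL
  out
}

reshape_configurations <- function(medians) {
  exp_ <- medians[medians$configuration == "expanding", ]
  con_ <- medians[medians$configuration == "contracting", ]
  key <- c("participant", "task", "bar_length_cm")
  merged <- merge(exp_[c(key, "response_cm")], con_[c(key, "response_cm")],
                  by = key, suffixes = c(".exp", ".con"))
  names(merged)[names(merged) == "response_cm.exp"] <- "expanding"
  names(merged)[names(merged) == "response_cm.con"] <- "contracting"
  merged[order(merged$participant, merged$task, merged$bar_length_cm), ]
}

#' Category-averaged percent effects
#'
#' Averages the per-size percentages over the two sizes within each category
#' (small / large) for every participant x task. A category average requires
#' both of its sizes to be present; otherwise it is missing.
#'
#' @param effects Output of [percent_effects()].
#' @return A data frame with `participant`, `task`, `category`, `percent`.
#' @export
category_effects <- function(effects) {
  sizes_per_cat <- tapply(effects$bar_length_cm,
                          list(effects$task, effects$category),
                          function(x) length(unique(x)))
  n_expected <- max(sizes_per_cat, na.rm = TRUE)
  agg <- aggregate(percent ~ participant + task + category, data = effects,
                   FUN = mean)
  cnt <- aggregate(percent ~ participant + task + category, data = effects,
                   FUN = length)
  agg$percent[cnt$percent < n_expected] <- NA_real_
  agg <- agg[order(agg$participant, agg$task, agg$category), ]
  rownames(agg) <- NULL
  agg
}

#' Within-participant variability of responses
#'
#' Sample standard deviation (n-1 denominator) and mean of the responses in
#' each participant x task x size x configuration cell: the precision measure
#' behind the Weber-law analysis. Cells with fewer than 2 usable trials are
#' reported with `sd_cm = NA`.
#'
#' @param trials A trial data frame or `grasp_cohort`.
#' @return A data frame with columns `participant`, `task`, `bar_length_cm`,
#'   `configuration`, `mean_cm`, `sd_cm`, `n_trials`.
#' @export
variability_table <- function(trials) {
  trials <- as_trial_frame(trials)
  trials <- trials[!is.na(trials$response_cm), , drop = FALSE]
  agg <- aggregate(
    response_cm ~ participant + task + bar_length_cm + configuration,
    data = trials,
    FUN = function(x) c(mean = mean(x), sd = if (length(x) >= 2) sd(x) else NA_real_,
                        n = length(x))
  )
  out <- data.frame(
    agg[c("participant", "task", "bar_length_cm", "configuration")],
    mean_cm = agg$response_cm[, "mean"],
    sd_cm = agg$response_cm[, "sd"],
    n_trials = as.integer(agg$response_cm[, "n"]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$participant, out$task, out$bar_length_cm,
                   out$configuration), ]
  rownames(out) <- NULL
  out
}
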