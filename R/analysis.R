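#' Fit the full illusion-effect analysis to a cohort
#'
#' The end-to-end analysis of a matching + grasping experiment: per-cell
#' medians, response-on-size slopes, slope-scaled percent illusion effects
#' averaged into size categories, the 2 (size category) x 2 (task)
#' within-subject ANOVA on those percentages, the variability analysis
#' (per-cell SDs with 4 (size) x 2 (configuration) ANOVAs and Weber-fraction
#' fits for each task), the across-participant correlation pattern of effects,
#' and — when trajectories are available — the mid-movement (20 cm) aperture
#' checkpoint. Deterministic given the data and options.
#'
#' If the cohort carries trajectories and grasping responses are missing, the
#' kinematic event chain is run first ([extract_cohort_mga()]); trials whose
#' event detection fails are excluded and counted in the QC summary.
#'
#' @param data A `grasp_cohort` or a trial data frame (see [simulate_cohort()]
#'   for the schema).
#' @param use_means Use cell means instead of medians (robustness variant).
#' @param percent_base Percentage normalisation, see [percent_effects()].
#' @param per_size_scaling Per-category slope scaling (robustness variant).
#' @param category_threshold_cm Boundary between small and large objects (cm).
#' @param checkpoint_cm Transport distance of the mid-movement checkpoint (cm).
#' @param onset_threshold Thumb-speed threshold for movement onset (cm/s).
#' @param height_margin Near-target height margin (cm).
#' @return An object of class `illusion_analysis`; see [summary.illusion_analysis()].
#' @examples
#' cohort <- simulate_cohort(generator_config(seed = 42))
#' fit <- illusion_analysis(cohort)
#' coef(fit)
#' @export
illusion_analysis <- function(data,
                              use_means = FALSE,
                              percent_base = c("size", "response", "raw"),
                              per_size_scaling = FALSE,
                              category_threshold_cm = 3.0,
                              checkpoint_cm = 20,
                              onset_threshold = 2,
                              height_margin = 1.0) {
  percent_base <- match.arg(percent_base)
  qc <- NULL
  cohort <- NULL
  if (inherits(data, "grasp_cohort")) {
    cohort <- data
    needs_extraction <- !is.null(cohort$trajectories) &&
      any(cohort$trials$task == "grasping" & is.na(cohort$trials$response_cm))
    if (needs_extraction) {
      cohort <- extract_cohort_mga(cohort, speed_threshold = onset_threshold,
                                   height_margin = height_margin)
      qc <- cohort$qc
    }
    trials <- cohort$trials
  } else {
    trials <- as_trial_frame(data)
  }

  tasks <- unique(trials$task)
  partial <- !all(c("matching", "grasping") %in% tasks)
  if (partial) {
    warning("dataset contains only the '", paste(tasks, collapse = "','"),
            "' task; report will be partial", call. = FALSE)
  }

  medians <- median_table(trials, use_means = use_means)
  slopes <- response_slope(medians, per_category = per_size_scaling,
                           category_threshold_cm = category_threshold_cm)
  effects <- percent_effects(medians, slopes, percent_base = percent_base,
                             per_size_scaling = per_size_scaling,
                             category_threshold_cm = category_threshold_cm)
  categories <- category_effects(effects)

  anova_effects <- NULL
  if (!partial && !anyNA(categories$percent)) {
    anova_effects <- tryCatch(
      rm_anova(categories, "percent", within = c("category", "task")),
      error = function(e) e
    )
  }

  variability <- variability_table(trials)
  anova_variability <- list()
  weber <- list()
  sd_size_slope <- list()
  for (tk in tasks) {
    v <- variability[variability$task == tk & !is.na(variability$sd_cm), ]
    anova_variability[[tk]] <- tryCatch(
      rm_anova(transform(v, bar_length_cm = factor(bar_length_cm)),
               "sd_cm", within = c("bar_length_cm", "configuration")),
      error = function(e) e
    )
    weber[[tk]] <- weber_fit(v$mean_cm, v$sd_cm)
    # affine SD-on-size slope: the "moderate increase of variability" measure
    sd_size_slope[[tk]] <- unname(coef(lm(sd_cm ~ bar_length_cm, data = v))[2])
  }

  correlations <- if (!partial) effect_correlations(categories) else NULL

  checkpoint <- NULL
  if (!is.null(cohort) && !is.null(cohort$trajectories)) {
    checkpoint <- checkpoint_effect(cohort, distance_cm = checkpoint_cm,
                                    use_means = use_means)
  }

  summary_gains <- slope_summaries(slopes, variability)

  structure(list(
    medians = medians, slopes = slopes, effects = effects,
    categories = categories, anova_effects = anova_effects,
    variability = variability, anova_variability = anova_variability,
    weber = weber, sd_size_slope = sd_size_slope,
    correlations = correlations, checkpoint = checkpoint,
    gains = summary_gains, qc = qc,
    options = list(use_means = use_means, percent_base = percent_base,
                   per_size_scaling = per_size_scaling,
                   category_threshold_cm = category_threshold_cm,
                   checkpoint_cm = checkpoint_cm,
                   onset_threshold = onset_threshold,
                   height_margin = height_margin),
    n_participants = length(unique(trials$participant)),
    tasks = tasks
  ), class = "illusion_analysis")
}

# mean +/- SEM of the per-participant response-on-size slopes, and mean MGA SD
slope_summaries <- function(slopes, variability) {
  out <- list()
  for (tk in unique(slopes$task)) {
    sl <- slopes$slope[slopes$task == tk]
    out[[tk]] <- c(mean = mean(sl), sem = sd(sl) / sqrt(length(sl)))
  }
  v <- variability[variability$task == "grasping" & !is.na(variability$sd_cm), ]
  if (nrow(v) > 0) out$mga_sd_mm <- 10 * mean(v$sd_cm)
  out
}

# across-participant correlation pattern of category effects
effect_correlations <- function(categories) {
  # subsets below are participant-ordered consistently (categories is sorted)
  get <- function(task, cat) {
    categories$percent[categories$task == task & categories$category == cat]
  }
  pairs <- list(
    c("matching small vs grasping small", "matching", "small", "grasping", "small"),
    c("matching large vs grasping large", "matching", "large", "grasping", "large"),
    c("matching small vs matching large", "matching", "small", "matching", "large"),
    c("grasping small vs grasping large", "grasping", "small", "grasping", "large")
  )
  rows <- lapply(pairs, function(p) {
    res <- tryCatch(pearson_r2(get(p[2], p[3]), get(p[4], p[5])),
                    error = function(e) list(r2 = NA, r = NA, p = NA, n = NA))
    data.frame(comparison = p[1], r = res$r, r2 = res$r2, p = res$p,
               n = res$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# illusion effect on grip aperture at a fixed transport distance (mm)
checkpoint_effect <- function(cohort, distance_cm = 20, use_means = FALSE) {
  trials <- cohort$trials
  grasp <- trials[trials$task == "grasping", ]
  ap <- rep(NA_real_, nrow(grasp))
  for (r in seq_len(nrow(grasp))) {
    id <- sprintf("%s_T%03d", grasp$participant[r], grasp$trial_index[r])
    traj <- cohort$trajectories[[id]]
    if (is.null(traj)) next
    res <- tryCatch(aperture_at_distance(traj, distance_cm),
                    error = function(e) NULL)
    if (!is.null(res)) ap[r] <- res$aperture_cm
  }
  grasp$response_cm <- ap
  med <- median_table(grasp, use_means = use_means)
  wide <- reshape_configurations(med)
  wide$raw_cm <- wide$expanding - wide$contracting
  per_pp <- aggregate(raw_cm ~ participant, data = wide, FUN = mean)
  ci <- ci_mean(per_pp$raw_cm)
  list(distance_cm = distance_cm,
       effect_mm = unname(10 * ci["mean"]),
       sem_mm = unname(10 * ci["sem"]),
       per_participant_mm = setNames(10 * per_pp$raw_cm, per_pp$participant))
}

#' @export
print.illusion_analysis <- function(x, ...) {
  cat("Illusion-effect analysis of a matching + grasping cohort\n")
  cat(sprintf("  %d participants; tasks: %s; percent base: '%s'; %s\n",
              x$n_participants, paste(x$tasks, collapse = ", "),
              x$options$percent_base,
              if (x$options$use_means) "cell means" else "cell medians"))
  cm <- coef(x)
  cat("  mean percent illusion effects (across participants):\n")
  for (nm in names(cm)) cat(sprintf("    %-16s %6.2f %%\n", nm, cm[nm]))
  if (!is.null(x$qc) && x$qc$n_flagged > 0) {
    cat(sprintf("  QC: %d grasping trial(s) flagged and excluded\n",
                x$qc$n_flagged))
  }
  invisible(x)
}

#' Mean category effects of a fitted analysis
#'
#' @param object An `illusion_analysis`.
#' @param ... Unused.
#' @return Named vector of across-participant mean percent effects, one per
#'   task x size category.
#' @export
coef.illusion_analysis <- function(object, ...) {
  agg <- aggregate(percent ~ task + category, data = object$categories,
                   FUN = mean, na.rm = TRUE)
  setNames(agg$percent, paste(agg$task, agg$category, sep = "_"))
}

#' Summarise a fitted illusion analysis
#'
#' Prints the category effects with 95% confidence intervals, the 2x2 ANOVA,
#' the task slopes (gain of matched size, slope of MGA on size), the
#' variability analysis (Weber fits, SD-on-size slopes, 4x2 ANOVAs), the
#' correlation pattern and, when available, the mid-movement checkpoint effect.
#'
#' @param object An `illusion_analysis`.
#' @param ... Unused.
#' @return `object`, invisibly.
#' @export
summary.illusion_analysis <- function(object, ...) {
  x <- object
  cat("=== Illusion effects (percent, across participants) ===\n")
  for (tk in unique(x$categories$task)) {
    for (ct in levels(factor(x$categories$category))) {
      v <- x$categories$percent[x$categories$task == tk &
                                  x$categories$category == ct]
      ci <- ci_mean(v)
      cat(sprintf("  %-9s %-6s: %6.2f %% [%.2f, %.2f]\n", tk, ct,
                  ci["mean"], ci["lower"], ci["upper"]))
    }
  }
  if (!is.null(x$anova_effects)) {
    cat("\n=== 2 (size category) x 2 (task) ANOVA on percent effects ===\n")
    if (inherits(x$anova_effects, "error")) {
      cat("  not available:", conditionMessage(x$anova_effects), "\n")
    } else print(x$anova_effects)
  }
  cat("\n=== Response-on-size slopes ===\n")
  for (tk in names(x$gains)) {
    if (tk == "mga_sd_mm") next
    cat(sprintf("  %-9s: %.3f +/- %.3f (mean +/- SEM)\n", tk,
                x$gains[[tk]]["mean"], x$gains[[tk]]["sem"]))
  }
  cat("\n=== Variability ===\n")
  for (tk in names(x$weber)) {
    cat(sprintf("  %-9s: Weber fraction %.4f; SD-on-size slope %.4f\n",
                tk, x$weber[[tk]]$fraction, x$sd_size_slope[[tk]]))
  }
  if (!is.null(x$gains$mga_sd_mm)) {
    cat(sprintf("  mean within-participant MGA SD: %.2f mm\n", x$gains$mga_sd_mm))
  }
  for (tk in names(x$anova_variability)) {
    cat(sprintf("\n  4 (size) x 2 (configuration) ANOVA on %s SDs:\n", tk))
    a <- x$anova_variability[[tk]]
    if (inherits(a, "error")) cat("  not available:", conditionMessage(a), "\n")
    else print(a)
  }
  if (!is.null(x$correlations)) {
    cat("\n=== Across-participant correlations of effects ===\n")
    df <- x$correlations
    df$r <- round(df$r, 3); df$r2 <- round(df$r2, 3); df$p <- signif(df$p, 3)
    print(df, row.names = FALSE)
  }
  if (!is.null(x$checkpoint)) {
    cat(sprintf("\n=== Grip aperture %d cm into the movement ===\n",
                x$checkpoint$distance_cm))
    cat(sprintf("  illusion effect: %.2f mm (SEM %.2f mm)\n",
                x$checkpoint$effect_mm, x$checkpoint$sem_mm))
  }
  invisible(x)
}

#' Plot a fitted illusion analysis
#'
#' `which = 1`: category percent effects with 95% CIs per task. `which = 2` /
#' `3`: within-participant SD against cell mean for matching / grasping, with
#' the through-origin Weber line.
#'
#' @param x An `illusion_analysis`.
#' @param which Which panel(s) to draw.
#' @param ... Unused.
#' @export
plot.illusion_analysis <- function(x, which = 1, ...) {
  for (w in which) {
    if (w == 1) plot_effects_panel(x) else {
      tk <- c("matching", "grasping")[w - 1]
      if (tk %in% names(x$weber)) plot_variability_panel(x, tk)
    }
  }
  invisible(x)
}

plot_effects_panel <- function(x) {
  combos <- expand.grid(category = c("small", "large"),
                        task = c("matching", "grasping"),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$task %in% x$tasks, ]
  stats_ <- t(apply(combos, 1, function(row) {
    v <- x$categories$percent[x$categories$task == row["task"] &
                                x$categories$category == row["category"]]
    ci_mean(v)[c("mean", "lower", "upper")]
  }))
  at <- seq_len(nrow(combos))
  plot(at, stats_[, "mean"], ylim = range(0, stats_), xaxt = "n", pch = 19,
       xlab = "", ylab = "illusion effect (%)", xlim = c(0.5, nrow(combos) + 0.5))
  axis(1, at = at, labels = paste(combos$task, combos$category, sep = "\n"),
       padj = 0.5)
  arrows(at, stats_[, "lower"], at, stats_[, "upper"], angle = 90, code = 3,
         length = 0.05)
  abline(h = 0, col = "grey60")
}

plot_variability_panel <- function(x, task) {
  v <- x$variability[x$variability$task == task & !is.na(x$variability$sd_cm), ]
  cols <- ifelse(v$configuration == "expanding", "blue", "red")
  pch <- ifelse(v$configuration == "expanding", 16, 15)
  plot(v$mean_cm, 10 * v$sd_cm, col = adjustcolor(cols, 0.5), pch = pch,
       xlab = sprintf("mean %s (cm)", if (task == "matching") "matched size"
                      else "maximum grip aperture"),
       ylab = "within-participant SD (mm)")
  abline(0, 10 * x$weber[[task]]$fraction, lty = 2)  # mm per cm of mean
  legend("topleft", c("expanding", "contracting"), col = c("blue", "red"),
         pch = c(16, 15), bty = "n")
}
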