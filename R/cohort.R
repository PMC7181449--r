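#' Simulate a full grasping-illusion cohort
#'
#' Generates the complete trial table of a study: every participant matches and
#' grasps each of the eight stimuli (bar length x illusion configuration)
#' `n_reps` times, in an independent pseudorandom stimulus order per
#' participant. Matching responses and maximum grip apertures are drawn from
#' the models in [sample_matching()] and [sample_mga()]; optionally each grasp
#' also gets a synthetic marker trajectory whose embedded aperture peak equals
#' the drawn MGA, so the kinematic event chain can be exercised end to end.
#'
#' The returned trial table is in long format: one row per participant x trial
#' x task, so a default cohort (19 participants, 80 trials) has 1520 trials and
#' 3040 rows. With `trajectories = TRUE` the grasping `response_cm` is left
#' `NA` (to be recovered by the kinematics stage) and the drawn value is kept
#' in `mga_target_cm`.
#'
#' @param config A [generator_config()]. Its `seed` (if non-`NULL`) makes the
#'   cohort bit-reproducible.
#' @param trajectories Generate per-grasp marker trajectories? Slower; only
#'   needed when the kinematics stage itself is under study.
#' @return An object of class `grasp_cohort`: a list with `trials` (data
#'   frame), `trajectories` (named list or `NULL`), `participants`, `config`
#'   and `provenance`.
#' @examples
#' cohort <- simulate_cohort(generator_config(n_participants = 2, n_reps = 2, seed = 1))
#' head(cohort$trials)
#' @export
simulate_cohort <- function(config = generator_config(), trajectories = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  participants <- draw_participants(config)
  stimuli <- expand.grid(
    bar_length_cm = config$bar_lengths_cm,
    configuration = c("expanding", "contracting"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n_stim <- nrow(stimuli)
  n_trials <- n_stim * config$n_reps

  per_participant <- vector("list", config$n_participants)
  traj_store <- if (trajectories) list() else NULL

  for (i in seq_len(config$n_participants)) {
    pp <- participants[i, ]
    order_idx <- sample(rep(seq_len(n_stim), config$n_reps))
    stim <- stimuli[order_idx, , drop = FALSE]

    match_resp <- sample_matching(stim$bar_length_cm, stim$configuration,
                                  pp$susc_matching, config)
    mga <- sample_mga(stim$bar_length_cm, stim$configuration,
                      pp$susc_grasp, pp$susc_position, config)

    trial_id <- sprintf("%s_T%03d", pp$participant, seq_len(n_trials))
    traj_file <- rep(NA_character_, n_trials)
    if (trajectories) {
      for (j in seq_len(n_trials)) {
        traj_store[[trial_id[j]]] <- synth_trajectory(
          mga[j], stim$bar_length_cm[j], config)
      }
      traj_file <- paste0("trajectories/", trial_id, ".csv")
    }

    base <- data.frame(
      participant = pp$participant,
      trial_index = seq_len(n_trials),
      bar_length_cm = stim$bar_length_cm,
      configuration = stim$configuration,
      stringsAsFactors = FALSE
    )
    matching <- cbind(base, task = "matching", response_cm = match_resp,
                      mga_target_cm = NA_real_,
                      trajectory_file = NA_character_)
    grasping <- cbind(base, task = "grasping",
                      response_cm = if (trajectories) NA_real_ else mga,
                      mga_target_cm = if (trajectories) mga else NA_real_,
                      trajectory_file = traj_file)
    per_participant[[i]] <- rbind(matching, grasping)
  }

  trials <- do.call(rbind, per_participant)
  rownames(trials) <- NULL
  col_order <- c("participant", "trial_index", "task", "bar_length_cm",
                 "configuration", "response_cm", "mga_target_cm",
                 "trajectory_file")
  trials <- trials[col_order]

  structure(list(
    trials = trials,
    trajectories = traj_store,
    participants = participants,
    config = config,
    provenance = list(
      seed = config$seed,
      package_version = as.character(packageVersion("graspillusion")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
    )
  ), class = "grasp_cohort")
}

#' @export
print.grasp_cohort <- function(x, ...) {
  n_trials <- length(unique(paste(x$trials$participant, x$trials$trial_index)))
  cat("Grasping-illusion cohort\n")
  cat(sprintf("  %d participants, %d trials (%d rows: matching + grasping)\n",
              length(unique(x$trials$participant)), n_trials, nrow(x$trials)))
  cat(sprintf("  trajectories: %s\n",
              if (is.null(x$trajectories)) "none (responses pre-extracted)"
              else sprintf("%d stored in memory", length(x$trajectories))))
  if (!is.null(x$config)) {
    cat(sprintf("  control hypothesis: '%s', seed: %s\n",
                x$config$control_hypothesis,
                if (is.null(x$config$seed)) "none" else x$config$seed))
  }
  invisible(x)
}

#' Recover grasping responses from stored trajectories
#'
#' Runs the kinematic event chain ([grasp_events()]) on every grasping trial
#' that has a trajectory but no response, filling `response_cm` with the
#' extracted MGA. Trials whose event detection fails (no movement, thumb never
#' descending) are flagged in a `qc_flag` column and their response left `NA`.
#'
#' @param cohort A `grasp_cohort` with stored trajectories.
#' @param ... Passed to [grasp_events()].
#' @return The cohort with grasping responses filled in and a QC summary in
#'   `cohort$qc`.
#' @export
extract_cohort_mga <- function(cohort, ...) {
  stopifnot(inherits(cohort, "grasp_cohort"))
  if (is.null(cohort$trajectories)) {
    stop("cohort has no stored trajectories", call. = FALSE)
  }
  trials <- cohort$trials
  trials$qc_flag <- NA_character_
  todo <- which(trials$task == "grasping" & is.na(trials$response_cm))
  for (r in todo) {
    id <- sprintf("%s_T%03d", trials$participant[r], trials$trial_index[r])
    traj <- cohort$trajectories[[id]]
    if (is.null(traj)) {
      trials$qc_flag[r] <- "missing trajectory"
      next
    }
    ev <- tryCatch(grasp_events(traj, ...), error = function(e) e)
    if (inherits(ev, "error")) {
      trials$qc_flag[r] <- conditionMessage(ev)
    } else {
      trials$response_cm[r] <- ev$mga_cm
    }
  }
  cohort$trials <- trials
  flagged <- trials[!is.na(trials$qc_flag), c("participant", "trial_index", "qc_flag")]
  cohort$qc <- list(n_extracted = sum(!is.na(trials$response_cm[todo])),
                    n_flagged = nrow(flagged), flagged = flagged)
  cohort
}
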