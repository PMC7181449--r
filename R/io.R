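#' Write a cohort to disk as plain-text files
#'
#' Writes `trials.csv` (long-format schema: `participant`, `trial_index`,
#' `task`, `bar_length_cm`, `configuration`, `response_cm`,
#' `trajectory_file`), one trajectory CSV per stored grasp under
#' `trajectories/`, and a `provenance.yaml` recording the generator
#' configuration, seed, package version and a checksum of the trial table.
#'
#' @param cohort A `grasp_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trials <- function(cohort, dir) {
  stopifnot(inherits(cohort, "grasp_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  schema <- c("participant", "trial_index", "task", "bar_length_cm",
              "configuration", "response_cm", "trajectory_file")
  trials <- cohort$trials[schema]
  write.csv(trials, file.path(dir, "trials.csv"), row.names = FALSE)
  if (!is.null(cohort$trajectories)) {
    dir.create(file.path(dir, "trajectories"), showWarnings = FALSE)
    for (id in names(cohort$trajectories)) {
      write_trajectory(cohort$trajectories[[id]],
                       file.path(dir, "trajectories", paste0(id, ".csv")))
    }
  }
  prov <- cohort$provenance
  prov$trials_md5 <- unname(tools::md5sum(file.path(dir, "trials.csv")))
  if (!is.null(cohort$config)) {
    prov$config <- unclass(cohort$config)
    prov$config <- prov$config[!vapply(prov$config, is.null, logical(1))]
  }
  writeLines(yaml::as.yaml(prov, precision = 12L),
             file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' Read a trial table (native or foreign column layout)
#'
#' Reads a directory written by [write_trials()] or a single trial CSV.
#' Foreign layouts (e.g. a downloaded per-trial deposit) are handled by
#' `columns`, a named character vector mapping native column names to the
#' file's names, and `unit`, which rescales responses to cm. Schema violations
#' are reported by column name; non-numeric responses by row.
#'
#' @param path Directory containing `trials.csv` or path to a CSV file.
#' @param columns Optional mapping, e.g.
#'   `c(participant = "subj", response_cm = "mga")`.
#' @param unit Unit of the response column in the file: `"cm"` (default) or
#'   `"mm"`.
#' @param load_trajectories Read referenced trajectory files (native layout
#'   only).
#' @return A `grasp_cohort` (without a generator config; provenance is loaded
#'   if present).
#' @export
read_trials <- function(path, columns = NULL, unit = c("cm", "mm"),
                        load_trajectories = TRUE) {
  unit <- match.arg(unit)
  is_dir <- dir.exists(path)
  csv <- if (is_dir) file.path(path, "trials.csv") else path
  if (!file.exists(csv)) stop("no trial table at: ", csv, call. = FALSE)
  trials <- read.csv(csv, stringsAsFactors = FALSE)

  if (!is.null(columns)) {
    for (native in names(columns)) {
      foreign <- columns[[native]]
      if (!foreign %in% names(trials)) {
        stop("mapped column '", foreign, "' (for '", native,
             "') not found in file", call. = FALSE)
      }
      names(trials)[names(trials) == foreign] <- native
    }
  }
  required <- c("participant", "task", "bar_length_cm", "configuration",
                "response_cm")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    stop("trial table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"trial_index" %in% names(trials)) {
    trials$trial_index <- stats::ave(seq_len(nrow(trials)), trials$participant,
                                     trials$task, FUN = seq_along)
  }
  if (!"trajectory_file" %in% names(trials)) {
    trials$trajectory_file <- NA_character_
  }

  resp <- trials$response_cm
  if (!is.numeric(resp)) {
    parsed <- suppressWarnings(as.numeric(resp))
    bad <- which(!is.na(resp) & resp != "" & is.na(parsed))
    if (length(bad) > 0) {
      stop("non-numeric response values in row(s): ",
           paste(head(bad, 10), collapse = ", "),
           if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10),
           call. = FALSE)
    }
    trials$response_cm <- parsed
  }
  if (unit == "mm") trials$response_cm <- trials$response_cm / 10

  traj_store <- NULL
  if (is_dir && load_trajectories) {
    refs <- unique(trials$trajectory_file[!is.na(trials$trajectory_file) &
                                            trials$trajectory_file != ""])
    if (length(refs) > 0) {
      traj_store <- list()
      for (ref in refs) {
        f <- file.path(path, ref)
        if (!file.exists(f)) stop("referenced trajectory missing: ", ref,
                                  call. = FALSE)
        id <- sub("\\.csv$", "", basename(ref))
        traj_store[[id]] <- read_trajectory(f)
      }
    }
  }

  provenance <- NULL
  if (is_dir && file.exists(file.path(path, "provenance.yaml"))) {
    provenance <- yaml::read_yaml(file.path(path, "provenance.yaml"))
  }

  structure(list(trials = trials, trajectories = traj_store,
                 participants = NULL, config = NULL, provenance = provenance),
            class = "grasp_cohort")
}
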