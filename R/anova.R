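#' Repeated-measures ANOVA from sums of squares
#'
#' Fully within-subject ANOVA for one or two crossed within-participant
#' factors, computed directly from the classical sums-of-squares
#' decomposition: each effect is tested against its own participant-by-effect
#' interaction (`F = MS_effect / MS_error`). The design must be complete and
#' balanced with exactly one value per participant x cell (aggregate first if
#' necessary). No sphericity correction is applied; for factors with more than
#' two levels the Greenhouse-Geisser epsilon is reported alongside the
#' uncorrected test so the reader can judge how much the nominal p could
#' shrink.
#'
#' @param data A data frame in long format.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of one or two within-participant factor
#'   column names.
#' @param subject Name of the participant identifier column.
#' @return An object of class `rm_anova`: a data frame with one row per effect
#'   and columns `effect`, `df_num`, `df_den`, `ss_effect`, `ss_error`, `F`,
#'   `p`, `gg_epsilon`.
#' @examples
#' d <- expand.grid(participant = paste0("P", 1:6),
#'                  task = c("matching", "grasping"),
#'                  size = c("small", "large"))
#' d$y <- rnorm(nrow(d)) + (d$task == "matching") * 2
#' rm_anova(d, "y", within = c("size", "task"))
#' @export
rm_anova <- function(data, dv, within, subject = "participant") {
  if (!dv %in% names(data)) stop("no column '", dv, "' in data", call. = FALSE)
  if (!subject %in% names(data)) {
    stop("no column '", subject, "' in data", call. = FALSE)
  }
  if (!all(within %in% names(data))) {
    stop("within factor(s) not found: ",
         paste(setdiff(within, names(data)), collapse = ", "), call. = FALSE)
  }
  if (!length(within) %in% 1:2) {
    stop("'within' must name one or two factors", call. = FALSE)
  }
  y <- data[[dv]]
  if (any(is.na(y))) {
    bad <- unique(data[[subject]][is.na(y)])
    stop("missing cells for participant(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  s <- factor(data[[subject]])
  f1 <- factor(data[[within[1]]])
  f2 <- if (length(within) == 2) factor(data[[within[2]]]) else NULL

  cells <- if (is.null(f2)) table(s, f1) else table(s, f1, f2)
  if (any(cells != 1)) {
    idx <- which(apply(cells != 1, 1, any))
    stop("design not balanced (exactly one value per participant and cell ",
         "required); offending participant(s): ",
         paste(levels(s)[idx], collapse = ", "), call. = FALSE)
  }

  n <- nlevels(s)
  g <- mean(y)
  mean_by <- function(...) tapply(y, list(...), mean)

  rows <- list()
  add_effect <- function(name, ss_eff, df_eff, ss_err, df_err, eps = NA_real_) {
    if (ss_err <= 1e-12 * max(ss_eff, 1e-300) && ss_eff > 1e-12) {
      stop("zero error variance for effect '", name,
           "': F is undefined", call. = FALSE)
    }
    f_val <- if (ss_eff <= 1e-12 && ss_err <= 1e-12) 0 else
      (ss_eff / df_eff) / (ss_err / df_err)
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = name, df_num = df_eff, df_den = df_err,
      ss_effect = ss_eff, ss_error = ss_err,
      F = f_val, p = pf(f_val, df_eff, df_err, lower.tail = FALSE),
      gg_epsilon = eps, stringsAsFactors = FALSE
    )
  }

  if (is.null(f2)) {
    a <- nlevels(f1)
    m_s <- mean_by(s); m_a <- mean_by(f1); m_sa <- mean_by(s, f1)
    ss_a <- n * sum((m_a - g)^2)
    ss_sa <- sum((m_sa - outer(m_s, m_a, "+") + g)^2)
    add_effect(within[1], ss_a, a - 1, ss_sa, (a - 1) * (n - 1),
               if (a > 2) gg_epsilon(m_sa) else NA_real_)
  } else {
    a <- nlevels(f1); b <- nlevels(f2)
    m_s <- mean_by(s); m_a <- mean_by(f1); m_b <- mean_by(f2)
    m_ab <- mean_by(f1, f2)
    m_sa <- mean_by(s, f1); m_sb <- mean_by(s, f2)
    y_cells <- tapply(y, list(s, f1, f2), mean)  # one obs per cell

    ss_a <- n * b * sum((m_a - g)^2)
    ss_b <- n * a * sum((m_b - g)^2)
    ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + g)^2)
    ss_sa <- b * sum((m_sa - outer(m_s, m_a, "+") + g)^2)
    ss_sb <- a * sum((m_sb - outer(m_s, m_b, "+") + g)^2)
    ss_total <- sum((y - g)^2)
    ss_s <- a * b * sum((m_s - g)^2)
    ss_sab <- ss_total - ss_s - ss_a - ss_b - ss_ab - ss_sa - ss_sb
    ss_sab <- max(ss_sab, 0)

    add_effect(within[1], ss_a, a - 1, ss_sa, (a - 1) * (n - 1),
               if (a > 2) gg_epsilon(apply(y_cells, c(1, 2), mean)) else NA_real_)
    add_effect(within[2], ss_b, b - 1, ss_sb, (b - 1) * (n - 1),
               if (b > 2) gg_epsilon(apply(y_cells, c(1, 3), mean)) else NA_real_)
    add_effect(paste(within, collapse = ":"), ss_ab, (a - 1) * (b - 1),
               ss_sab, (a - 1) * (b - 1) * (n - 1))
  }

  out <- do.call(rbind, rows)
  attr(out, "subject") <- subject
  attr(out, "n_subjects") <- n
  class(out) <- c("rm_anova", "data.frame")
  out
}

# Greenhouse-Geisser epsilon from the n x k matrix of per-subject level scores
gg_epsilon <- function(scores) {
  k <- ncol(scores)
  S <- stats::cov(scores)
  d <- mean(diag(S))
  sbar <- mean(S)
  row_means <- rowMeans(S)
  num <- (k * (d - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_means^2) + k^2 * sbar^2)
  if (den <= 0) return(NA_real_)
  num / den
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d participants)\n",
              attr(x, "n_subjects")))
  df <- as.data.frame(x)
  df$F <- signif(df$F, 4)
  df$p <- signif(df$p, 3)
  df$ss_effect <- signif(df$ss_effect, 4)
  df$ss_error <- signif(df$ss_error, 4)
  df$gg_epsilon <- ifelse(is.na(df$gg_epsilon), "", signif(df$gg_epsilon, 3))
  print(df, row.names = FALSE)
  invisible(x)
}
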