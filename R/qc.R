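#' Quality-control screen for a study
#'
#' Applies the pre-analysis exclusion rules: a post-removal recording
#' shorter than 10 s (thermal compensation cannot be anchored reliably), a
#' total study duration beyond 15 min (drift accrual out of protocol),
#' residual pressure held on any sensor after catheter exit (pressure
#' applied to the sensors), and a catheter-fold annotation. The verdict is
#' \code{"exclude"} exactly when at least one reason is present.
#'
#' @param study A [pressure_study()].
#' @param min_post_exit Minimum post-removal recording in seconds.
#' @param max_duration Maximum study duration in seconds.
#' @param residual_threshold Residual-pressure threshold in mmHg: a sensor
#'   whose mean over the last second of the recording exceeds this flags
#'   the study.
#' @return An object of class \code{qc_report}: list with
#'   \code{post_exit_duration}, \code{study_duration},
#'   \code{residual_pressure_flag}, \code{fold_flag}, \code{verdict}
#'   (\code{"include"}/\code{"exclude"}) and \code{reasons}.
#' @export
#' @examples
#' st <- simulate_study("nem", drift_model(0, 0), seed = 1, fs = 10)
#' qc_screen(st)$verdict
qc_screen <- function(study, min_post_exit = 10, max_duration = 900,
                      residual_threshold = 20) {
  validate_study(study)
  dur <- study_duration(study)
  post <- dur - study$t_exit
  reasons <- character(0)
  if (post < min_post_exit)
    reasons <- c(reasons, sprintf(
      "post-removal recording < %g s (%.1f s)", min_post_exit, post))
  if (dur > max_duration)
    reasons <- c(reasons, sprintf(
      "study duration exceeds %g min (%.1f min)", max_duration / 60,
      dur / 60))
  n <- ncol(study$pressure)
  idx <- window_idx(dur - 1, dur, study$fs, n)
  resid <- rowMeans(study$pressure[, idx, drop = FALSE])
  residual_flag <- any(resid > residual_threshold)
  if (residual_flag)
    reasons <- c(reasons, sprintf(
      "residual pressure on %d sensor(s) after catheter exit (max %.1f mmHg)",
      sum(resid > residual_threshold), max(resid)))
  fold_flag <- isTRUE(study$ground_truth$fold)
  if (fold_flag)
    reasons <- c(reasons, "catheter fold annotated")
  structure(list(study_id = study$study_id,
                 post_exit_duration = post,
                 study_duration = dur,
                 residual_pressure_flag = residual_flag,
                 fold_flag = fold_flag,
                 verdict = if (length(reasons)) "exclude" else "include",
                 reasons = reasons),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report '%s'>: %s\n", x$study_id, x$verdict))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Screen a list of studies
#'
#' @param studies List of [pressure_study()] objects.
#' @param ... Passed to [qc_screen()].
#' @return A data.frame with one row per study: id, durations, flags,
#'   verdict and collapsed reasons.
#' @export
qc_screen_cohort <- function(studies, ...) {
  reports <- lapply(studies, qc_screen, ...)
  data.frame(
    study_id = vapply(reports, `[[`, character(1), "study_id"),
    post_exit_duration = vapply(reports, `[[`, numeric(1),
                                "post_exit_duration"),
    study_duration = vapply(reports, `[[`, numeric(1), "study_duration"),
    residual_pressure_flag = vapply(reports, `[[`, logical(1),
                                    "residual_pressure_flag"),
    fold_flag = vapply(reports, `[[`, logical(1), "fold_flag"),
    verdict = vapply(reports, `[[`, character(1), "verdict"),
    reasons = vapply(reports, function(r)
      paste(r$reasons, collapse = "; "), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
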