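#' Analysis parameters for pressure-topography metrics
#'
#' Bundles every tunable threshold used by the metric and classification
#' stages. Defaults follow the Chicago conventions for supine 5-mL water
#' swallows on a 36-sensor solid-state catheter: an integrated relaxation
#' pressure (IRP) computed as the lowest 4 s within a 10-s deglutitive
#' window, a 20-mmHg gastric-referenced floor for the distal contractile
#' integral (DCI), a 30-mmHg isobaric contour for the distal latency (DL),
#' and the usual 100 / 450 / 8000 mmHg.s.cm vigor cut-offs with the
#' 15-mmHg supine IRP threshold.
#'
#' @param irp_window Deglutitive window length in seconds over which the
#'   IRP is evaluated, starting at UES-relaxation onset.
#' @param irp_relax_span Duration in seconds of the (noncontiguous) most
#'   relaxed portion of the window averaged into the IRP.
#' @param dci_floor Gastric-referenced pressure floor in mmHg below which
#'   samples do not contribute to the DCI.
#' @param dl_contour Gastric-referenced isobaric contour in mmHg whose
#'   first crossing defines the contraction-front arrival per sensor.
#' @param premature_dl DL threshold in seconds below which a swallow with
#'   adequate vigor is premature (spastic).
#' @param failed_dci DCI in mmHg.s.cm below which a swallow is failed.
#' @param weak_dci_upper DCI in mmHg.s.cm below which a non-failed swallow
#'   is weak (and hence ineffective).
#' @param hyper_dci DCI in mmHg.s.cm above which a swallow counts toward
#'   the hypercontractile (>= 2 swallows) rule.
#' @param irp_threshold Median-IRP cut-off in mmHg separating normal from
#'   elevated EGJ relaxation pressure (strict inequality).
#' @param borderline_irp Length-2 numeric, the half-open interval
#'   (lower, upper] of "borderline" median IRP used by the
#'   achalasia-cannot-rule-out rule; the upper bound must equal
#'   \code{irp_threshold}.
#' @param break_len Length in cm of a defect in the 30-mmHg contour above
#'   which a swallow with adequate vigor is fragmented.
#' @param pressurization_level Gastric-referenced pressure in mmHg that an
#'   isobaric column must reach across the whole esophageal body to count
#'   as panesophageal pressurization.
#' @param pressurization_pct Percent of swallows with panesophageal
#'   pressurization needed as "evidence of pressurization" (type 2
#'   achalasia and the cannot-rule-out rule).
#' @param gastric_sensors Number of sensors immediately distal to the LES
#'   band used as the intragastric pressure reference.
#' @param resting_window Length in seconds of the pre-swallow quiet window
#'   over which sphincter resting pressures are averaged.
#' @param dci_window Length in seconds of the post-onset window integrated
#'   by the DCI.
#'
#' @return An object of class \code{analysis_params} (a named list).
#' @export
#' @examples
#' p <- analysis_params()
#' p$irp_threshold
analysis_params <- function(irp_window = 10,
                            irp_relax_span = 4,
                            dci_floor = 20,
                            dl_contour = 30,
                            premature_dl = 4.5,
                            failed_dci = 100,
                            weak_dci_upper = 450,
                            hyper_dci = 8000,
                            irp_threshold = 15,
                            borderline_irp = c(10, 15),
                            break_len = 5,
                            pressurization_level = 30,
                            pressurization_pct = 20,
                            gastric_sensors = 3,
                            resting_window = 20,
                            dci_window = 15) {
  p <- list(irp_window = irp_window, irp_relax_span = irp_relax_span,
            dci_floor = dci_floor, dl_contour = dl_contour,
            premature_dl = premature_dl, failed_dci = failed_dci,
            weak_dci_upper = weak_dci_upper, hyper_dci = hyper_dci,
            irp_threshold = irp_threshold, borderline_irp = borderline_irp,
            break_len = break_len,
            pressurization_level = pressurization_level,
            pressurization_pct = pressurization_pct,
            gastric_sensors = as.integer(gastric_sensors),
            resting_window = resting_window, dci_window = dci_window)
  num <- vapply(p[setdiff(names(p), "borderline_irp")], is.numeric, logical(1))
  if (!all(num))
    stop("analysis_params: all thresholds must be numeric", call. = FALSE)
  pos <- unlist(p[c("irp_window", "irp_relax_span", "dci_floor", "dl_contour",
                    "premature_dl", "failed_dci", "weak_dci_upper",
                    "hyper_dci", "irp_threshold", "break_len",
                    "pressurization_level", "gastric_sensors",
                    "resting_window", "dci_window")])
  if (any(pos <= 0))
    stop("analysis_params: thresholds must be strictly positive",
         call. = FALSE)
  if (length(borderline_irp) != 2L || borderline_irp[1] >= borderline_irp[2])
    stop("analysis_params: borderline_irp must be an increasing interval",
         call. = FALSE)
  if (borderline_irp[2] != irp_threshold)
    stop("analysis_params: upper borderline_irp bound must equal irp_threshold",
         call. = FALSE)
  structure(p, class = "analysis_params")
}
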