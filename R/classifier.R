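#' Diagnosis labels emitted by the decision tree
#' @return Character vector of the possible labels.
#' @export
diagnosis_labels <- function() {
  c("T1A", "T2A", "T3A", "EGJ_OO", "AC", "ACR", "DES", "HE", "IEM",
    "FP", "DES_IEM", "NEM")
}

#' IRP category
#'
#' Elevated exactly when the median IRP strictly exceeds the threshold
#' (15 mmHg supine); 15.0 itself is normal.
#'
#' @param median_irp Median IRP in mmHg (or a \code{study_metrics}).
#' @param params An [analysis_params()].
#' @return \code{"normal"} or \code{"elevated"}.
#' @export
irp_category <- function(median_irp, params = analysis_params()) {
  if (inherits(median_irp, "study_metrics"))
    median_irp <- median_irp$median_irp
  ifelse(median_irp > params$irp_threshold, "elevated", "normal")
}

#' Classify study metrics into a motility diagnosis
#'
#' Implements the hierarchical decision tree over study-level metrics.
#' With elevated median IRP (> 15 mmHg strictly): 100% failed peristalsis
#' is type 2 achalasia when panesophageal pressurization accompanies at
#' least 20% of swallows, else type 1; otherwise, no intact peristalsis
#' with at least 20% premature vigorous contractions is type 3 achalasia;
#' any remaining evidence of peristalsis is EGJ outflow obstruction. With
#' normal median IRP: 100% failed peristalsis is achalasia-cannot-rule-out
#' when the IRP is borderline (within \code{borderline_irp}) and there is
#' pressurization evidence, else absent contractility; then, in order of
#' precedence, distal esophageal spasm (>= 20% premature vigorous
#' contractions), hypercontractile esophagus (at least two swallows above
#' the hypercontractile DCI), ineffective esophageal motility (> 50%
#' ineffective swallows) and fragmented peristalsis (> 50% fragmented
#' vigorous contractions); spasm and ineffective motility firing together
#' yield the composite DES_IEM. Anything else is normal esophageal
#' motility. Precedence follows the listing order of the defining
#' criteria; all thresholds come from [analysis_params()].
#'
#' @param sm A \code{study_metrics} object (or a list with the same
#'   fields).
#' @param hyper_count Number of swallows with DCI above the
#'   hypercontractile cut-off; defaults to \code{sm$hyper_count}.
#' @param params An [analysis_params()].
#' @return An object of class \code{diagnosis}: list with \code{label}
#'   and \code{rule_trace} (every predicate evaluated, in order, with its
#'   outcome).
#' @export
#' @examples
#' m <- list(median_irp = 8.9, pct_failed = 0, pct_weak = 0,
#'           pct_ineffective = 0, pct_premature = 0, pct_fragmented = 0,
#'           pct_intact = 100, pct_pressurization = 0, hyper_count = 0)
#' classify_diagnosis(m)$label
classify_diagnosis <- function(sm, hyper_count = NULL,
                               params = analysis_params()) {
  if (is.null(hyper_count)) hyper_count <- sm$hyper_count
  if (is.null(hyper_count)) hyper_count <- 0L
  trace <- character(0)
  note <- function(test, val) {
    trace[[length(trace) + 1L]] <<- sprintf("%s: %s", test,
                                            ifelse(val, "yes", "no"))
    val
  }
  pp <- params$pressurization_pct
  elevated <- note(sprintf("median IRP > %g mmHg", params$irp_threshold),
                   sm$median_irp > params$irp_threshold)
  label <- if (elevated) {
    if (note("100% failed peristalsis", sm$pct_failed == 100)) {
      if (note(sprintf("pressurization in >= %g%% of swallows", pp),
               sm$pct_pressurization >= pp)) "T2A" else "T1A"
    } else if (note(
      sprintf("no intact peristalsis and >= 20%% premature vigorous contractions"),
      sm$pct_intact == 0 && sm$pct_premature >= 20)) {
      "T3A"
    } else {
      note("evidence of peristalsis without achalasia criteria", TRUE)
      "EGJ_OO"
    }
  } else {
    if (note("100% failed peristalsis", sm$pct_failed == 100)) {
      borderline <- sm$median_irp > params$borderline_irp[1] &&
        sm$median_irp <= params$borderline_irp[2]
      if (note(sprintf("borderline IRP (%g, %g] with pressurization evidence",
                       params$borderline_irp[1], params$borderline_irp[2]),
               borderline && sm$pct_pressurization >= pp)) "ACR" else "AC"
    } else {
      des <- note(">= 20% premature vigorous contractions",
                  sm$pct_premature >= 20)
      he <- note(sprintf("at least 2 swallows with DCI > %g mmHg.s.cm",
                         params$hyper_dci), hyper_count >= 2)
      iem <- note("> 50% ineffective swallows", sm$pct_ineffective > 50)
      fp <- note("> 50% fragmented vigorous contractions",
                 sm$pct_fragmented > 50)
      if (des && iem) "DES_IEM"
      else if (des) "DES"
      else if (he) "HE"
      else if (iem) "IEM"
      else if (fp) "FP"
      else "NEM"
    }
  }
  structure(list(label = label, rule_trace = trace), class = "diagnosis")
}

#' @export
print.diagnosis <- function(x, ...) {
  cat(sprintf("<diagnosis> %s\n", x$label))
  for (r in x$rule_trace) cat("  ", r, "\n", sep = "")
  invisible(x)
}
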