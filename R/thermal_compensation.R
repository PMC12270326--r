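#' Thermal-compensation condition
#'
#' Names the five analysis conditions compared throughout the package:
#' no compensation (\code{"nontc"}), formal compensation anchored at the
#' end of the waterfall image (\code{"ftc"}, offset 0 s), and compensation
#' anchored 1, 5 or 10 s later (\code{"tc1"}, \code{"tc5"},
#' \code{"tc10"}). Arbitrary nonnegative anchor offsets are allowed for
#' exploration via \code{anchor_offset}.
#'
#' @param name One of \code{"nontc"}, \code{"ftc"}, \code{"tc1"},
#'   \code{"tc5"}, \code{"tc10"}, or \code{"anchored"} with an explicit
#'   \code{anchor_offset}.
#' @param anchor_offset Seconds after catheter exit at which the residual
#'   offsets are measured (ignored for \code{"nontc"}).
#' @return An object of class \code{tc_condition} with fields \code{mode}
#'   (\code{"none"} or \code{"anchored"}), \code{anchor_offset} and
#'   \code{label}.
#' @export
#' @examples
#' tc_condition("tc5")$anchor_offset
tc_condition <- function(name = c("ftc", "nontc", "tc1", "tc5", "tc10",
                                  "anchored"),
                         anchor_offset = NULL) {
  name <- match.arg(name)
  if (name == "anchored") {
    if (is.null(anchor_offset) || anchor_offset < 0)
      stop("tc_condition: explicit anchor_offset >= 0 required", call. = FALSE)
    off <- anchor_offset
  } else {
    off <- switch(name, nontc = NA_real_, ftc = 0, tc1 = 1, tc5 = 5,
                  tc10 = 10)
  }
  structure(list(mode = if (name == "nontc") "none" else "anchored",
                 anchor_offset = off,
                 label = if (name == "anchored")
                   sprintf("tc%g", anchor_offset) else name),
            class = "tc_condition")
}

#' The paper-style set of five compensation conditions
#' @return Named list of [tc_condition()] objects: nontc, ftc, tc1, tc5,
#'   tc10.
#' @export
standard_conditions <- function() {
  nm <- c("nontc", "ftc", "tc1", "tc5", "tc10")
  stats::setNames(lapply(nm, tc_condition), nm)
}

#' Detect the end of the waterfall image
#'
#' Finds the earliest time after the last swallow at which the spatial
#' range of temporally smoothed pressures across all sensors stays below
#' \code{threshold} for at least \code{hold} seconds -- the moment
#' anatomical pressure gives way to atmospheric pressure on every sensor.
#' On simulated studies this agrees with the annotated \code{t_exit}
#' within half a second.
#'
#' @param study A [pressure_study()].
#' @param threshold Spatial pressure range in mmHg below which the
#'   catheter is considered out of the body.
#' @param hold Required duration in seconds of the collapsed state.
#' @param smooth Temporal smoothing window in seconds applied before
#'   computing the spatial range.
#' @return Detected exit time in seconds.
#' @export
detect_waterfall_end <- function(study, threshold = 15, hold = 0.5,
                                 smooth = 0.2) {
  validate_study(study)
  n <- ncol(study$pressure)
  dur <- n / study$fs
  if (dur - study$t_exit < 1)
    stop("detect_waterfall_end: recording must extend >= 1 s beyond catheter exit",
         call. = FALSE)
  t_last <- if (length(study$swallow_onsets))
    max(study$swallow_onsets) else 0
  i0 <- max(1L, window_idx(t_last, dur, study$fs, n)[1])
  P <- study$pressure[, i0:n, drop = FALSE]
  k <- max(1L, round(smooth * study$fs))
  if (k > 1L) {
    kern <- rep(1 / k, k)
    P <- t(apply(P, 1, function(x)
      stats::filter(x, kern, sides = 2)))
  }
  rng <- apply(P, 2, function(col) diff(range(col)))
  below <- !is.na(rng) & rng < threshold
  need <- max(1L, round(hold * study$fs))
  run <- rle(below)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  ok <- which(run$values & run$lengths >= need)
  if (!length(ok))
    stop("catheter exit not detected: pressures never collapse below ",
         threshold, " mmHg", call. = FALSE)
  (i0 - 1L + starts[ok[1]] - 1L) / study$fs
}

#' Estimate per-sensor residual offsets at a post-removal anchor
#'
#' Averages each sensor over the half-open window
#' \eqn{[t_{exit} + a, t_{exit} + a + w)} where \eqn{a} is the condition's
#' anchor offset. Because post-removal anatomical pressure is zero, the
#' window mean estimates the residual thermal drift of that sensor at the
#' anchor time.
#'
#' @param study A [pressure_study()].
#' @param condition An anchored [tc_condition()].
#' @param window Averaging window length in seconds.
#' @return An object of class \code{offset_vector}: list with \code{o}
#'   (mmHg per sensor), \code{anchor_time} (s) and \code{window} (s).
#' @export
estimate_offsets <- function(study, condition = tc_condition("ftc"),
                             window = 0.5) {
  validate_study(study)
  if (!inherits(condition, "tc_condition") || condition$mode != "anchored")
    stop("estimate_offsets: an anchored tc_condition is required",
         call. = FALSE)
  t0 <- study$t_exit + condition$anchor_offset
  dur <- study_duration(study)
  if (t0 + window > dur + 1e-9)
    stop("insufficient post-removal recording: anchor window [",
         sprintf("%.2f, %.2f", t0, t0 + window),
         ") s extends beyond the recording end (", sprintf("%.2f", dur),
         " s)", call. = FALSE)
  idx <- window_idx(t0, t0 + window, study$fs, ncol(study$pressure))
  o <- rowMeans(study$pressure[, idx, drop = FALSE])
  if (any(!is.finite(o)))
    stop("estimate_offsets: non-finite offsets", call. = FALSE)
  structure(list(o = o, anchor_time = t0, window = window,
                 condition = condition$label),
            class = "offset_vector")
}

#' Subtract linearly accrued drift from a study
#'
#' Applies the compensation model
#' \eqn{P'[i,t] = P[i,t] - o_i \, r(t)} with
#' \eqn{r(t) = \min(t, t_{exit}) / t_{exit}}: the correction is zero at
#' recording start, grows linearly to the full measured offset at catheter
#' exit, and stays at the full offset afterwards (so re-running exit
#' detection on a corrected study is stable). With \code{offsets = NULL}
#' (the uncompensated condition) the study is returned unchanged.
#'
#' @param study A [pressure_study()].
#' @param offsets An \code{offset_vector} from [estimate_offsets()] on the
#'   same study, or \code{NULL} for no compensation.
#' @return A re-validated [pressure_study()] with annotations preserved.
#' @export
apply_compensation <- function(study, offsets) {
  validate_study(study)
  if (is.null(offsets)) return(study)
  if (!inherits(offsets, "offset_vector"))
    stop("apply_compensation: 'offsets' must be an offset_vector or NULL",
         call. = FALSE)
  if (length(offsets$o) != study$n_sensors)
    stop("apply_compensation: offset length (", length(offsets$o),
         ") != n_sensors (", study$n_sensors, ")", call. = FALSE)
  tv <- (seq_len(ncol(study$pressure)) - 1L) / study$fs
  r <- pmin(tv, study$t_exit) / study$t_exit
  study$pressure <- study$pressure - outer(offsets$o, r)
  validate_study(study)
  study
}

#' Compensate a study under a named condition
#'
#' Convenience wrapper: estimates offsets at the condition's anchor and
#' subtracts the linear ramp; the uncompensated condition returns the
#' study unchanged.
#'
#' @param study A [pressure_study()].
#' @param condition A [tc_condition()] (or a name accepted by
#'   [tc_condition()]).
#' @param window Anchor averaging window in seconds.
#' @return A compensated [pressure_study()].
#' @export
compensate <- function(study, condition = tc_condition("ftc"),
                       window = 0.5) {
  if (is.character(condition)) condition <- tc_condition(condition)
  if (condition$mode == "none") return(study)
  apply_compensation(study, estimate_offsets(study, condition, window))
}
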