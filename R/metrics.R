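# Chicago-style swallow metrics on a (compensated) pressure topography.
# Every metric is referenced to mean intragastric pressure, including the
# DCI floor and the DL contour, so a spatially uniform baseline shift
# cancels out of all of them.

col_min <- function(M) do.call(pmin, lapply(seq_len(nrow(M)),
                                            function(i) M[i, ]))

#' Landmark set for metric computation
#'
#' Sensor-index ranges for the sphincter bands, the eSleeve, the gastric
#' reference and the esophageal body. Usually produced by
#' [locate_landmarks()]; constructing one directly is useful for toy
#' fixtures.
#'
#' @param ues_band,les_band Integer ranges of the UES and LES
#'   high-pressure zones (proximal to distal, non-overlapping).
#' @param gastric Integer indices of the intragastric reference sensors,
#'   all distal to \code{les_band}.
#' @param body_span Integer range between the UES distal margin and the
#'   LES proximal margin.
#' @param egj_sleeve Sensor range spanning the EGJ high-pressure zone used
#'   by the eSleeve; defaults to \code{les_band}.
#' @return An object of class \code{landmarks}.
#' @export
landmarks <- function(ues_band, les_band, gastric, body_span,
                      egj_sleeve = les_band) {
  lm <- list(ues_band = as.integer(ues_band),
             les_band = as.integer(les_band),
             gastric = as.integer(gastric),
             body_span = as.integer(body_span),
             egj_sleeve = as.integer(egj_sleeve))
  if (max(lm$ues_band) >= min(lm$les_band))
    stop("landmarks: ues_band must lie proximal to les_band", call. = FALSE)
  if (any(lm$gastric <= max(lm$les_band)))
    stop("landmarks: gastric sensors must be distal to les_band",
         call. = FALSE)
  if (length(lm$body_span) &&
      (min(lm$body_span) <= max(lm$ues_band) ||
       max(lm$body_span) >= min(lm$les_band)))
    stop("landmarks: body_span must lie between the sphincter bands",
         call. = FALSE)
  structure(lm, class = "landmarks")
}

#' Locate sphincter bands and gastric reference automatically
#'
#' Averages the topography over the pre-swallow resting window, smooths
#' the spatial profile, and takes the two dominant high-pressure bands as
#' the UES (most proximal) and LES (most distal). Band extent is the
#' contiguous run of sensors above half prominence; the gastric reference
#' is the configured number of sensors immediately distal to the LES band
#' and the body span is everything strictly between the bands. The result
#' is deterministic on fixed input.
#'
#' @param study A [pressure_study()] with at least 10 s of quiet baseline
#'   before the first swallow.
#' @param params An [analysis_params()].
#' @param min_prominence Minimum band prominence above the median resting
#'   profile in mmHg.
#' @return A [landmarks()] object.
#' @export
locate_landmarks <- function(study, params = analysis_params(),
                             min_prominence = 10) {
  validate_study(study)
  t1 <- if (length(study$swallow_onsets)) study$swallow_onsets[1] else
    study$t_exit
  if (t1 < 10)
    stop("locate_landmarks: need >= 10 s of quiet baseline before the first swallow",
         call. = FALSE)
  w0 <- max(0, t1 - 2 - params$resting_window)
  idx <- window_idx(w0, t1 - 2, study$fs, ncol(study$pressure))
  prof <- rowMeans(study$pressure[, idx, drop = FALSE])
  ns <- length(prof)
  sm <- prof
  if (ns >= 3)
    sm[2:(ns - 1)] <- (prof[1:(ns - 2)] + prof[2:(ns - 1)] +
                         prof[3:ns]) / 3
  base <- stats::median(sm)
  is_peak <- vapply(seq_len(ns), function(i) {
    left <- if (i > 1) sm[i - 1] else -Inf
    right <- if (i < ns) sm[i + 1] else -Inf
    sm[i] >= left && sm[i] >= right && (sm[i] - base) > min_prominence
  }, logical(1))
  peaks <- which(is_peak)
  # collapse adjacent plateau peaks
  if (length(peaks) > 1)
    peaks <- peaks[c(TRUE, diff(peaks) > 3)]
  if (length(peaks) < 2)
    stop("landmarks not found: fewer than two distinct high-pressure bands",
         call. = FALSE)
  ues_peak <- peaks[1]
  les_peak <- peaks[length(peaks)]
  # peak finding on the smoothed profile, band extent on the raw one so
  # smoothing bleed cannot pull a flanking sensor into a band
  band_around <- function(pk) {
    cut <- base + 0.5 * (prof[pk] - base)
    lo <- pk; while (lo > 1 && prof[lo - 1] >= cut) lo <- lo - 1
    hi <- pk; while (hi < ns && prof[hi + 1] >= cut) hi <- hi + 1
    lo:hi
  }
  ues <- band_around(ues_peak)
  les <- band_around(les_peak)
  if (max(ues) >= min(les))
    stop("landmarks not found: sphincter bands overlap", call. = FALSE)
  g0 <- max(les) + 1L
  g1 <- g0 + params$gastric_sensors - 1L
  if (g1 > ns)
    stop("landmarks not found: not enough sensors distal to the LES band for the gastric reference",
         call. = FALSE)
  landmarks(ues_band = ues, les_band = les, gastric = g0:g1,
            body_span = (max(ues) + 1L):(min(les) - 1L))
}

# Mean gastric trace over a sample index range.
gastric_trace <- function(study, lm, idx) {
  colMeans(study$pressure[lm$gastric, idx, drop = FALSE])
}

#' Sphincter resting pressures
#'
#' Band-maximum pressure averaged over the pre-swallow resting window,
#' referenced to the mean gastric pressure over the same window.
#'
#' @param study A [pressure_study()].
#' @param lm A [landmarks()] object.
#' @param params An [analysis_params()].
#' @return Named numeric vector \code{c(uesp =, lesp =)} in mmHg.
#' @export
resting_pressures <- function(study, lm, params = analysis_params()) {
  validate_study(study)
  t1 <- if (length(study$swallow_onsets)) study$swallow_onsets[1] else
    study$t_exit
  w0 <- max(0, t1 - 2 - params$resting_window)
  w1 <- t1 - 2
  if (w1 <= w0)
    stop("resting_pressures: resting window is empty", call. = FALSE)
  if (any(study$swallow_onsets >= w0 & study$swallow_onsets < w1))
    stop("resting_pressures: resting window overlaps a swallow",
         call. = FALSE)
  idx <- window_idx(w0, w1, study$fs, ncol(study$pressure))
  g <- mean(gastric_trace(study, lm, idx))
  band_max <- function(band)
    mean(apply(study$pressure[band, idx, drop = FALSE], 2, max))
  c(uesp = band_max(lm$ues_band) - g, lesp = band_max(lm$les_band) - g)
}

#' Integrated relaxation pressure (eSleeve, lowest 4 of 10 s)
#'
#' The eSleeve signal is the instantaneous minimum over the EGJ sleeve
#' sensors; the IRP is the mean of the lowest \code{irp_relax_span}
#' seconds' worth of samples (not necessarily contiguous) of the
#' gastric-referenced sleeve signal within the deglutitive window
#' \eqn{[onset, onset + irp\_window)}.
#'
#' @param study A [pressure_study()].
#' @param lm A [landmarks()] object.
#' @param onset UES-relaxation onset of the swallow in seconds.
#' @param params An [analysis_params()].
#' @return IRP in mmHg.
#' @export
compute_irp <- function(study, lm, onset, params = analysis_params()) {
  if (onset + params$irp_window > study$t_exit + 1e-9)
    stop("compute_irp: deglutitive window truncated by catheter exit",
         call. = FALSE)
  idx <- window_idx(onset, onset + params$irp_window, study$fs,
                    ncol(study$pressure))
  sleeve <- col_min(study$pressure[lm$egj_sleeve, idx, drop = FALSE])
  x <- sleeve - gastric_trace(study, lm, idx)
  k <- round(params$irp_relax_span * study$fs)
  if (k >= length(x)) return(mean(x))
  mean(sort(x, partial = k)[seq_len(k)])
}

#' Distal contractile integral
#'
#' Sums the gastric-referenced pressure excess above the
#' \code{dci_floor} over the esophageal body and the contraction window
#' \eqn{[onset, onset + dci\_window)} (clipped at catheter exit), scaled
#' by sample duration and sensor spacing, yielding mmHg.s.cm.
#'
#' @inheritParams compute_irp
#' @return DCI in mmHg.s.cm (nonnegative).
#' @export
compute_dci <- function(study, lm, onset, params = analysis_params()) {
  if (!length(lm$body_span))
    stop("compute_dci: empty body span", call. = FALSE)
  idx <- window_idx(onset, min(onset + params$dci_window, study$t_exit),
                    study$fs, ncol(study$pressure))
  g <- gastric_trace(study, lm, idx)
  x <- study$pressure[lm$body_span, idx, drop = FALSE] -
    rep(g + params$dci_floor, each = length(lm$body_span))
  sum(pmax(x, 0)) * study$spacing / study$fs
}

# First crossing time of the gastric-referenced dl_contour per body
# sensor, NA where the contour is never reached in the window.
front_arrivals <- function(study, lm, onset, params) {
  idx <- window_idx(onset, min(onset + params$dci_window, study$t_exit),
                    study$fs, ncol(study$pressure))
  g <- gastric_trace(study, lm, idx)
  M <- study$pressure[lm$body_span, idx, drop = FALSE] -
    rep(g, each = length(lm$body_span))
  above <- M >= params$dl_contour
  first <- apply(above, 1, function(row) {
    w <- which(row); if (length(w)) w[1] else NA_integer_
  })
  (idx[1] - 1L + first - 1L) / study$fs
}

#' Distal latency and contractile deceleration point
#'
#' Per body sensor, the contraction-front arrival is the first crossing of
#' the gastric-referenced 30-mmHg contour after onset. A continuous
#' two-segment line is least-squares fitted to (distance, arrival) for
#' every admissible interior breakpoint; the breakpoint with minimal
#' residual sum of squares (earliest on ties) is the contractile
#' deceleration point (CDP) and DL is the observed arrival at the CDP
#' minus the onset. DL is undefined (NA) for failed swallows whose contour
#' never reaches the distal body.
#'
#' @inheritParams compute_irp
#' @param min_sensors Minimum number of sensors with defined arrivals.
#' @return List with \code{dl} (s, NA if undefined), \code{cdp_sensor}
#'   (absolute sensor index or NA), and \code{arrivals} (per body sensor,
#'   seconds, NA where the contour is not reached).
#' @export
compute_dl <- function(study, lm, onset, params = analysis_params(),
                       min_sensors = 6) {
  arr <- front_arrivals(study, lm, onset, params)
  def <- which(!is.na(arr))
  nb <- length(lm$body_span)
  reaches_distal <- length(def) && max(def) >= nb - 2L
  if (length(def) < max(min_sensors, 4L) || !reaches_distal)
    return(list(dl = NA_real_, cdp_sensor = NA_integer_, arrivals = arr))
  x <- (def - 1) * study$spacing
  y <- arr[def]
  m <- length(def)
  best <- NULL; best_rss <- Inf
  for (bi in 2:(m - 1)) {
    c0 <- x[bi]
    X <- cbind(1, x, pmax(x - c0, 0))
    fit <- stats::.lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss - 1e-12) { best_rss <- rss; best <- bi }
  }
  cdp_body <- def[best]
  list(dl = y[best] - onset,
       cdp_sensor = lm$body_span[cdp_body],
       arrivals = arr)
}

#' Length of the largest defect in the contraction contour
#'
#' Longest run of body sensors whose gastric-referenced pressure never
#' reaches the DL contour during the contraction window, counted strictly
#' between sensors that do reach it (an interior break in the wave front),
#' in cm.
#'
#' @inheritParams compute_irp
#' @return Break length in cm (0 when the contour is unbroken, NA when no
#'   sensor reaches the contour).
#' @export
contour_break_length <- function(study, lm, onset,
                                 params = analysis_params()) {
  arr <- front_arrivals(study, lm, onset, params)
  def <- which(!is.na(arr))
  if (!length(def)) return(NA_real_)
  lo <- min(def); hi <- max(def)
  if (hi - lo < 1) return(0)
  inner <- is.na(arr[lo:hi])
  if (!any(inner)) return(0)
  r <- rle(inner)
  max(r$lengths[r$values]) * study$spacing
}

#' Panesophageal pressurization test
#'
#' TRUE when, at any instant of the deglutitive window, the
#' gastric-referenced pressure of every body-span sensor simultaneously
#' reaches the pressurization level (an isobaric column spanning the
#' whole esophageal body).
#'
#' @inheritParams compute_irp
#' @return Logical.
#' @export
detect_pressurization <- function(study, lm, onset,
                                  params = analysis_params()) {
  idx <- window_idx(onset, min(onset + params$irp_window, study$t_exit),
                    study$fs, ncol(study$pressure))
  g <- gastric_trace(study, lm, idx)
  M <- study$pressure[lm$body_span, idx, drop = FALSE] -
    rep(g, each = length(lm$body_span))
  any(col_min(M) >= params$pressurization_level)
}

#' Classify one swallow's strength and pattern
#'
#' Strength: failed below the failed-DCI cut-off, weak below the upper
#' weak cut-off, normal-strength otherwise (failed and weak together are
#' ineffective). Pattern: failed swallows carry only the failed label;
#' otherwise premature when DL is short with adequate vigor, fragmented
#' when the contour break is long with adequate vigor, intact otherwise
#' (so weak swallows still carry a pattern label).
#'
#' @param irp,dci,dl,break_length,pressurization Per-swallow metric
#'   values; \code{dl}/\code{break_length} may be NA.
#' @param params An [analysis_params()].
#' @return A list of class \code{swallow_metrics} with the inputs plus
#'   \code{strength_label}, \code{pattern_label} and \code{hyper}
#'   (counts toward the hypercontractile rule).
#' @export
classify_swallow <- function(irp, dci, dl, break_length, pressurization,
                             params = analysis_params()) {
  strength <- if (dci < params$failed_dci) "failed"
  else if (dci < params$weak_dci_upper) "weak"
  else "normal"
  pattern <- if (strength == "failed") "failed"
  else if (!is.na(dl) && dl < params$premature_dl &&
           dci > params$weak_dci_upper) "premature"
  else if (!is.na(break_length) && break_length > params$break_len &&
           dci > params$weak_dci_upper) "fragmented"
  else "intact"
  structure(list(irp = irp, dci = dci, dl = dl,
                 break_length = break_length,
                 pressurization = isTRUE(pressurization),
                 strength_label = strength, pattern_label = pattern,
                 hyper = dci > params$hyper_dci),
            class = "swallow_metrics")
}

#' Aggregate per-swallow metrics into study-level metrics
#'
#' Medians are taken over defined values; percentages are
#' \eqn{100 \times count / n} over the wet swallows, so every percentage
#' is a multiple of \code{100/n}. Ineffective is failed plus weak.
#'
#' @param swallows List of [classify_swallow()] results.
#' @param uesp,lesp Sphincter resting pressures in mmHg.
#' @param params An [analysis_params()].
#' @return An object of class \code{study_metrics}.
#' @export
summarize_study <- function(swallows, uesp = NA_real_, lesp = NA_real_,
                            params = analysis_params()) {
  n <- length(swallows)
  if (!n) stop("summarize_study: no classified swallows", call. = FALSE)
  gv <- function(f) vapply(swallows, `[[`, numeric(1), f)
  gs <- function(f) vapply(swallows, `[[`, character(1), f)
  pat <- gs("pattern_label"); str_ <- gs("strength_label")
  dl <- gv("dl")
  pct <- function(k) 100 * k / n
  out <- list(
    uesp = as.numeric(uesp), lesp = as.numeric(lesp),
    median_irp = stats::median(gv("irp")),
    median_dci = stats::median(gv("dci")),
    median_dl = if (all(is.na(dl))) NA_real_ else
      stats::median(dl, na.rm = TRUE),
    pct_failed = pct(sum(str_ == "failed")),
    pct_weak = pct(sum(str_ == "weak")),
    pct_ineffective = pct(sum(str_ %in% c("failed", "weak"))),
    pct_premature = pct(sum(pat == "premature")),
    pct_fragmented = pct(sum(pat == "fragmented")),
    pct_intact = pct(sum(pat == "intact")),
    pct_pressurization = pct(sum(vapply(swallows, `[[`, logical(1),
                                        "pressurization"))),
    hyper_count = sum(vapply(swallows, `[[`, logical(1), "hyper")),
    n_swallows = n)
  structure(out, class = "study_metrics")
}

#' @export
print.study_metrics <- function(x, ...) {
  cat(sprintf(
    "<study_metrics> UESP %.1f, LESP %.1f, IRP %.1f mmHg; DCI %.0f mmHg.s.cm; DL %.1f s\n",
    x$uesp, x$lesp, x$median_irp, x$median_dci, x$median_dl))
  cat(sprintf(
    "  failed %g%%, weak %g%%, ineffective %g%%, premature %g%%, fragmented %g%%, intact %g%%, pressurization %g%% (n=%d)\n",
    x$pct_failed, x$pct_weak, x$pct_ineffective, x$pct_premature,
    x$pct_fragmented, x$pct_intact, x$pct_pressurization, x$n_swallows))
  invisible(x)
}

#' Full metric analysis of one study under a compensation condition
#'
#' Compensates the study (unless \code{condition} is NULL or the
#' uncompensated condition), locates landmarks, computes sphincter resting
#' pressures and the per-swallow metric set, and aggregates them.
#'
#' @param study A [pressure_study()].
#' @param condition A [tc_condition()], condition name, or NULL for no
#'   compensation.
#' @param params An [analysis_params()].
#' @return A \code{study_metrics} object whose \code{swallows} attribute
#'   holds the per-swallow [classify_swallow()] results.
#' @export
analyze_study <- function(study, condition = NULL,
                          params = analysis_params()) {
  if (!is.null(condition)) study <- compensate(study, condition)
  lm <- locate_landmarks(study, params)
  rp <- resting_pressures(study, lm, params)
  sw <- lapply(study$swallow_onsets, function(o) {
    irp <- compute_irp(study, lm, o, params)
    dci <- compute_dci(study, lm, o, params)
    dlr <- compute_dl(study, lm, o, params)
    brk <- contour_break_length(study, lm, o, params)
    prs <- detect_pressurization(study, lm, o, params)
    classify_swallow(irp, dci, dlr$dl, brk, prs, params)
  })
  sm <- summarize_study(sw, rp["uesp"], rp["lesp"], params)
  attr(sm, "swallows") <- sw
  attr(sm, "landmarks") <- lm
  sm
}
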