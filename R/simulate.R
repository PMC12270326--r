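# Synthetic 10-swallow supine pressure-topography generator.
#
# Fixed catheter geometry (36 sensors, 1 cm spacing): UES high-pressure
# band at sensors 3-5, esophageal body 6-29, LES band 30-32, intragastric
# sensors 33-36. The contraction wave is a Gaussian ridge (temporal sd
# 0.8 s) whose center propagates distally at the archetype's front
# velocity and decelerates to 1.2 cm/s at the contractile deceleration
# point, 3 cm above the LES band.

SIM_UES <- 3:5
SIM_BODY <- 6:29
SIM_LES <- 30:32
SIM_GASTRIC <- 33:36
SIM_CDP_SENSOR <- 27L
SIM_WAVE_SIGMA <- 0.8
SIM_WAVE_LAT <- 1.0
SIM_V_DISTAL <- 1.2

# Evaluate a function under a fixed seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Smooth boxcar on [t0, t1) with raised-cosine ramps of length `ramp`.
smooth_box <- function(tv, t0, t1, ramp = 0.3) {
  w <- numeric(length(tv))
  up <- tv >= t0 & tv < t0 + ramp
  hold <- tv >= t0 + ramp & tv < t1 - ramp
  down <- tv >= t1 - ramp & tv < t1
  w[up] <- 0.5 * (1 - cos(pi * (tv[up] - t0) / ramp))
  w[hold] <- 1
  w[down] <- 0.5 * (1 - cos(pi * (t1 - tv[down]) / ramp))
  w
}

#' Simulate one 10-swallow supine manometry study
#'
#' Generates a [pressure_study()] following the standard supine wet-swallow
#' protocol: a quiet accommodation baseline, \code{n_swallows} sequential
#' swallows at fixed intervals, catheter withdrawal at \code{t_exit} (the
#' instant the waterfall image ends and all sensors read atmospheric
#' pressure plus drift), and a short post-removal tail used by thermal
#' compensation. Sphincter zones carry a respiratory sinusoid; measurement
#' noise is Gaussian, with a larger in-body sd (physiological plus
#' electronic artifact) than after withdrawal (electronic only). Additive
#' per-sensor thermal drift follows the [drift_model()]; post-exit
#' anatomical pressure is zero, so the residual baseline equals the drift.
#'
#' The returned study's \code{ground_truth} records the archetype label,
#' the drawn drift amplitudes, the instantaneous residual drift at the
#' post-removal anchor offsets 0, 1, 5 and 10 s, per-swallow wave types
#' and any planted quality-control violation.
#'
#' @param archetype An [archetype_spec()] or a preset name for
#'   [archetype()].
#' @param drift A [drift_model()]; use \code{drift_model(mu = 0, sigma = 0)}
#'   for a drift-free study.
#' @param seed Integer seed; fixed seed gives a byte-identical study.
#' @param fs Sampling rate in Hz.
#' @param n_swallows Number of wet swallows.
#' @param first_onset Time of the first swallow onset in seconds.
#' @param swallow_spacing Interval between swallow onsets in seconds.
#' @param exit_gap Quiet interval between the last swallow onset and
#'   catheter withdrawal in seconds.
#' @param post_exit Recorded tail after withdrawal in seconds.
#' @param noise_sd In-body measurement noise sd in mmHg (0 disables).
#' @param post_exit_noise_sd Post-withdrawal noise sd in mmHg.
#' @param resp_amplitude Amplitude of the respiratory sinusoid on the
#'   sphincter bands in mmHg.
#' @param qc_violation Planted protocol violation: \code{"none"},
#'   \code{"short_tail"} (post-removal recording shorter than 10 s),
#'   \code{"overlong"} (study duration beyond 15 min), \code{"fold"}
#'   (catheter-fold annotation) or \code{"residual"} (pressure held on a
#'   block of sensors after withdrawal).
#' @param study_id Optional identifier; a default is derived from the
#'   label and seed.
#' @return A validated [pressure_study()] with simulator ground truth.
#' @export
#' @examples
#' st <- simulate_study("nem", drift_model(mu = 0, sigma = 0), seed = 1,
#'                      fs = 20)
#' st$t_exit
simulate_study <- function(archetype = "nem",
                           drift = drift_model(),
                           seed = 1L,
                           fs = 50,
                           n_swallows = 10,
                           first_onset = 30,
                           swallow_spacing = 25,
                           exit_gap = 45,
                           post_exit = 12,
                           noise_sd = 1,
                           post_exit_noise_sd = 0.2,
                           resp_amplitude = 1.5,
                           qc_violation = c("none", "short_tail",
                                            "overlong", "fold", "residual"),
                           study_id = NULL) {
  if (is.character(archetype)) archetype <- archetype(archetype)
  if (!inherits(archetype, "archetype_spec"))
    stop("simulate_study: 'archetype' must be an archetype_spec",
         call. = FALSE)
  qc_violation <- match.arg(qc_violation)
  if (qc_violation == "short_tail") post_exit <- 8
  if (qc_violation == "overlong") first_onset <- first_onset + 610

  a <- archetype
  n_sensors <- 36L
  t_exit <- first_onset + (n_swallows - 1) * swallow_spacing + exit_gap
  n <- round((t_exit + post_exit) * fs)
  tv <- (seq_len(n) - 1L) / fs
  in_body <- tv < t_exit - 1e-9

  base <- numeric(n_sensors)
  base[SIM_UES] <- c(0.85, 1, 0.85) * a$ues_peak
  base[SIM_LES] <- c(0.85, 1, 0.85) * a$les_rest
  base[SIM_GASTRIC] <- a$gastric_pressure
  relax_abs <- a$gastric_pressure + a$relax_residual

  onsets <- first_onset + (seq_len(n_swallows) - 1L) * swallow_spacing
  body_x <- (SIM_BODY - SIM_BODY[1]) * 1.0   # cm from body start
  cdp_x <- (SIM_CDP_SENSOR - SIM_BODY[1]) * 1.0

  with_seed(seed, {
    D <- draw_drift_amplitudes(drift, n_sensors)
    u <- stats::runif(n_swallows)
    cuts <- cumsum(c(a$p_failed, a$p_weak, a$p_premature, a$p_fragmented,
                     a$p_hyper))
    types <- c("failed", "weak", "premature", "fragmented", "hyper",
               "normal")[findInterval(u, c(0, cuts)) ]
    press <- stats::runif(n_swallows) < a$p_pressurization
    amps <- vapply(types, function(ty) switch(ty,
      failed = 0,
      weak = stats::rnorm(1, a$amp_weak_mean, a$amp_weak_sd),
      hyper = stats::rnorm(1, a$amp_hyper_mean, a$amp_hyper_sd),
      stats::rnorm(1, a$amp_mean, a$amp_sd)), numeric(1))

    P <- outer(base, as.numeric(in_body))
    resp <- resp_amplitude * sin(2 * pi * 0.25 * tv) * in_body
    for (r in c(SIM_UES, SIM_LES)) P[r, ] <- P[r, ] + resp

    for (k in seq_len(n_swallows)) {
      o <- onsets[k]
      # UES relaxation: brief near-complete drop of the UES band.
      wu <- smooth_box(tv, o, o + 0.8, ramp = 0.15)
      iu <- which(wu > 0)
      for (r in SIM_UES)
        P[r, iu] <- P[r, iu] + (2 - base[r]) * wu[iu]
      # Deglutitive EGJ relaxation (or impaired residual for achalasia).
      wl <- smooth_box(tv, o + 0.3, o + 7.8, ramp = 0.3)
      il <- which(wl > 0)
      for (r in SIM_LES)
        P[r, il] <- P[r, il] + (relax_abs - base[r]) * wl[il]
      # Peristaltic ridge.
      ty <- types[k]
      if (ty != "failed") {
        v1 <- if (ty == "premature") a$v_premature else a$v_normal
        centers <- o + SIM_WAVE_LAT +
          ifelse(body_x <= cdp_x, body_x / v1,
                 cdp_x / v1 + (body_x - cdp_x) / SIM_V_DISTAL)
        amp_j <- rep(amps[k], length(SIM_BODY))
        if (ty == "fragmented")
          amp_j[SIM_BODY %in% 14:20] <- amps[k] * 0.25
        for (jj in seq_along(SIM_BODY)) {
          c_j <- centers[jj]
          idx <- window_idx(c_j - 4 * SIM_WAVE_SIGMA,
                            min(c_j + 4 * SIM_WAVE_SIGMA, t_exit), fs, n)
          if (length(idx))
            P[SIM_BODY[jj], idx] <- P[SIM_BODY[jj], idx] +
              amp_j[jj] *
              exp(-((tv[idx] - c_j)^2) / (2 * SIM_WAVE_SIGMA^2))
        }
      }
      # Panesophageal pressurization: brief isobaric column over the body.
      if (press[k]) {
        wp <- smooth_box(tv, o + 2, o + 2.3, ramp = 0.02)
        ip <- which(wp > 0)
        P[SIM_BODY, ip] <- P[SIM_BODY, ip] +
          rep((a$gastric_pressure + 33) * wp[ip], each = length(SIM_BODY))
      }
    }

    P <- P + drift_trajectory(drift, D, tv, t_exit)
    if (qc_violation == "residual")
      P[10:14, !in_body] <- P[10:14, !in_body] + 30
    if (noise_sd > 0 || post_exit_noise_sd > 0) {
      sd_col <- ifelse(in_body, noise_sd, post_exit_noise_sd)
      noise <- matrix(stats::rnorm(n_sensors * n), n_sensors, n)
      P <- P + noise * rep(sd_col, each = n_sensors)
    }

    gt <- list(label = a$label,
               drift_amplitude = D,
               drift_at_anchor = lapply(
                 stats::setNames(c(0, 1, 5, 10),
                                 c("a0", "a1", "a5", "a10")),
                 function(an) drift_at_anchor(drift, D, t_exit, an)),
               swallow_types = types,
               pressurization = press,
               qc_violation = qc_violation,
               fold = (qc_violation == "fold"),
               seed = seed)
    if (is.null(study_id))
      study_id <- sprintf("%s_s%04d", tolower(a$label), seed %% 10000L)
    pressure_study(P, fs = fs, t_exit = t_exit, swallow_onsets = onsets,
                   spacing = 1, study_id = study_id, ground_truth = gt)
  })
}

#' Cohort specification for the simulator
#'
#' @param n_per_archetype Named integer vector: number of studies per
#'   archetype preset name (see [archetype()]).
#' @param seed Master seed; per-study seeds are derived deterministically
#'   from it, so a fixed seed yields a byte-identical cohort.
#' @param drift A [drift_model()] shared by the cohort.
#' @param fs Sampling rate in Hz.
#' @param qc_violations Optional character vector, one entry per study in
#'   archetype order, planting protocol violations (see
#'   [simulate_study()]).
#' @param ... Further arguments passed to [simulate_study()].
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_per_archetype, seed = 1L, drift = drift_model(),
                        fs = 50, qc_violations = NULL, ...) {
  if (is.null(names(n_per_archetype)) || any(n_per_archetype < 0) ||
      sum(n_per_archetype) < 1)
    stop("cohort_spec: n_per_archetype must be a named vector with total >= 1",
         call. = FALSE)
  total <- sum(n_per_archetype)
  if (!is.null(qc_violations) && length(qc_violations) != total)
    stop("cohort_spec: qc_violations must have one entry per study",
         call. = FALSE)
  structure(list(n_per_archetype = n_per_archetype, seed = as.integer(seed),
                 drift = drift, fs = fs, qc_violations = qc_violations,
                 sim_args = list(...)),
            class = "cohort_spec")
}

#' Simulate a cohort of studies
#'
#' Expands a [cohort_spec()] into simulated studies plus a manifest of
#' study id, true label, per-study seed and planted violation. With
#' \code{dir} given, study bundles and \code{manifest.csv} are written
#' there and the manifest gains a \code{path} column; otherwise studies
#' are returned in memory.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory.
#' @return A list with \code{studies} (list of [pressure_study()], named by
#'   id; \code{NULL} entries never occur) and \code{manifest} (data.frame).
#' @export
simulate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  arche <- rep(names(spec$n_per_archetype), spec$n_per_archetype)
  total <- length(arche)
  viol <- spec$qc_violations
  if (is.null(viol)) viol <- rep("none", total)
  seeds <- (as.numeric(spec$seed) * 10007 + seq_len(total) * 97) %%
    2147483647
  studies <- vector("list", total)
  ids <- character(total)
  for (i in seq_len(total)) {
    args <- c(list(archetype = arche[i], drift = spec$drift,
                   seed = as.integer(seeds[i]), fs = spec$fs,
                   qc_violation = viol[i],
                   study_id = sprintf("%s_%03d", arche[i], i)),
              spec$sim_args)
    studies[[i]] <- do.call(simulate_study, args)
    ids[i] <- studies[[i]]$study_id
  }
  names(studies) <- ids
  manifest <- data.frame(study_id = ids,
                         true_label = vapply(studies, function(s)
                           s$ground_truth$label, character(1)),
                         archetype = arche,
                         seed = as.integer(seeds),
                         qc_violation = viol,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest$path <- file.path(dir, manifest$study_id)
    for (i in seq_len(total)) write_study(studies[[i]], manifest$path[i])
    data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  }
  list(studies = studies, manifest = manifest)
}
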