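#' Pressure-topography study container
#'
#' A \code{pressure_study} holds one high-resolution manometry recording as
#' a space-time matrix of pressures together with its geometry, sampling
#' and event metadata. Pressures are in mmHg relative to atmospheric at
#' calibration, so uncorrected thermal drift appears as a nonzero residual
#' baseline after the catheter leaves the body. Sensor 1 is the most
#' proximal (pharyngeal) sensor and sensor numbers increase distally, the
#' top-down reading order of a Clouse plot. Sample \eqn{j} (1-based) covers
#' the half-open interval \eqn{[(j-1)/f_s, j/f_s)} seconds from recording
#' start; all analysis windows are half-open \eqn{[t_0, t_0 + w)}.
#'
#' @param pressure Numeric matrix, \code{n_sensors} rows (proximal first)
#'   by one column per sample, in mmHg.
#' @param fs Sampling rate in samples per second.
#' @param t_exit Annotated end of the "waterfall image" in seconds: the
#'   moment the catheter is fully out of the body and anatomical pressure
#'   gives way to atmospheric (plus any drift).
#' @param swallow_onsets Numeric vector of UES-relaxation onset times in
#'   seconds, one per swallow, all before \code{t_exit}.
#' @param spacing Distance between adjacent sensors in cm.
#' @param study_id Character identifier.
#' @param ground_truth Optional list of simulator annotations (true
#'   diagnosis label, true drift offsets, planted QC violations). Ignored
#'   by every analysis stage.
#'
#' @return An object of class \code{pressure_study}.
#' @seealso [read_study()], [write_study()], [simulate_study()]
#' @export
pressure_study <- function(pressure, fs, t_exit, swallow_onsets,
                           spacing = 1, study_id = "study",
                           ground_truth = NULL) {
  s <- structure(
    list(pressure = pressure,
         n_sensors = nrow(pressure),
         spacing = spacing,
         fs = fs,
         t_exit = t_exit,
         swallow_onsets = as.numeric(swallow_onsets),
         study_id = study_id,
         ground_truth = ground_truth),
    class = "pressure_study")
  validate_study(s)
}

#' Validate a pressure study's invariants
#'
#' Checks matrix shape, sampling rate, exit annotation and swallow onsets;
#' called by every constructor and reader. Errors name the offending
#' field.
#'
#' @param study A \code{pressure_study}.
#' @return The study, invisibly unchanged, if valid.
#' @export
validate_study <- function(study) {
  if (!inherits(study, "pressure_study"))
    stop("validate_study: not a pressure_study", call. = FALSE)
  p <- study$pressure
  if (!is.matrix(p) || !is.numeric(p))
    stop("pressure_study: 'pressure' must be a numeric matrix", call. = FALSE)
  if (nrow(p) != study$n_sensors)
    stop("pressure_study: 'pressure' must have exactly n_sensors rows",
         call. = FALSE)
  if (!is.numeric(study$fs) || length(study$fs) != 1L || study$fs <= 0)
    stop("pressure_study: 'fs' must be a positive scalar", call. = FALSE)
  if (!is.numeric(study$spacing) || study$spacing <= 0)
    stop("pressure_study: 'spacing' must be positive", call. = FALSE)
  dur <- ncol(p) / study$fs
  if (!is.numeric(study$t_exit) || length(study$t_exit) != 1L ||
      study$t_exit <= 0 || study$t_exit >= dur)
    stop("pressure_study: 't_exit' must satisfy 0 < t_exit < duration",
         call. = FALSE)
  if (any(!is.finite(study$swallow_onsets)) ||
      any(study$swallow_onsets < 0) ||
      any(study$swallow_onsets >= study$t_exit))
    stop("pressure_study: 'swallow_onsets' must all lie before t_exit",
         call. = FALSE)
  if (is.unsorted(study$swallow_onsets))
    stop("pressure_study: 'swallow_onsets' must be nondecreasing",
         call. = FALSE)
  invisible(study)
}

#' Recording duration in seconds
#' @param study A \code{pressure_study}.
#' @return Duration in seconds (samples / fs).
#' @export
study_duration <- function(study) ncol(study$pressure) / study$fs

#' @export
print.pressure_study <- function(x, ...) {
  cat(sprintf(
    "<pressure_study '%s'>: %d sensors x %d samples (%.1f s at %g Hz)\n",
    x$study_id, x$n_sensors, ncol(x$pressure), study_duration(x), x$fs))
  cat(sprintf("  catheter exit at %.2f s; %d swallows; spacing %g cm\n",
              x$t_exit, length(x$swallow_onsets), x$spacing))
  if (!is.null(x$ground_truth$label))
    cat(sprintf("  simulator ground truth: %s\n", x$ground_truth$label))
  invisible(x)
}

# 1-based sample indices covering the half-open window [t0, t1).
# Windows are aligned to the left-closed sample convention: sample j
# belongs to the window iff t0 <= (j-1)/fs < t1.
window_idx <- function(t0, t1, fs, n) {
  i0 <- ceiling(t0 * fs - 1e-9) + 1
  i1 <- ceiling(t1 * fs - 1e-9)
  if (i1 < i0) return(integer(0))
  seq.int(max(i0, 1L), min(i1, n))
}

#' Read a study bundle (CSV matrix + JSON sidecar)
#'
#' A study bundle is a pair \code{<id>.csv} / \code{<id>.json}. The CSV has
#' a header \code{t,p00..pNN} and one row per sample (column \code{p00} is
#' the most proximal sensor); the sidecar carries \code{fs},
#' \code{spacing_cm}, \code{t_exit_s}, \code{swallow_onsets_s} and an
#' optional \code{ground_truth} block.
#'
#' @param path Path to either file of the bundle, or the common stem.
#' @return A validated [pressure_study()].
#' @export
read_study <- function(path) {
  stem <- sub("\\.(csv|json)$", "", path)
  csv <- paste0(stem, ".csv"); json <- paste0(stem, ".json")
  if (!file.exists(csv)) stop("read_study: missing ", csv, call. = FALSE)
  if (!file.exists(json)) stop("read_study: missing ", json, call. = FALSE)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  for (f in c("fs", "spacing_cm", "t_exit_s", "swallow_onsets_s"))
    if (is.null(meta[[f]]))
      stop("read_study: sidecar missing field '", f, "'", call. = FALSE)
  dt <- data.table::fread(csv)
  pcols <- grep("^p[0-9]+$", names(dt), value = TRUE)
  if (length(pcols) == 0L)
    stop("read_study: no sensor columns p00.. found in ", csv, call. = FALSE)
  pcols <- pcols[order(as.integer(sub("^p", "", pcols)))]
  tv <- dt[["t"]]
  if (is.null(tv) || is.unsorted(tv, strictly = TRUE))
    stop("read_study: time axis 't' missing or non-monotone", call. = FALSE)
  mat <- t(as.matrix(dt[, pcols, with = FALSE]))
  dimnames(mat) <- NULL
  pressure_study(mat, fs = meta$fs, t_exit = meta$t_exit_s,
                 swallow_onsets = meta$swallow_onsets_s,
                 spacing = meta$spacing_cm,
                 study_id = basename(stem),
                 ground_truth = meta$ground_truth)
}

#' Write a study bundle (CSV matrix + JSON sidecar)
#'
#' Inverse of [read_study()]; the round trip reproduces the pressure
#' matrix bit-exactly (values are written with shortest round-trippable
#' decimal representation) and sidecar fields in a fixed order.
#'
#' @param study A valid [pressure_study()].
#' @param path Output stem or either file name; both files are written.
#' @return The stem path, invisibly.
#' @export
write_study <- function(study, path) {
  validate_study(study)
  stem <- sub("\\.(csv|json)$", "", path)
  n <- ncol(study$pressure)
  # %.17g guarantees a bit-exact double round trip through the CSV
  M <- cbind((seq_len(n) - 1L) / study$fs, t(study$pressure))
  chr <- matrix(sprintf("%.17g", M), nrow = n)
  dt <- data.table::as.data.table(chr)
  data.table::setnames(dt, c("t", sprintf("p%02d",
                                          seq_len(study$n_sensors) - 1L)))
  data.table::fwrite(dt, paste0(stem, ".csv"), quote = FALSE)
  meta <- list(fs = study$fs, spacing_cm = study$spacing,
               t_exit_s = study$t_exit,
               swallow_onsets_s = study$swallow_onsets)
  if (!is.null(study$ground_truth)) meta$ground_truth <- study$ground_truth
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(stem)
}

#' Render a Clouse plot (space-time pressure heat map)
#'
#' Draws the study as the conventional pressure topography: time on the
#' x-axis, sensors on the y-axis with the most proximal sensor at the top,
#' a colour ramp over pressure, dashed markers at each swallow onset and a
#' solid marker at the catheter-exit annotation.
#'
#' @param study A valid [pressure_study()].
#' @param path Output image file (PNG).
#' @param width,height Device size in pixels.
#' @param zlim Optional pressure range for the colour scale.
#' @return Invisibly, a list with the written \code{path}, the marker
#'   positions (\code{t_exit_marker}, \code{swallow_markers}) and the
#'   time-per-pixel resolution, so callers can verify marker placement.
#' @export
render_clouse_plot <- function(study, path, width = 900, height = 500,
                               zlim = NULL) {
  validate_study(study)
  p <- study$pressure
  if (is.null(zlim)) zlim <- range(p)
  if (zlim[1] == zlim[2]) zlim <- zlim + c(-1, 1)
  tv <- (seq_len(ncol(p)) - 1L) / study$fs
  pal <- grDevices::colorRampPalette(
    c("#08306b", "#2171b5", "#6baed6", "#ccebc5",
      "#fee391", "#fe9929", "#d7301f", "#7f0000"))(128)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::image(x = tv, y = seq_len(study$n_sensors), z = t(p),
                  ylim = c(study$n_sensors + 0.5, 0.5),
                  zlim = zlim, col = pal,
                  xlab = "time (s)", ylab = "sensor (proximal at top)",
                  main = study$study_id, useRaster = TRUE)
  graphics::abline(v = study$swallow_onsets, lty = 2, col = "grey20")
  graphics::abline(v = study$t_exit, lwd = 2, col = "black")
  invisible(list(path = path,
                 t_exit_marker = study$t_exit,
                 swallow_markers = study$swallow_onsets,
                 time_per_pixel = diff(range(tv)) / width))
}
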