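#' Motility-disorder archetype specification
#'
#' An archetype is a generative parameter set for [simulate_study()] chosen
#' so that, in expectation, the simulated study satisfies the diagnostic
#' criteria of its own label. Per-swallow behaviour is drawn from the type
#' probabilities (\code{p_failed}, \code{p_weak}, \code{p_premature},
#' \code{p_fragmented}, \code{p_hyper}; the remainder is a normal intact
#' wave), with panesophageal pressurization drawn independently with
#' probability \code{p_pressurization}.
#'
#' @param label Diagnosis label this archetype emulates (one of the labels
#'   emitted by [classify_diagnosis()]).
#' @param relax_residual Gastric-referenced EGJ pressure in mmHg the LES
#'   band holds during the deglutitive relaxation window; this is the main
#'   driver of the measured IRP. Non-relaxing (achalasia-type) archetypes
#'   simply use a high residual.
#' @param les_rest Absolute LES resting pressure in mmHg.
#' @param ues_peak Absolute UES resting peak pressure in mmHg.
#' @param amp_mean,amp_sd Peak amplitude (absolute mmHg) of a normal
#'   peristaltic contraction wave.
#' @param amp_weak_mean,amp_weak_sd Peak amplitude of a weak wave.
#' @param amp_hyper_mean,amp_hyper_sd Peak amplitude of a hypercontractile
#'   wave.
#' @param p_failed,p_weak,p_premature,p_fragmented,p_hyper Per-swallow type
#'   probabilities; their sum must not exceed 1.
#' @param p_pressurization Per-swallow probability of a panesophageal
#'   pressurization event (independent of wave type).
#' @param v_normal,v_premature Pre-deceleration contraction-front velocity
#'   in cm/s for normal and premature waves.
#' @param gastric_pressure Absolute intragastric baseline in mmHg.
#' @return An object of class \code{archetype_spec}.
#' @seealso [archetype()] for the named presets.
#' @export
archetype_spec <- function(label,
                           relax_residual = 7,
                           les_rest = 32,
                           ues_peak = 95,
                           amp_mean = 70, amp_sd = 6,
                           amp_weak_mean = 40, amp_weak_sd = 2,
                           amp_hyper_mean = 260, amp_hyper_sd = 15,
                           p_failed = 0, p_weak = 0, p_premature = 0,
                           p_fragmented = 0, p_hyper = 0,
                           p_pressurization = 0,
                           v_normal = 3.5, v_premature = 8,
                           gastric_pressure = 8) {
  a <- list(label = label, relax_residual = relax_residual,
            les_rest = les_rest, ues_peak = ues_peak,
            amp_mean = amp_mean, amp_sd = amp_sd,
            amp_weak_mean = amp_weak_mean, amp_weak_sd = amp_weak_sd,
            amp_hyper_mean = amp_hyper_mean, amp_hyper_sd = amp_hyper_sd,
            p_failed = p_failed, p_weak = p_weak,
            p_premature = p_premature, p_fragmented = p_fragmented,
            p_hyper = p_hyper, p_pressurization = p_pressurization,
            v_normal = v_normal, v_premature = v_premature,
            gastric_pressure = gastric_pressure)
  probs <- c(p_failed, p_weak, p_premature, p_fragmented, p_hyper,
             p_pressurization)
  if (any(probs < 0) || any(probs > 1) ||
      sum(probs[1:5]) > 1 + 1e-12)
    stop("archetype_spec: wave-type probabilities must lie in [0,1] and sum <= 1",
         call. = FALSE)
  amps <- c(amp_mean, amp_weak_mean, amp_hyper_mean, les_rest, ues_peak,
            relax_residual + gastric_pressure)
  if (any(amps < 0) || any(amps > 300))
    stop("archetype_spec: pressure parameters outside the plausible 0-300 mmHg range",
         call. = FALSE)
  structure(a, class = "archetype_spec")
}

#' Named archetype presets
#'
#' Returns the generative preset for one of the supported diagnosis
#' labels. The \code{nem_borderline} and \code{egjoo_borderline} variants
#' place the expected median IRP just below and just above the 15-mmHg
#' threshold; they exist to study drift-induced diagnosis flips between
#' normal motility and outflow obstruction and are deliberately unstable
#' under baseline perturbation (so they are excluded from the
#' archetype-fidelity contract of the standard presets).
#'
#' @param name One of \code{"nem"}, \code{"nem_borderline"},
#'   \code{"egjoo"}, \code{"egjoo_borderline"}, \code{"iem"}, \code{"t1a"},
#'   \code{"t2a"}, \code{"t3a"}, \code{"ac"}, \code{"acr"}, \code{"des"},
#'   \code{"he"}, \code{"fp"}.
#' @return An [archetype_spec()].
#' @export
#' @examples
#' archetype("nem")$label
archetype <- function(name = c("nem", "nem_borderline", "egjoo",
                               "egjoo_borderline", "iem", "t1a", "t2a",
                               "t3a", "ac", "acr", "des", "he", "fp")) {
  name <- match.arg(name)
  switch(name,
    nem = archetype_spec("NEM", relax_residual = 7),
    nem_borderline = archetype_spec("NEM", relax_residual = 16),
    egjoo = archetype_spec("EGJ_OO", relax_residual = 23, les_rest = 50,
                           amp_mean = 80),
    egjoo_borderline = archetype_spec("EGJ_OO", relax_residual = 18,
                                      les_rest = 45, amp_mean = 80),
    iem = archetype_spec("IEM", relax_residual = 9, les_rest = 26,
                         p_failed = 0.45, p_weak = 0.40),
    t1a = archetype_spec("T1A", relax_residual = 28, les_rest = 48,
                         p_failed = 1),
    t2a = archetype_spec("T2A", relax_residual = 28, les_rest = 48,
                         p_failed = 1, p_pressurization = 0.8),
    t3a = archetype_spec("T3A", relax_residual = 28, les_rest = 48,
                         amp_mean = 80, p_premature = 1),
    ac = archetype_spec("AC", relax_residual = 6, les_rest = 24,
                        p_failed = 1),
    acr = archetype_spec("ACR", relax_residual = 14, les_rest = 40,
                         p_failed = 1, p_pressurization = 0.8),
    des = archetype_spec("DES", relax_residual = 8, amp_mean = 80,
                         p_premature = 0.5),
    he = archetype_spec("HE", relax_residual = 8, p_hyper = 0.5),
    fp = archetype_spec("FP", relax_residual = 8, p_fragmented = 0.85))
}
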