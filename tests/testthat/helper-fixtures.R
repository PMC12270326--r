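# Shared toy fixtures. Toy studies use a 12-sensor layout so metric
# arithmetic can be checked against hand closed forms: UES band 2:3, body
# 4:7, LES band 8:9, gastric 10:11.

toy_landmarks <- function() {
  landmarks(ues_band = 2:3, les_band = 8:9, gastric = 10:11,
            body_span = 4:7)
}

# Constant-pressure toy study: `fill` may be a scalar, a per-sensor
# vector, or a full matrix.
toy_study <- function(fill = 0, n_sensors = 12, fs = 10, duration = 60,
                      t_exit = 50, swallow_onsets = 25) {
  n <- round(duration * fs)
  P <- if (is.matrix(fill)) fill else matrix(fill, n_sensors, n)
  pressure_study(P, fs = fs, t_exit = t_exit,
                 swallow_onsets = swallow_onsets, study_id = "toy")
}

# Drift-free, noise-free simulated study (smooth fixture).
clean_study <- function(archetype = "nem", seed = 1, fs = 50, ...) {
  simulate_study(archetype, drift_model(mu = 0, sigma = 0), seed = seed,
                 fs = fs, noise_sd = 0, post_exit_noise_sd = 0,
                 resp_amplitude = 0, ...)
}

study_metric_vector <- function(sm) {
  unlist(sm[c("uesp", "lesp", "median_irp", "median_dci", "median_dl",
              "pct_failed", "pct_weak", "pct_ineffective", "pct_premature",
              "pct_fragmented", "pct_intact", "pct_pressurization")])
}
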