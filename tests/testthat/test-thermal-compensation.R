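test_that("injected constant post-exit offsets are recovered exactly", {
  st <- toy_study(0, n_sensors = 10, fs = 10, duration = 70, t_exit = 50)
  o_true <- (seq_len(10) - 1) %% 5
  post <- (round(50 * 10) + 1):ncol(st$pressure)
  st$pressure[, post] <- matrix(o_true, 10, length(post))
  for (cond in c("ftc", "tc1", "tc5", "tc10")) {
    off <- estimate_offsets(st, tc_condition(cond))
    expect_equal(off$o, o_true, tolerance = 1e-12)
  }
})

test_that("zero post-exit pressure gives zero offsets", {
  st <- toy_study(matrix(0, 12, 600))
  expect_equal(estimate_offsets(st, tc_condition("ftc"))$o, rep(0, 12))
})

test_that("anchors beyond the recording end are rejected", {
  st <- toy_study(0, fs = 10, duration = 59, t_exit = 50) # 9 s tail
  expect_error(estimate_offsets(st, tc_condition("tc10")),
               "insufficient post-removal recording")
  expect_silent(estimate_offsets(st, tc_condition("tc5")))
})

test_that("compensation is the identity for zero offsets and for nonTC", {
  st <- simulate_study("nem", drift_model(), seed = 2, fs = 10)
  off0 <- estimate_offsets(st, tc_condition("ftc"))
  off0$o[] <- 0
  expect_identical(apply_compensation(st, off0)$pressure, st$pressure)
  expect_identical(compensate(st, "nontc")$pressure, st$pressure)
  expect_identical(apply_compensation(st, NULL)$pressure, st$pressure)
})

test_that("perfectly linear in-body drift is removed to numerical zero", {
  fs <- 10; t_exit <- 50; n <- 600
  o <- seq(0.5, 6, length.out = 12)
  tv <- (seq_len(n) - 1) / fs
  P <- outer(o, pmin(tv, t_exit) / t_exit)
  st <- toy_study(P, fs = fs, duration = 60, t_exit = t_exit)
  off <- estimate_offsets(st, tc_condition("ftc"))
  out <- apply_compensation(st, off)
  expect_lt(max(abs(out$pressure)), 1e-9)
})

test_that("compensating with o then -o restores the study", {
  st <- simulate_study("egjoo", drift_model(), seed = 4, fs = 10)
  off <- estimate_offsets(st, tc_condition("tc1"))
  neg <- off; neg$o <- -off$o
  back <- apply_compensation(apply_compensation(st, off), neg)
  expect_lt(max(abs(back$pressure - st$pressure)), 1e-9)
})

test_that("the correction ramp is zero at start and full at exit", {
  st <- toy_study(10, n_sensors = 3, fs = 10, duration = 60, t_exit = 50)
  off <- estimate_offsets(st, tc_condition("ftc"))
  out <- apply_compensation(st, off)
  expect_equal(out$pressure[, 1], st$pressure[, 1])          # r(0) = 0
  i_exit <- round(st$t_exit * st$fs) + 1L
  expect_equal(out$pressure[, i_exit], st$pressure[, i_exit] - off$o)
  # post-exit samples corrected with r = 1
  expect_equal(out$pressure[, ncol(out$pressure)],
               st$pressure[, ncol(st$pressure)] - off$o)
})

test_that("offset length mismatches are rejected", {
  st <- toy_study(0)
  off <- estimate_offsets(st, tc_condition("ftc"))
  off$o <- off$o[1:5]
  expect_error(apply_compensation(st, off), "n_sensors")
})

test_that("waterfall end detection agrees with the annotated exit", {
  st <- simulate_study("nem", drift_model(), seed = 6, fs = 20)
  det <- detect_waterfall_end(st)
  expect_lt(abs(det - st$t_exit), 0.5)
  # drift-free: spatial range after the detected exit is tiny
  st0 <- clean_study(fs = 20, seed = 6)
  det0 <- detect_waterfall_end(st0)
  post <- st0$pressure[, (round(det0 * st0$fs) + 5):ncol(st0$pressure)]
  expect_lt(max(apply(post, 2, function(x) diff(range(x)))), 15)
})

test_that("pressure held on sensors after the study defeats exit detection", {
  st <- simulate_study("nem", drift_model(), seed = 8, fs = 20,
                       qc_violation = "residual")
  expect_error(detect_waterfall_end(st), "catheter exit not detected")
})

test_that("with linear accrual and flat post-exit kinetics, formal TC recovers drift-free metrics", {
  lin <- drift_model(mu = 6, sigma = 3, warm_shape = "linear",
                     g_peak = 0, g_decay = 0)
  st_drift <- simulate_study("nem", lin, seed = 13, fs = 25,
                             noise_sd = 0, post_exit_noise_sd = 0,
                             resp_amplitude = 0)
  st_clean <- clean_study(seed = 13, fs = 25)
  m_drift <- study_metric_vector(analyze_study(st_drift, "ftc"))
  m_clean <- study_metric_vector(analyze_study(st_clean, "nontc"))
  expect_equal(m_drift, m_clean, tolerance = 1e-6)
})
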