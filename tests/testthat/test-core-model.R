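test_that("study bundle round-trip is bit-exact including annotations", {
  st <- simulate_study("nem", drift_model(), seed = 7, fs = 20)
  stem <- file.path(withr::local_tempdir(), "bundle")
  write_study(st, stem)
  back <- read_study(stem)
  expect_identical(dim(back$pressure), dim(st$pressure))
  expect_identical(back$pressure, st$pressure)
  expect_equal(back$fs, st$fs)
  expect_equal(back$t_exit, st$t_exit)
  expect_equal(back$swallow_onsets, st$swallow_onsets)
  expect_equal(back$ground_truth$label, st$ground_truth$label)
  expect_equal(unlist(back$ground_truth$drift_at_anchor$a0),
               st$ground_truth$drift_at_anchor$a0)
})

test_that("simulator fixture reads back with 36 sensor rows", {
  st <- simulate_study("iem", drift_model(), seed = 3, fs = 50,
                       n_swallows = 3, first_onset = 15,
                       swallow_spacing = 20, exit_gap = 25)
  stem <- file.path(withr::local_tempdir(), "fix")
  write_study(st, stem)
  back <- read_study(stem)
  expect_equal(back$n_sensors, 36L)
  expect_equal(nrow(back$pressure), 36L)
  expect_equal(back$fs, 50)
})

test_that("invariant violations produce structured validation errors", {
  P <- matrix(0, 4, 100)
  expect_error(pressure_study(P, fs = 10, t_exit = 10, swallow_onsets = 2),
               "t_exit")
  expect_error(pressure_study(P, fs = 10, t_exit = 12, swallow_onsets = 2),
               "t_exit")
  expect_error(pressure_study(P, fs = 10, t_exit = 5, swallow_onsets = 6),
               "swallow_onsets")
  expect_error(pressure_study(P, fs = -1, t_exit = 5, swallow_onsets = 2),
               "fs")
  st <- pressure_study(P, fs = 10, t_exit = 8, swallow_onsets = 2)
  st$n_sensors <- 5L
  expect_error(validate_study(st), "n_sensors")
})

test_that("sidecar with t_exit at or beyond duration is rejected on read", {
  st <- toy_study(5)
  stem <- file.path(withr::local_tempdir(), "bad")
  write_study(st, stem)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  meta$t_exit_s <- 60
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE)
  expect_error(read_study(stem), "t_exit")
})

test_that("a 2-sensor toy writes a 2-column CSV body plus time header", {
  st <- toy_study(1, n_sensors = 2, fs = 5, duration = 10, t_exit = 8,
                  swallow_onsets = 2)
  stem <- file.path(withr::local_tempdir(), "tiny")
  write_study(st, stem)
  header <- readLines(paste0(stem, ".csv"), n = 1)
  expect_equal(header, "t,p00,p01")
  expect_equal(length(readLines(paste0(stem, ".csv"))) - 1L, 50L)
})

test_that("clouse plot is rendered with the exit marker at t_exit", {
  st <- toy_study(matrix(rep(c(0, 40), each = 6), 12, 600), fs = 10)
  f <- file.path(withr::local_tempdir(), "plot.png")
  info <- render_clouse_plot(st, f)
  expect_true(file.exists(f))
  expect_lt(abs(info$t_exit_marker - st$t_exit), info$time_per_pixel)
  # constant field renders too
  f2 <- file.path(withr::local_tempdir(), "flat.png")
  expect_silent(render_clouse_plot(toy_study(3), f2))
  expect_true(file.exists(f2))
})

test_that("proximal/distal orientation is consistent across modules", {
  st <- clean_study(fs = 25)
  lm <- locate_landmarks(st)
  # proximal (low index) UES above the body, LES above the gastric sensors
  expect_true(max(lm$ues_band) < min(lm$body_span))
  expect_true(max(lm$body_span) < min(lm$les_band))
  expect_true(max(lm$les_band) < min(lm$gastric))
  # the UES really is the proximal band: its resting pressure dwarfs the
  # distal body's
  prof <- rowMeans(st$pressure[, 1:(20 * st$fs)])
  expect_gt(max(prof[lm$ues_band]), max(prof[lm$body_span]) + 30)
})
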