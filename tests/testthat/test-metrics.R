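# 16-sensor layout for DCI/DL closed-form checks: body 4:10 gives seven
# 1-cm sensors.
wide_landmarks <- function() {
  landmarks(ues_band = 2:3, les_band = 11:12, gastric = 13:14,
            body_span = 4:10)
}
wide_study <- function(P, fs = 10) {
  pressure_study(P, fs = fs, t_exit = 50, swallow_onsets = 25,
                 study_id = "wide")
}

test_that("IRP of a constant sleeve-gastric difference is that constant", {
  fill <- rep(0, 12); fill[8:9] <- 15; fill[10:11] <- 5
  st <- toy_study(fill)
  expect_equal(compute_irp(st, toy_landmarks(), 25), 10)
})

test_that("IRP selects the lowest noncontiguous 4 s of the window", {
  st <- toy_study(0)
  st$pressure[10:11, ] <- 5
  idx_lo <- manodrift:::window_idx(25, 29, 10, 600)
  idx_hi <- manodrift:::window_idx(29, 35, 10, 600)
  st$pressure[8:9, ] <- 55
  st$pressure[8:9, idx_lo] <- 5
  expect_equal(compute_irp(st, toy_landmarks(), 25), 0)
  # move the relaxed span to the end of the window: still 0
  st$pressure[8:9, ] <- 55
  st$pressure[8:9, idx_hi[(length(idx_hi) - 39):length(idx_hi)]] <- 5
  expect_equal(compute_irp(st, toy_landmarks(), 25), 0)
})

test_that("efficient IRP equals the full-sort oracle on random sleeve signals", {
  set.seed(99)
  lm <- toy_landmarks()
  for (i in 1:20) {
    st <- toy_study(0)
    idx <- manodrift:::window_idx(25, 35, 10, 600)
    st$pressure[8:9, ] <- matrix(rnorm(2 * 600, 20, 8), 2)
    st$pressure[10:11, ] <- matrix(rnorm(2 * 600, 5, 2), 2)
    sleeve <- pmin(st$pressure[8, idx], st$pressure[9, idx])
    gast <- colMeans(st$pressure[10:11, idx])
    oracle <- mean(sort(sleeve - gast)[1:40])
    expect_equal(compute_irp(st, lm, 25), oracle, tolerance = 1e-12)
  }
})

test_that("IRP windows truncated by catheter exit are an error", {
  st <- toy_study(0)
  expect_error(compute_irp(st, toy_landmarks(), 45), "truncated")
})

test_that("DCI of a rectangular ridge matches the closed form", {
  P <- matrix(0, 16, 600)
  idx <- manodrift:::window_idx(26, 30, 10, 600)   # 4.0 s
  P[4:8, idx] <- 30                                # 5 sensors x 1 cm
  st <- wide_study(P)
  expect_equal(compute_dci(st, wide_landmarks(), 25), (30 - 20) * 5 * 4)
  # everything at or below the 20 mmHg floor contributes nothing
  P2 <- matrix(0, 16, 600); P2[4:10, ] <- 20
  expect_equal(compute_dci(wide_study(P2), wide_landmarks(), 25), 0)
})

test_that("DCI is additive over disjoint regions and linear in the excess", {
  lm <- wide_landmarks()
  idx <- manodrift:::window_idx(26, 30, 10, 600)
  A <- matrix(0, 16, 600); A[4:5, idx] <- 35
  B <- matrix(0, 16, 600); B[8:9, idx] <- 41
  expect_equal(compute_dci(wide_study(A + B), lm, 25),
               compute_dci(wide_study(A), lm, 25) +
                 compute_dci(wide_study(B), lm, 25))
  # doubling the excess above the floor doubles the DCI
  E <- matrix(0, 16, 600); E[4:10, idx] <- 12
  base <- matrix(0, 16, 600); base[4:10, idx] <- 20
  d1 <- compute_dci(wide_study(base + E), lm, 25)
  d2 <- compute_dci(wide_study(base + 2 * E), lm, 25)
  expect_equal(d2, 2 * d1)
})

test_that("uniform pressure offsets cancel out of every study metric", {
  st <- clean_study(fs = 25, seed = 31)
  shifted <- st
  shifted$pressure <- shifted$pressure + 7
  m0 <- study_metric_vector(analyze_study(st))
  m7 <- study_metric_vector(analyze_study(shifted))
  expect_equal(m7, m0, tolerance = 1e-9)
})

test_that("resting pressures are gastric-referenced band maxima", {
  fill <- rep(0, 12); fill[2:3] <- 30; fill[8:9] <- 25; fill[10:11] <- 5
  st <- toy_study(fill)
  rp <- resting_pressures(st, toy_landmarks())
  expect_equal(unname(rp["uesp"]), 25)
  expect_equal(unname(rp["lesp"]), 20)
  st$pressure <- st$pressure + 7
  expect_equal(resting_pressures(st, toy_landmarks()), rp)
})

test_that("simulated LES resting pressure is recovered within noise tolerance", {
  st <- simulate_study("nem", drift_model(0, 0), seed = 17, fs = 25)
  sm <- analyze_study(st)
  expect_lt(abs(sm$lesp - 24), 2)   # les_rest 32 over gastric 8
})

test_that("two-segment arrival fits recover the programmed breakpoint exactly", {
  fs <- 10
  y <- c(1.0, 1.3, 1.6, 1.9, 2.2, 3.2, 4.2)  # slope change at x = 4
  P <- matrix(0, 16, 600)
  P[13:14, ] <- 0
  for (j in seq_along(y)) {
    i0 <- manodrift:::window_idx(25 + y[j], 50, fs, 600)
    P[3 + j, i0] <- 50
  }
  st <- wide_study(P, fs = fs)
  res <- compute_dl(st, wide_landmarks(), 25, min_sensors = 4)
  expect_equal(res$cdp_sensor, 8L)           # body index 5 -> sensor 8
  expect_equal(res$dl, y[5], tolerance = 1e-9)
  # exhaustive oracle: try every interior breakpoint with lm()
  x <- 0:6
  rss <- sapply(2:6, function(bi)
    sum(resid(lm(y ~ x + pmax(x - x[bi], 0)))^2))
  expect_equal(x[(2:6)[which.min(rss)]], 4)
})

test_that("simulator waves put the CDP 3 cm above the LES with DL near 6 s", {
  st <- clean_study(fs = 25, seed = 41)
  lm <- locate_landmarks(st)
  res <- compute_dl(st, lm, st$swallow_onsets[1])
  expect_equal(res$cdp_sensor, 27L)
  expect_gt(res$dl, 5.6); expect_lt(res$dl, 6.6)
})

test_that("failed swallows have undefined DL and the failed pattern", {
  st <- clean_study("ac", fs = 25, seed = 19)
  lm <- locate_landmarks(st)
  res <- compute_dl(st, lm, st$swallow_onsets[1])
  expect_true(is.na(res$dl))
  sm <- analyze_study(st)
  expect_true(is.na(sm$median_dl))
  expect_equal(sm$pct_failed, 100)
})

test_that("fragmented waves show their programmed contour break", {
  st <- clean_study("fp", fs = 25, seed = 23)
  lm <- locate_landmarks(st)
  types <- st$ground_truth$swallow_types
  k <- which(types == "fragmented")[1]
  brk <- contour_break_length(st, lm, st$swallow_onsets[k])
  expect_equal(brk, 7)
  k2 <- which(types == "normal")
  if (length(k2))
    expect_equal(contour_break_length(st, lm, st$swallow_onsets[k2[1]]), 0)
})

test_that("panesophageal pressurization is detected only when present", {
  st <- clean_study("t2a", fs = 25, seed = 29)
  lm <- locate_landmarks(st)
  flags <- st$ground_truth$pressurization
  got <- vapply(seq_along(flags), function(k)
    detect_pressurization(st, lm, st$swallow_onsets[k]), logical(1))
  expect_equal(got, flags)
  st2 <- clean_study("nem", fs = 25, seed = 29)
  lm2 <- locate_landmarks(st2)
  expect_false(detect_pressurization(st2, lm2, st2$swallow_onsets[1]))
})

test_that("swallow strength and pattern thresholds behave at the boundaries", {
  p <- analysis_params()
  s1 <- classify_swallow(8, 449, 6, 0, FALSE, p)
  expect_equal(s1$strength_label, "weak")
  expect_equal(s1$pattern_label, "intact")   # not premature-eligible
  s2 <- classify_swallow(8, 449, 3, 0, FALSE, p)
  expect_equal(s2$pattern_label, "intact")   # short DL but inadequate vigor
  s3 <- classify_swallow(8, 9000, 6, 0, FALSE, p)
  expect_true(s3$hyper)
  expect_equal(s3$strength_label, "normal")
  expect_equal(classify_swallow(8, 0, NA, NA, FALSE, p)$strength_label,
               "failed")
  s4 <- classify_swallow(8, 600, 3.9, 0, FALSE, p)
  expect_equal(s4$pattern_label, "premature")
  s5 <- classify_swallow(8, 600, 6, 6, FALSE, p)
  expect_equal(s5$pattern_label, "fragmented")
})

test_that("study summaries aggregate swallows as medians and counts", {
  p <- analysis_params()
  ten <- replicate(10, classify_swallow(8, 1200, 6, 0, FALSE, p),
                   simplify = FALSE)
  sm <- summarize_study(ten, 80, 20, p)
  expect_equal(sm$median_irp, 8)
  expect_equal(sm$pct_intact, 100)
  mix <- c(replicate(6, classify_swallow(5, 0, NA, NA, FALSE, p),
                     simplify = FALSE),
           replicate(4, classify_swallow(5, 1000, 6, 0, FALSE, p),
                     simplify = FALSE))
  sm2 <- summarize_study(mix, 80, 20, p)
  expect_equal(sm2$pct_failed, 60)
  expect_gte(sm2$pct_ineffective, 60)
  expect_equal(sm2$pct_intact, 40)
  three <- lapply(c(3, 15, 27), function(i)
    classify_swallow(i, 1200, 6, 0, FALSE, p))
  expect_equal(summarize_study(three, 0, 0, p)$median_irp,
               sort(c(3, 15, 27))[2])
  expect_error(summarize_study(list(), 0, 0, p), "no classified")
})

test_that("landmark detection fails cleanly on degenerate fields", {
  st <- toy_study(seq(0, 44, length.out = 12))  # monotone, no bands
  expect_error(locate_landmarks(st), "landmarks not found")
})

test_that("detected gastric sensors sit distal to the LES band across seeds", {
  for (s in 1:10) {
    a <- c("nem", "egjoo", "iem", "t2a", "fp")[(s %% 5) + 1]
    st <- simulate_study(a, drift_model(), seed = 300 + s, fs = 10)
    lm <- locate_landmarks(st)
    expect_true(31 %in% lm$les_band)
    expect_true(all(lm$gastric > max(lm$les_band)))
    expect_true(all(diff(c(max(lm$ues_band), min(lm$body_span))) > 0))
  }
})

test_that("metrics are stable under sampling-rate refinement", {
  m50 <- study_metric_vector(analyze_study(clean_study(fs = 50, seed = 37)))
  m100 <- study_metric_vector(analyze_study(clean_study(fs = 100, seed = 37)))
  num <- c("uesp", "lesp", "median_irp", "median_dci", "median_dl")
  expect_equal(m100[num], m50[num], tolerance = 0.02)
  pct <- setdiff(names(m50), num)
  expect_equal(m100[pct], m50[pct])
})
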