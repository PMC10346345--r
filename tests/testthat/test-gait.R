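# Heel-strike detection, reconciliation and cycle segmentation.

test_that("marker minima recover the true heel strikes on synthetic data", {
  ses <- fixture_session()
  ev <- detect_events_marker(ses$heel_z_right)
  truth <- ses$true_events$right
  expect_equal(length(ev$times), length(truth))
  err <- vapply(truth, function(x) min(abs(ev$times - x)), numeric(1))
  expect_lt(max(err), 0.010)     # within +/- 10 ms, no misses/false alarms
})

test_that("flat or constant trajectories give an empty event series", {
  ms <- motion_series(seq(0, 5, by = 0.01), rep(10, 501))
  expect_warning(ev <- detect_events_marker(ms), "flat")
  expect_length(ev$times, 0)
})

test_that("two identical strides give exactly two events one period apart", {
  fs <- 100
  period <- 1.2
  t <- seq(0, 3 * period, by = 1 / fs)
  # minima at t = period and t = 2*period
  h <- 20 + 60 * (0.5 - 0.5 * cos(2 * pi * t / period))
  ev <- detect_events_marker(motion_series(t, h))
  inner <- ev$times[ev$times > 0.5 & ev$times < 3 * period - 0.5]
  expect_length(inner, 2)
  expect_equal(diff(inner), period, tolerance = 0.01)
})

test_that("GRF onsets recover the true heel strikes", {
  ses <- fixture_session()
  ev <- detect_events_grf(ses$grf_right)
  truth <- ses$true_events$right
  err <- vapply(truth, function(x) min(abs(ev$times - x)), numeric(1))
  expect_lt(max(err), 0.010)
})

test_that("GRF edge cases behave as specified", {
  t <- seq(0, 10, by = 0.01)
  expect_length(detect_events_grf(
    motion_series(t, rep(0, length(t)), kind = "force"))$times, 0)
  expect_error(detect_events_grf(
    motion_series(t, rep(0, length(t)), kind = "force"), threshold = 0),
    "positive")
  # square pulse train of period T: events spaced T
  period <- 2
  pulse <- ifelse((t %% period) < 0.8, 600, 0)
  ev <- detect_events_grf(motion_series(t, pulse, kind = "force"))
  expect_true(all(abs(diff(ev$times) - period) < 0.02))
})

test_that("reconciliation keeps confirmed marker events and reports the rate", {
  m <- gait_events(c(1, 2.1, 3.2, 4.3), source = "marker")
  f <- gait_events(c(1.01, 2.11, 3.21, 4.31), source = "force")
  r <- reconcile_events(m, f)
  expect_equal(r$times, m$times)       # marker timing is primary
  expect_equal(r$match_rate, 1.0)
  # an extra marker event without a force partner is dropped
  m2 <- gait_events(c(1, 1.6, 2.1, 3.2, 4.3), source = "marker")
  r2 <- reconcile_events(m2, f)
  expect_equal(r2$times, m$times)
  expect_equal(r2$match_rate, 0.8)
  # sides must agree
  expect_error(reconcile_events(
    gait_events(1:3, side = "left", source = "marker"), f), "sides")
  # empty input
  r3 <- reconcile_events(gait_events(numeric(0), source = "marker"), f)
  expect_length(r3$times, 0)
})

test_that("synthetic marker and force events reconcile almost completely", {
  ses <- fixture_session()
  r <- reconcile_events(detect_events_marker(ses$heel_z_right),
                        detect_events_grf(ses$grf_right))
  expect_gte(r$match_rate, 0.98)
})

test_that("segmentation yields one cycle per retained event pair", {
  rec <- eeg_recording(matrix(rnorm(2 * 5000), 2), 1000)
  ev <- gait_events(c(1, 2.1, 3.2))
  cyc <- segment_and_normalize(rec, ev)
  expect_length(cyc, 2)
  expect_equal(dim(cyc$normalized), c(2, 100, 2))
  # raw slice length matches round(duration * rate)
  expect_equal(ncol(cyc$raw[[1]]), round(1.1 * 1000))
  # fewer than 2 events: empty
  expect_length(segment_and_normalize(rec, gait_events(2)), 0)
  # events outside the recording span
  expect_error(segment_and_normalize(rec, gait_events(c(1, 6))), "span")
})

test_that("implausible cycle durations are discarded and counted", {
  rec <- eeg_recording(matrix(rnorm(10000), 1), 1000)
  ev <- gait_events(c(0.5, 1.6, 4.5, 5.6), bounds = c(0.1, 10))
  cyc <- segment_and_normalize(rec, ev)
  expect_length(cyc, 2)                 # the 2.9 s middle cycle is dropped
  expect_equal(cyc$n_discarded, 1L)
})

test_that("no EEG sample is assigned to two cycles", {
  rec <- eeg_recording(matrix(seq_len(4000), 1), 1000)
  ev <- gait_events(c(0.5, 1.5, 2.5, 3.5))
  cyc <- segment_and_normalize(rec, ev)
  idx <- unlist(lapply(cyc$raw, function(m) m[1, ]))
  expect_false(any(duplicated(idx)))    # sample values are unique indices
  expect_equal(length(idx), 3 * 1000)   # half-open spans tile the range
})

test_that("normalization preserves constants and amplitude bounds", {
  rec <- eeg_recording(rbind(rep(7, 3000), rnorm(3000)), 1000)
  cyc <- segment_and_normalize(rec, gait_events(c(0.2, 1.3, 2.4)))
  expect_true(all(cyc$normalized[1, , ] == 7))
  for (k in 1:2) {
    expect_gte(min(cyc$normalized[2, , k]), min(cyc$raw[[k]][2, ]))
    expect_lte(max(cyc$normalized[2, , k]), max(cyc$raw[[k]][2, ]))
  }
})

test_that("a sinusoid at stride frequency yields identical normalized cycles", {
  fs <- 1000
  period <- 1.1
  t <- seq(1 / fs, 12, by = 1 / fs)
  rec <- eeg_recording(rbind(sin(2 * pi * t / period)), fs)
  ev <- gait_events(seq(0.55, 11.5, by = period))
  cyc <- segment_and_normalize(rec, ev)
  ref <- cyc$normalized[1, , 1]
  for (k in 2:length(cyc)) {
    rel_rms <- sqrt(mean((cyc$normalized[1, , k] - ref)^2)) /
      sqrt(mean(ref^2))
    expect_lt(rel_rms, 0.01)
  }
})
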