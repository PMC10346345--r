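# Synthetic session generator: determinism, planted spectral structure,
# waveform/event consistency, artifact injection.

test_that("identical seed and config give bit-identical sessions", {
  cfg <- session_config(trial_duration = 10, n_channels = 8, seed = 7)
  a <- generate_session(cfg, "STROOP", 2)
  b <- generate_session(cfg, "STROOP", 2)
  expect_identical(a$eeg$data, b$eeg$data)
  expect_identical(a$true_events, b$true_events)
  expect_identical(a$heel_z_right$values, b$heel_z_right$values)
  # different subject or condition gives different data
  expect_false(identical(generate_session(cfg, "STROOP", 3)$eeg$data,
                         a$eeg$data))
})

test_that("config validation rejects bad values", {
  expect_error(session_config(trial_duration = 0), "positive")
  expect_error(session_config(sampling_rate_eeg = -1), "positive")
  expect_error(session_config(stride_mean = 0), "positive")
  bad_fx <- default_band_effects <- neurogait:::default_band_effects()
  bad_fx$MLP["beta"] <- -1
  expect_error(session_config(band_effects = bad_fx), "positive")
})

no_artifacts <- function() {
  list(blink_rate = 0, blink_amplitude = 0, blink_duration = 0.3,
       line_freq = 60, line_amplitude = 0, emg_rate = 0, emg_amplitude = 0,
       emg_duration = 0.3)
}

test_that("equal band factors give equal beta power across conditions", {
  # null case: with all band effects at 1 and artifacts off, sensorimotor
  # beta power must not differ between conditions beyond sampling error
  fx <- lapply(neurogait:::default_band_effects(), function(x) x * 0 + 1)
  p_nw <- p_mlp <- numeric(20)
  for (s in 1:20) {
    cfg <- session_config(trial_duration = 20, n_channels = 16, seed = s,
                          band_effects = fx, artifact_spec = no_artifacts())
    cz <- function(ses) which(ses$eeg$channel_labels == "Cz")
    nw <- generate_session(cfg, "NW", 1)
    mlp <- generate_session(cfg, "MLP", 1)
    p_nw[s] <- band_power(nw$eeg$data[cz(nw), ], 1000, c(12, 30))
    p_mlp[s] <- band_power(mlp$eeg$data[cz(mlp), ], 1000, c(12, 30))
  }
  expect_gt(t.test(p_nw, p_mlp)$p.value, 0.01)
})

test_that("planted beta suppression is recoverable by spectral oracle", {
  # default MLP beta factor 0.7: Welch-integrated 12-30 Hz power on Cz,
  # MLP vs NW, should recover the planted ratio within 0.1
  ratios <- numeric(10)
  for (s in 1:10) {
    cfg <- session_config(trial_duration = 30, n_channels = 16, seed = s,
                          artifact_spec = no_artifacts())
    nw <- generate_session(cfg, "NW", 1)
    mlp <- generate_session(cfg, "MLP", 1)
    cz <- which(nw$eeg$channel_labels == "Cz")
    ratios[s] <- band_power(mlp$eeg$data[cz, ], 1000, c(12, 30)) /
      band_power(nw$eeg$data[cz, ], 1000, c(12, 30))
  }
  expect_lt(abs(mean(ratios) - 0.7), 0.1)
})

test_that("heel waveform minima and GRF onsets sit at the true events", {
  cfg <- session_config(trial_duration = 25, n_channels = 4,
                        marker_noise_sd = 0, seed = 9)
  ses <- generate_session(cfg, "NW", 1)
  t_mo <- ses$heel_z_right$time
  step <- 1 / ses$heel_z_right$sampling_rate
  for (ev in ses$true_events$right[2:20]) {
    win <- which(abs(t_mo - ev) <= 5 * step)
    i_min <- win[which.min(ses$heel_z_right$values[win])]
    expect_lte(abs(t_mo[i_min] - ev), step + 1e-9)
  }
  # GRF zero during late swing, rising after each event
  ph_idx <- which(t_mo > ses$true_events$right[2] - 0.15 &
                  t_mo < ses$true_events$right[2] - 0.05)
  expect_true(all(ses$grf_right$values[ph_idx] == 0))
})

test_that("inject_artifacts with zero rates is the identity", {
  rec <- eeg_recording(matrix(rnorm(2 * 2000), 2), 250, c("Fp1", "T7"))
  out <- inject_artifacts(rec, no_artifacts(), seed = 1)
  expect_equal(out$data, rec$data)
  expect_length(out$artifact_log$blink_times, 0)
})

test_that("line-noise injection raises 60 Hz power by a^2/2", {
  fs <- 500
  rec <- eeg_recording(matrix(rnorm(2 * 20 * fs, sd = 0.5), 2), fs,
                       c("Fp1", "T7"))
  a <- 4
  spec <- no_artifacts(); spec$line_amplitude <- a
  out <- inject_artifacts(rec, spec, seed = 2)
  for (ch in 1:2) {
    gain <- band_power(out$data[ch, ], fs, c(59.5, 60.5)) -
      band_power(rec$data[ch, ], fs, c(59.5, 60.5))
    expect_lt(abs(gain - a^2 / 2) / (a^2 / 2), 0.05)
  }
})

test_that("blink counts follow the requested Poisson rate", {
  rec <- eeg_recording(matrix(rnorm(2 * 300 * 100), 2), 100, c("Fp1", "T7"))
  spec <- no_artifacts()
  spec$blink_rate <- 0.2; spec$blink_amplitude <- 100
  counts <- vapply(1:5, function(s) {
    length(inject_artifacts(rec, spec, seed = s)$artifact_log$blink_times)
  }, numeric(1))
  # rate 0.2/s over 300 s: 60 +/- 15 expected per draw
  expect_true(all(abs(counts - 60) <= 15))
  # input unmodified
  expect_false(any(is.na(rec$data)))
})

test_that("negative artifact rates are rejected", {
  rec <- eeg_recording(matrix(rnorm(200), 2), 100, c("Fp1", "T7"))
  spec <- no_artifacts(); spec$blink_rate <- -1
  expect_error(inject_artifacts(rec, spec), ">= 0")
})
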