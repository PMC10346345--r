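# Synthetic walking-session generator: 64-channel EEG with gait-phase-locked
# oscillations plus heel-marker and ground-reaction-force waveforms with known
# heel-strike times, so the whole pipeline is testable without recordings.

# 64-channel actiCAP-style 10-20/10-10 montage.
MONTAGE_64 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6",
  "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
  "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10",
  "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
  "FT9", "FT7", "FC3", "FC4", "FT8", "FT10", "C5", "C1", "C2", "C6",
  "TP7", "CP3", "CPz", "CP4", "TP8", "P5", "P1", "P2", "P6",
  "PO7", "PO3", "POz", "PO4", "PO8")

# Spatial weight of each channel for a named scalp region, used both to
# project oscillatory sources and to place artifacts.
region_weights <- function(labels, region) {
  w <- setNames(numeric(length(labels)), labels)
  set <- function(chans, val) {
    hit <- intersect(chans, labels)
    w[hit] <<- pmax(w[hit], val)
  }
  switch(region,
    frontal = {
      set(c("Fp1", "Fp2", "AF7", "AF3", "AF4", "AF8"), 1)
      set(c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"), 0.4)
    },
    midline_frontal = {
      set(c("Fz", "F1", "F2", "FC1", "FC2"), 1)
      set(c("Cz", "F3", "F4", "FC3", "FC4"), 0.5)
    },
    sensorimotor = {
      set(c("C3", "Cz", "C4"), 1)
      set(c("C5", "C1", "C2", "C6", "FC3", "FC1", "FC2", "FC4",
            "CP3", "CP1", "CPz", "CP2", "CP4"), 0.7)
    },
    posterior = {
      set(c("O1", "Oz", "O2", "PO7", "PO3", "POz", "PO4", "PO8"), 1)
      set(c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
            "PO9", "PO10"), 0.5)
    },
    temporal = {
      set(c("T7", "T8", "FT7", "FT8", "FT9", "FT10",
            "TP7", "TP8", "TP9", "TP10"), 1)
    },
    stop("unknown region: ", region))
  unname(w)
}

CONDITIONS <- c("NW", "STROOP", "COM", "MLP")
UNSTABLE_CONDITIONS <- c("STROOP", "MLP")

default_band_effects <- function() {
  list(
    NW     = c(alpha = 1, beta = 1,    theta = 1),
    COM    = c(alpha = 1, beta = 1,    theta = 1),
    STROOP = c(alpha = 1, beta = 0.75, theta = 1.35),
    MLP    = c(alpha = 1, beta = 0.70, theta = 1.25))
}

default_artifact_spec <- function() {
  list(blink_rate = 0.2, blink_amplitude = 120, blink_duration = 0.3,
       line_freq = 60, line_amplitude = 5,
       emg_rate = 0.1, emg_amplitude = 30, emg_duration = 0.3)
}

#' Configuration of a synthetic walking session
#'
#' Bundles every parameter of the synthetic-session generator. The defaults
#' describe the emulated study: 13 subjects, 5-minute trials per condition,
#' 64-channel EEG at 1000 Hz, 100 Hz motion capture, mean stride time 1.10 s
#' with 3% variability during stable and 7% during unstable walking, and
#' condition-dependent band-power effects (sensorimotor beta suppressed,
#' frontal-midline theta enhanced during unstable conditions).
#'
#' @param n_subjects number of subjects the session set describes.
#' @param trial_duration trial length in seconds.
#' @param sampling_rate_eeg EEG sampling rate in Hz.
#' @param sampling_rate_mocap motion-capture/forceplate sampling rate in Hz.
#' @param n_channels number of EEG channels (up to 64; the first
#'   `n_channels` montage labels are used).
#' @param stride_mean mean stride (right heel strike to right heel strike)
#'   duration in seconds.
#' @param stride_cv coefficient of variation of stride time; named vector
#'   with `stable` and `unstable` entries.
#' @param band_effects per-condition multiplicative band-power factors, a
#'   named list `NW`, `STROOP`, `COM`, `MLP` each with `alpha`, `beta`,
#'   `theta` entries (applied to oscillation power, not amplitude).
#' @param artifact_spec list with `blink_rate` (1/s), `blink_amplitude` (uV),
#'   `blink_duration` (s), `line_freq` (Hz), `line_amplitude` (uV),
#'   `emg_rate` (1/s), `emg_amplitude` (uV), `emg_duration` (s). Set the
#'   rates/amplitudes to 0 for artifact-free sessions.
#' @param osc_amplitude oscillation source amplitudes (standard deviation,
#'   uV) for alpha, beta and theta at their core channels.
#' @param background_sd standard deviation (uV) of the 1/f background.
#' @param modulation_depth depth of the sinusoidal gait-phase amplitude
#'   modulation of every oscillatory source.
#' @param marker_noise_sd heel-marker measurement noise in mm.
#' @param force_noise_sd forceplate noise in N.
#' @param seed integer seed; identical seed and configuration give
#'   bit-identical sessions.
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_subjects = 13L, trial_duration = 300,
                           sampling_rate_eeg = 1000,
                           sampling_rate_mocap = 100, n_channels = 64L,
                           stride_mean = 1.10,
                           stride_cv = c(stable = 0.03, unstable = 0.07),
                           band_effects = default_band_effects(),
                           artifact_spec = default_artifact_spec(),
                           osc_amplitude = c(alpha = 18, beta = 14, theta = 12),
                           background_sd = 6,
                           modulation_depth = 0.2,
                           marker_noise_sd = 0.1, force_noise_sd = 3,
                           seed = 1L) {
  if (trial_duration <= 0) stop("trial_duration must be positive")
  if (sampling_rate_eeg <= 0 || sampling_rate_mocap <= 0) {
    stop("sampling rates must be positive")
  }
  if (stride_mean <= 0) stop("stride_mean must be positive")
  if (n_channels < 1L || n_channels > length(MONTAGE_64)) {
    stop("n_channels must be between 1 and ", length(MONTAGE_64))
  }
  for (cond in CONDITIONS) {
    fx <- band_effects[[cond]]
    if (is.null(fx) || any(fx <= 0)) {
      stop("band_effects must contain positive factors for ", cond)
    }
  }
  if (any(unlist(artifact_spec[c("blink_rate", "emg_rate")]) < 0)) {
    stop("artifact rates must be >= 0")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         trial_duration = trial_duration,
         sampling_rate_eeg = sampling_rate_eeg,
         sampling_rate_mocap = sampling_rate_mocap,
         n_channels = as.integer(n_channels),
         stride_mean = stride_mean, stride_cv = stride_cv,
         band_effects = band_effects, artifact_spec = artifact_spec,
         osc_amplitude = osc_amplitude, background_sd = background_sd,
         modulation_depth = modulation_depth,
         marker_noise_sd = marker_noise_sd,
         force_noise_sd = force_noise_sd,
         seed = as.integer(seed)),
    class = "session_config"
  )
}

# Deterministic per-trial seed below 2^31, derived from config seed,
# subject and condition.
trial_seed <- function(seed, subject_id, condition) {
  cond_idx <- match(condition, CONDITIONS)
  (abs(as.integer(seed)) %% 1000003L) * 2048L + as.integer(subject_id) * 8L +
    cond_idx
}

# 1/f-background noise (power spectral slope -1) via spectral shaping of
# white noise; flat below f0 to keep variance finite.
pink_noise <- function(n, sd_target, fs, f0 = 1) {
  white <- rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)          # two-sided frequency axis
  amp <- 1 / sqrt(pmax(f, f0))
  amp[1] <- 0                   # no DC
  x <- Re(fft(fft(white) * amp, inverse = TRUE)) / n
  x * sd_target / sd(x)
}

# Band-limited unit-variance noise source.
band_source <- function(n, fs, edges) {
  flt <- butter_design(4L, edges / (fs / 2), "pass")
  x <- zp_filtfilt(flt$b, flt$a, rnorm(n))
  x / sd(x)
}

# Strictly increasing heel-strike times covering (t0, duration), with
# normally distributed stride intervals truncated to stay physiological.
draw_events <- function(duration, stride_mean, stride_sd, t0) {
  t <- t0
  out <- numeric(0)
  repeat {
    out <- c(out, t)
    gap <- rnorm(1, stride_mean, stride_sd)
    gap <- min(max(gap, stride_mean - 3 * stride_sd, 0.4),
               stride_mean + 3 * stride_sd)
    t <- t + gap
    if (t > duration - 0.2) break
  }
  out
}

# Gait phase in [0,1) at arbitrary times, piecewise linear between events
# and extrapolated with the mean stride outside them.
gait_phase <- function(t, events) {
  if (length(events) < 2L) return(rep(0, length(t)))
  stride <- mean(diff(events))
  idx <- findInterval(t, events)
  phase <- numeric(length(t))
  inside <- idx >= 1L & idx < length(events)
  lo <- events[pmax(idx, 1L)]
  hi <- events[pmin(idx + 1L, length(events))]
  phase[inside] <- (t[inside] - lo[inside]) / (hi[inside] - lo[inside])
  before <- idx < 1L
  phase[before] <- ((t[before] - events[1]) / stride) %% 1
  after <- idx >= length(events)
  phase[after] <- ((t[after] - events[length(events)]) / stride) %% 1
  phase
}

# Heel vertical position (mm): cosine swing bump with its minimum exactly at
# each heel strike.
heel_waveform <- function(phase) {
  15 + 80 * (0.5 - 0.5 * cos(2 * pi * phase))
}

# Vertical GRF (N): double-peaked stance curve over the first `stance_frac`
# of the cycle, zero during swing, rising sharply at heel strike.
grf_waveform <- function(phase, stance_frac = 0.62, peak = 750) {
  s <- phase / stance_frac
  f <- ifelse(phase < stance_frac,
              peak * sin(pi * s) * (1 + 0.25 * cos(2 * pi * s)), 0)
  pmax(f, 0)
}

#' Generate one synthetic walking trial
#'
#' Builds a complete session for one subject and condition: EEG as a 1/f
#' background plus gait-phase-modulated alpha (posterior), beta
#' (sensorimotor) and theta (frontal-midline) oscillations with
#' condition-dependent band-power factors; heel-marker trajectories with
#' local minima exactly at the true heel-strike times; double-peaked vertical
#' ground reaction forces rising sharply at each heel strike; and, unless the
#' artifact rates are zero, injected blink, line-noise and muscle artifacts.
#'
#' @param config a [session_config()].
#' @param condition one of `"NW"`, `"STROOP"`, `"COM"`, `"MLP"`.
#' @param subject_id integer subject identifier.
#' @return An object of class `gait_session` with elements `eeg`,
#'   `heel_z_left`, `heel_z_right`, `grf_left`, `grf_right`, `true_events`
#'   (list with `left` and `right` heel-strike times), `condition`,
#'   `subject_id` and `artifact_log`.
#' @examples
#' cfg <- session_config(trial_duration = 20, n_channels = 8, seed = 1)
#' ses <- generate_session(cfg, "NW", subject_id = 1)
#' @export
generate_session <- function(config, condition = CONDITIONS,
                             subject_id = 1L) {
  stopifnot(inherits(config, "session_config"))
  condition <- match.arg(condition)
  set.seed(trial_seed(config$seed, subject_id, condition))

  fs <- config$sampling_rate_eeg
  dur <- config$trial_duration
  n <- round(dur * fs)
  labels <- MONTAGE_64[seq_len(config$n_channels)]

  cv <- if (condition %in% UNSTABLE_CONDITIONS) config$stride_cv[["unstable"]]
        else config$stride_cv[["stable"]]
  stride_sd <- cv * config$stride_mean
  ev_right <- draw_events(dur, config$stride_mean, stride_sd, t0 = 0.5)
  gaps <- diff(c(ev_right, ev_right[length(ev_right)] + config$stride_mean))
  ev_left <- ev_right + 0.5 * gaps + rnorm(length(ev_right), 0, 0.01)
  ev_left <- ev_left[ev_left < dur - 0.2]

  t_eeg <- (seq_len(n) - 1) / fs
  phase <- gait_phase(t_eeg, ev_right)
  mod <- 1 + config$modulation_depth * sin(2 * pi * phase)
  fx <- config$band_effects[[condition]]

  bands <- list(
    alpha = list(edges = c(8, 12), region = "posterior"),
    beta  = list(edges = c(12, 30), region = "sensorimotor"),
    theta = list(edges = c(4, 7), region = "midline_frontal"))

  data <- matrix(0, length(labels), n)
  for (ch in seq_along(labels)) {
    data[ch, ] <- pink_noise(n, config$background_sd, fs)
  }
  for (b in names(bands)) {
    src <- band_source(n, fs, bands[[b]]$edges) * mod
    w <- region_weights(labels, bands[[b]]$region)
    amp <- config$osc_amplitude[[b]] * sqrt(fx[[b]])
    active <- which(w > 0)
    if (length(active)) {
      data[active, ] <- data[active, ] +
        outer(w[active] * amp, rep(1, n)) * rep(src, each = length(active))
    }
  }
  eeg <- eeg_recording(data, fs, labels)

  spec <- config$artifact_spec
  art_seed <- trial_seed(config$seed, subject_id, condition) + 1L
  eeg <- inject_artifacts(eeg, spec, seed = art_seed)

  t_mo <- seq(0, dur - 1 / config$sampling_rate_mocap,
              by = 1 / config$sampling_rate_mocap)
  make_side <- function(events, side) {
    ph <- gait_phase(t_mo, events)
    heel <- heel_waveform(ph) + rnorm(length(t_mo), 0, config$marker_noise_sd)
    grf <- grf_waveform(ph) + rnorm(length(t_mo), 0, config$force_noise_sd)
    grf <- pmax(grf, 0)
    # keep swing exactly unloaded so force onsets stay crisp
    grf[gait_phase(t_mo, events) >= 0.62] <- 0
    list(
      heel = motion_series(t_mo, heel, side = side, kind = "marker"),
      grf = motion_series(t_mo, grf, side = side, kind = "force"))
  }
  right <- make_side(ev_right, "right")
  left <- make_side(ev_left, "left")

  structure(
    list(eeg = eeg,
         heel_z_left = left$heel, heel_z_right = right$heel,
         grf_left = left$grf, grf_right = right$grf,
         true_events = list(left = ev_left, right = ev_right),
         condition = condition, subject_id = as.integer(subject_id),
         artifact_log = eeg$artifact_log),
    class = "gait_session"
  )
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf(
    "<gait_session> subject %d, condition %s: %d-ch EEG, %d right strides\n",
    x$subject_id, x$condition, nrow(x$eeg$data),
    length(x$true_events$right)))
  invisible(x)
}

#' Inject stereotyped artifacts into an EEG recording
#'
#' Adds three artifact families to a copy of the recording: eye blinks
#' (~300 ms low-frequency transients with a frontal-dominant scalp pattern),
#' sinusoidal mains interference on all channels, and broadband EMG bursts on
#' temporal channels. Ground-truth artifact time stamps are retained in the
#' returned recording's `artifact_log`.
#'
#' @param eeg an [eeg_recording()].
#' @param spec artifact specification list, see [session_config()]. Rates or
#'   amplitudes of zero disable the corresponding family.
#' @param seed integer seed for artifact placement.
#' @return A new [eeg_recording()]; the input is unmodified.
#' @export
inject_artifacts <- function(eeg, spec = default_artifact_spec(), seed = 1L) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (any(unlist(spec[c("blink_rate", "emg_rate")]) < 0)) {
    stop("artifact rates must be >= 0")
  }
  set.seed(as.integer(seed))
  fs <- eeg$sampling_rate
  n <- n_samples(eeg)
  dur <- n / fs
  labels <- eeg$channel_labels
  data <- eeg$data
  log <- list(blink_times = numeric(0), emg_times = numeric(0),
              line_amplitude = 0, blink_duration = spec$blink_duration %||% 0.3,
              emg_duration = spec$emg_duration %||% 0.3)

  if (spec$blink_rate > 0 && spec$blink_amplitude > 0) {
    n_blinks <- rpois(1, spec$blink_rate * dur)
    bdur <- spec$blink_duration
    times <- sort(runif(n_blinks, bdur, dur - bdur))
    w <- region_weights(labels, "frontal")
    len <- round(bdur * fs)
    template <- spec$blink_amplitude * 0.5 *
      (1 - cos(2 * pi * seq_len(len) / (len + 1)))
    for (tt in times) {
      i0 <- round(tt * fs)
      idx <- i0:(i0 + len - 1L)
      keep <- idx >= 1L & idx <= n
      data[w > 0, idx[keep]] <- data[w > 0, idx[keep]] +
        outer(w[w > 0], template[keep])
    }
    log$blink_times <- times
  }

  if ((spec$line_amplitude %||% 0) > 0) {
    tvec <- (seq_len(n) - 1) / fs
    line <- spec$line_amplitude * sin(2 * pi * spec$line_freq * tvec +
                                      runif(1, 0, 2 * pi))
    data <- data + matrix(line, nrow(data), n, byrow = TRUE)
    log$line_amplitude <- spec$line_amplitude
  }

  if (spec$emg_rate > 0 && spec$emg_amplitude > 0) {
    n_bursts <- rpois(1, spec$emg_rate * dur)
    edur <- spec$emg_duration
    times <- sort(runif(n_bursts, edur, dur - edur))
    w <- region_weights(labels, "temporal")
    len <- round(edur * fs)
    env <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
    hp_edge <- min(100, fs / 2 * 0.9)
    flt <- butter_design(4L, c(30, hp_edge) / (fs / 2), "pass")
    for (tt in times) {
      burst <- zp_filtfilt(flt$b, flt$a, rnorm(len))
      burst <- spec$emg_amplitude * env * burst / sd(burst)
      i0 <- round(tt * fs)
      idx <- i0:(i0 + len - 1L)
      keep <- idx >= 1L & idx <= n
      chan <- which(w > 0)
      gains <- runif(length(chan), 0.5, 1)
      data[chan, idx[keep]] <- data[chan, idx[keep]] +
        outer(gains, burst[keep])
    }
    log$emg_times <- times
  }

  out <- eeg_recording(data, fs, labels, eeg$start_time)
  out$artifact_log <- log
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
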