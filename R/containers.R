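# Core data containers shared by all pipeline stages.

#' Multichannel EEG recording
#'
#' Container for a multichannel EEG signal in microvolts. Data are stored as a
#' channels x samples matrix together with the sampling rate and 10-20 channel
#' labels, mirroring the layout of common EEG acquisition formats.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param channel_labels character vector of channel names, one per row of
#'   `data`. Defaults to `Ch1..ChN`.
#' @param start_time time of the first sample in seconds from trial start.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels = NULL,
                          start_time = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("EEG data must be numeric")
  if (!all(is.finite(data))) stop("EEG data must be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("Ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels length (", length(channel_labels),
         ") must equal channel count (", nrow(data), ")")
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, sampling_rate = as.numeric(sampling_rate),
         channel_labels = as.character(channel_labels),
         start_time = as.numeric(start_time)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)
rec_times <- function(rec) {
  rec$start_time + (seq_len(n_samples(rec)) - 1L) / rec$sampling_rate
}

#' Uniformly sampled motion or force time series
#'
#' Holds one side's heel-marker vertical position (mm) or vertical ground
#' reaction force (N) on a uniform time grid.
#'
#' @param time time stamps in seconds, strictly increasing and uniform.
#' @param values signal values (mm for markers, N for forces).
#' @param side `"left"` or `"right"`.
#' @param kind `"marker"` or `"force"`.
#' @param tol_step allowed relative deviation of the time step from its
#'   median before the grid is declared non-uniform.
#' @return An object of class `motion_series`.
#' @export
motion_series <- function(time, values, side = c("right", "left"),
                          kind = c("marker", "force"), tol_step = 0.01) {
  side <- match.arg(side)
  kind <- match.arg(kind)
  time <- as.numeric(time); values <- as.numeric(values)
  if (length(time) != length(values)) stop("time and values lengths differ")
  if (length(time) < 2L) stop("need at least two samples")
  if (!all(is.finite(time)) || !all(is.finite(values))) {
    stop("time and values must be finite")
  }
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  step <- median(dt)
  if (max(abs(dt - step)) > tol_step * step) {
    stop("time grid is not uniform (max deviation exceeds ", tol_step * 100,
         "% of the median step)")
  }
  structure(
    list(time = time, values = values, side = side, kind = kind,
         sampling_rate = 1 / step),
    class = "motion_series"
  )
}

#' @export
print.motion_series <- function(x, ...) {
  cat(sprintf("<motion_series> %s %s: %d samples @ %g Hz\n",
              x$side, x$kind, length(x$time), x$sampling_rate))
  invisible(x)
}

#' Gait event series
#'
#' Strictly increasing heel-strike times for one body side, with the source
#' they were detected from. Inter-event intervals are validated against
#' physiological stride bounds.
#'
#' @param times event times in seconds.
#' @param side `"left"` or `"right"`.
#' @param source `"marker"`, `"force"` or `"reconciled"`.
#' @param bounds physiological stride-duration bounds in seconds; intervals
#'   outside them raise an error (use the detectors, which filter, rather
#'   than constructing invalid series directly).
#' @param match_rate for reconciled series, fraction of marker events
#'   confirmed by a force event.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(times, side = c("right", "left"),
                        source = c("marker", "force", "reconciled"),
                        bounds = c(0.4, 2.5), match_rate = NA_real_) {
  side <- match.arg(side)
  source <- match.arg(source)
  times <- as.numeric(times)
  if (any(!is.finite(times))) stop("event times must be finite")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("event times must be strictly increasing")
  }
  structure(
    list(times = times, side = side, source = source, bounds = bounds,
         match_rate = match_rate),
    class = "gait_events"
  )
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %s/%s: %d events", x$side, x$source,
              length(x$times)))
  if (length(x$times) > 1L) {
    cat(sprintf(", stride %.3f +/- %.3f s", mean(diff(x$times)),
                sd(diff(x$times))))
  }
  if (!is.na(x$match_rate)) cat(sprintf(", match rate %.3f", x$match_rate))
  cat("\n")
  invisible(x)
}

#' @export
length.gait_events <- function(x) length(x$times)

#' Set of time-normalized gait cycles
#'
#' Result of cutting an EEG recording into gait cycles. `normalized` holds the
#' channels x n x cycles array of cycles linearly resampled onto n equally
#' spaced points of the 0-100% gait cycle; `raw` keeps the untouched
#' native-rate slice of each cycle (used by features that need the original
#' sampling rate, such as wavelet energies and band-filtered Hjorth
#' parameters).
#'
#' @param normalized channels x n x cycles numeric array.
#' @param raw list of channels x m_k matrices, one per cycle.
#' @param spans cycles x 2 matrix of (t_start, t_end) in seconds.
#' @param sampling_rate native EEG sampling rate in Hz.
#' @param channel_labels channel names.
#' @param subject,condition identifiers propagated to feature tables.
#' @param n_discarded number of candidate cycles dropped by the stride-duration
#'   bounds.
#' @return An object of class `cycle_set`.
#' @export
cycle_set <- function(normalized, raw, spans, sampling_rate, channel_labels,
                      subject = NA, condition = NA, n_discarded = 0L) {
  stopifnot(length(dim(normalized)) == 3L)
  if (dim(normalized)[3] != length(raw)) stop("raw/normalized cycle mismatch")
  structure(
    list(normalized = normalized, raw = raw, spans = spans,
         sampling_rate = sampling_rate,
         channel_labels = as.character(channel_labels),
         subject = subject, condition = condition,
         n_discarded = as.integer(n_discarded)),
    class = "cycle_set"
  )
}

#' @export
length.cycle_set <- function(x) dim(x$normalized)[3]

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf(
    "<cycle_set> %d cycles x %d channels (normalized to %d samples; %d discarded)\n",
    length(x), dim(x$normalized)[1], dim(x$normalized)[2], x$n_discarded))
  invisible(x)
}
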