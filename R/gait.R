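# Heel-strike detection from heel-marker minima and GRF onsets, marker/force
# reconciliation, and EEG segmentation into 0-100% time-normalized cycles.

# Prominence of a local minimum: smallest rise separating it from a lower
# point (or the record edge) on either side.
min_prominence <- function(x, i) {
  n <- length(x)
  left_max <- -Inf
  j <- i - 1L
  while (j >= 1L && x[j] >= x[i]) {
    if (x[j] > left_max) left_max <- x[j]
    j <- j - 1L
  }
  if (j < 1L && left_max == -Inf) left_max <- x[i]
  right_max <- -Inf
  j <- i + 1L
  while (j <= n && x[j] >= x[i]) {
    if (x[j] > right_max) right_max <- x[j]
    j <- j + 1L
  }
  if (j > n && right_max == -Inf) right_max <- x[i]
  min(left_max, right_max) - x[i]
}

# Sub-sample refinement of a local extremum by parabolic interpolation.
parabolic_vertex <- function(x, i, time, step) {
  if (i <= 1L || i >= length(x)) return(time[i])
  denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
  if (abs(denom) < .Machine$double.eps) return(time[i])
  delta <- 0.5 * (x[i - 1L] - x[i + 1L]) / denom
  time[i] + max(-1, min(1, delta)) * step
}

#' Detect heel strikes from heel-marker minima
#'
#' Low-pass filters the heel vertical position and places one event at each
#' sufficiently prominent local minimum (the lowest heel position during
#' walking marks heel strike), with a minimum separation between events.
#' Event times are refined to sub-sample precision by parabolic
#' interpolation.
#'
#' @param heel_z a [motion_series()] of kind `"marker"`.
#' @param lowpass low-pass edge in Hz applied before minimum picking.
#' @param prominence_frac required minimum prominence as a fraction of the
#'   filtered signal range.
#' @param min_separation minimum time between successive events in seconds.
#' @param resolution signals with a range below this (mm) are treated as
#'   flat and give an empty series with a warning.
#' @return A [gait_events()] with `source = "marker"`.
#' @export
detect_events_marker <- function(heel_z, lowpass = 6, prominence_frac = 0.3,
                                 min_separation = 0.4, resolution = 1e-3) {
  stopifnot(inherits(heel_z, "motion_series"))
  fs <- heel_z$sampling_rate
  x <- heel_z$values
  if (diff(range(x)) < resolution) {
    warning("flat heel trajectory: no events detected")
    return(gait_events(numeric(0), side = heel_z$side, source = "marker"))
  }
  flt <- butter_design(4L, min(lowpass / (fs / 2), 0.99), "low")
  xf <- zp_filtfilt(flt$b, flt$a, x)
  n <- length(xf)
  cand <- which(diff(sign(diff(xf))) > 0) + 1L   # strict local minima
  if (!length(cand)) {
    return(gait_events(numeric(0), side = heel_z$side, source = "marker"))
  }
  prom <- vapply(cand, function(i) min_prominence(xf, i), numeric(1))
  rng <- diff(range(xf))
  cand <- cand[prom >= prominence_frac * rng]
  # enforce minimum separation, keeping the deeper minimum of any close pair
  if (length(cand) > 1L) {
    ord <- cand[order(xf[cand])]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(heel_z$time[kept] - heel_z$time[i]) >=
                               min_separation)) {
        kept <- c(kept, i)
      }
    }
    cand <- sort(kept)
  }
  times <- vapply(cand, function(i) parabolic_vertex(xf, i, heel_z$time,
                                                     1 / fs), numeric(1))
  gait_events(times, side = heel_z$side, source = "marker")
}

#' Detect heel strikes from vertical GRF onsets
#'
#' Places an event at every upward crossing of the force threshold that is
#' preceded by at least `swing_min` seconds below threshold (the unloaded
#' swing phase); heel strike produces a sudden rise of the vertical ground
#' reaction force. Crossing times are linearly interpolated between samples.
#'
#' @param grf a [motion_series()] of kind `"force"`.
#' @param threshold force threshold in newtons (> 0).
#' @param swing_min required duration below threshold before a crossing, in
#'   seconds.
#' @return A [gait_events()] with `source = "force"`.
#' @export
detect_events_grf <- function(grf, threshold = 20, swing_min = 0.05) {
  stopifnot(inherits(grf, "motion_series"))
  if (threshold <= 0) stop("threshold must be positive")
  x <- grf$values
  fs <- grf$sampling_rate
  below <- x < threshold
  cross <- which(below[-length(x)] & !below[-1]) + 1L
  need <- max(1L, round(swing_min * fs))
  ok <- vapply(cross, function(i) {
    lo <- max(1L, i - need)
    all(below[lo:(i - 1L)]) && (i - 1L) >= need
  }, logical(1))
  cross <- cross[ok]
  if (!length(cross)) {
    return(gait_events(numeric(0), side = grf$side, source = "force"))
  }
  times <- vapply(cross, function(i) {
    frac <- (threshold - x[i - 1L]) / (x[i] - x[i - 1L])
    grf$time[i - 1L] + frac / fs
  }, numeric(1))
  gait_events(times, side = grf$side, source = "force")
}

#' Reconcile marker-derived events with forceplate events
#'
#' Keeps the marker events that are confirmed by a force event within the
#' tolerance; marker timing is primary, the forceplate only confirms. The
#' fraction of confirmed marker events is reported as the match rate.
#'
#' @param marker a [gait_events()] with `source = "marker"`.
#' @param force a [gait_events()] with `source = "force"`, same side.
#' @param tol matching tolerance in seconds.
#' @return A [gait_events()] with `source = "reconciled"` and a
#'   `match_rate` element.
#' @export
reconcile_events <- function(marker, force, tol = 0.05) {
  stopifnot(inherits(marker, "gait_events"), inherits(force, "gait_events"))
  if (marker$side != force$side) {
    stop("marker and force series are from different sides")
  }
  if (!length(marker$times)) {
    return(gait_events(numeric(0), side = marker$side, source = "reconciled",
                       match_rate = NA_real_))
  }
  matched <- vapply(marker$times, function(t) {
    length(force$times) > 0L && min(abs(force$times - t)) <= tol
  }, logical(1))
  gait_events(marker$times[matched], side = marker$side,
              source = "reconciled",
              match_rate = mean(matched))
}

#' Cut an EEG recording into time-normalized gait cycles
#'
#' Each pair of consecutive events defines one half-open cycle
#' `[e_k, e_{k+1})`. The native-rate EEG slice of every retained cycle is
#' kept untouched, and each channel is additionally resampled by linear
#' interpolation onto `n` equally spaced points of the 0-100% gait cycle.
#' Cycles whose duration falls outside the physiological stride bounds are
#' discarded and counted.
#'
#' @param rec a preprocessed [eeg_recording()].
#' @param events a [gait_events()]; all events must lie within the recording.
#' @param n number of normalized samples per cycle (default 100).
#' @param bounds stride-duration bounds in seconds; cycles outside are
#'   dropped.
#' @return A [cycle_set()] (empty when fewer than 2 events are given).
#' @export
segment_and_normalize <- function(rec, events, n = 100L,
                                  bounds = c(0.4, 2.5)) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(events, "gait_events"))
  n <- as.integer(n)
  fs <- rec$sampling_rate
  n_ch <- n_channels(rec)
  t_end_rec <- rec$start_time + n_samples(rec) / fs
  empty <- function(n_disc = 0L) {
    cycle_set(array(numeric(0), c(n_ch, n, 0L)), list(),
              matrix(numeric(0), 0L, 2L), fs, rec$channel_labels,
              n_discarded = n_disc)
  }
  ev <- events$times
  if (length(ev) < 2L) return(empty())
  if (any(ev < rec$start_time) || any(ev > t_end_rec)) {
    stop("events lie outside the recording span")
  }
  durs <- diff(ev)
  keep <- durs >= bounds[1] & durs <= bounds[2]
  n_disc <- sum(!keep)
  starts <- ev[-length(ev)][keep]
  ends <- ev[-1L][keep]
  if (!length(starts)) return(empty(n_disc))

  raw <- vector("list", length(starts))
  norm <- array(NA_real_, c(n_ch, n, length(starts)))
  for (k in seq_along(starts)) {
    # half-open sample span [start, end): samples with t in [e_k, e_{k+1})
    s0 <- ceiling((starts[k] - rec$start_time) * fs - 1e-9) + 1L
    m <- round((ends[k] - starts[k]) * fs)
    s1 <- min(s0 + m - 1L, n_samples(rec))
    slice <- rec$data[, s0:s1, drop = FALSE]
    raw[[k]] <- slice
    m_k <- ncol(slice)
    # positions (in slice sample coordinates) of the n normalized points,
    # covering phases 0, 1/n, ..., (n-1)/n of the half-open cycle
    pos <- 1 + (0:(n - 1L)) / n * m_k
    j <- pmin(floor(pos), m_k)
    w <- pos - j
    j2 <- pmin(j + 1L, m_k)
    norm[, , k] <- slice[, j, drop = FALSE] * rep(1 - w, each = n_ch) +
      slice[, j2, drop = FALSE] * rep(w, each = n_ch)
  }
  cycle_set(norm, raw, cbind(starts, ends), fs, rec$channel_labels,
            n_discarded = n_disc)
}
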