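# Zero-phase Butterworth filtering used by preprocessing, event detection
# and band-limited feature extraction.

# Steady-state initial conditions for a direct-form-II-transposed filter
# driven by a unit step, so that forward-backward filtering has no start-up
# transient on constant signals.
filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  if (n == 1L) return(numeric(0))
  A <- cbind(-a[-1], rbind(diag(1, n - 2L), rep(0, max(n - 2L, 0))))
  if (n == 2L) A <- matrix(-a[2], 1, 1)
  zid <- b[-1] - a[-1] * b[1]
  M <- diag(1, n - 1L) - A
  tryCatch(solve(M, zid), error = function(e) {
    # very narrow-band designs can be numerically singular here; a zero
    # initial state is safe because callers reflect-pad the signal
    tryCatch(qr.solve(M, zid), error = function(e2) numeric(n - 1L))
  })
}

# Zero-phase (forward-backward) filtering of a samples x channels matrix.
zp_filtfilt <- function(b, a, x, padlen = NULL) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  if (is.null(padlen)) padlen <- 3L * (max(length(a), length(b)) - 1L)
  padlen <- min(padlen, nrow(x) - 1L)
  zi <- filter_zi(b, a)
  out <- cpp_filtfilt(as.numeric(b), as.numeric(a), x, as.numeric(zi),
                      as.integer(padlen))
  if (vec) drop(out) else out
}

butter_design <- function(order, w, type) {
  flt <- signal::butter(order, w, type = type)
  list(b = flt$b, a = flt$a)
}

# Zero-phase Butterworth applied to an eeg_recording (channels x samples),
# returning a new recording. A generous reflection pad (~1 s) keeps the
# forward-backward start-up transient of narrow-band and low-cutoff stages
# out of the returned signal.
apply_zp_butter <- function(rec, order, w, type) {
  flt <- butter_design(order, w, type)
  padlen <- min(n_samples(rec) - 1L, round(rec$sampling_rate))
  out <- t(zp_filtfilt(flt$b, flt$a, t(rec$data), padlen = padlen))
  eeg_recording(out, rec$sampling_rate, rec$channel_labels, rec$start_time)
}

#' Band-pass plus band-stop filtering of an EEG recording
#'
#' Applies the standard EEG cleaning filters: a high-pass at `hp`, a low-pass
#' at `lp`, and a band-stop over `stop` to suppress mains interference. All
#' stages are 4th-order Butterworth filters applied forward-backward
#' (zero-phase), so gait-event timing is not shifted.
#'
#' @param rec an [eeg_recording()].
#' @param hp high-pass edge in Hz (default 1).
#' @param lp low-pass edge in Hz (default 70).
#' @param stop length-2 numeric, band-stop edges in Hz (default `c(55, 65)`).
#' @param order filter order per stage (default 4).
#' @return A new, filtered [eeg_recording()].
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2000), 2), 500)
#' filt <- bandpass_bandstop(rec, hp = 1, lp = 70, stop = c(55, 65))
#' @export
bandpass_bandstop <- function(rec, hp = 1, lp = 70, stop = c(55, 65),
                              order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(hp < stop[1] && stop[1] < stop[2] && stop[2] < lp)) {
    stop("frequency ordering violated: need hp < stop[1] < stop[2] < lp")
  }
  if (lp >= nyq) {
    stop("low-pass edge ", lp, " Hz requires sampling rate > ", 2 * lp, " Hz")
  }
  rec <- apply_zp_butter(rec, order, hp / nyq, "high")
  rec <- apply_zp_butter(rec, order, lp / nyq, "low")
  apply_zp_butter(rec, order, stop / nyq, "stop")
}

# Band-pass filter a samples x channels matrix to a named EEG band.
# Narrow bands ring for a while, so pad with up to half a second.
band_filter <- function(x, sampling_rate, band, order = 4L) {
  edges <- switch(band,
    theta = c(4, 7), alpha = c(8, 12), beta = c(12, 30),
    stop("unknown band: ", band))
  flt <- butter_design(order, edges / (sampling_rate / 2), "pass")
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  zp_filtfilt(flt$b, flt$a, x,
              padlen = min(n - 1L, round(sampling_rate / 2)))
}

#' Welch band power estimate
#'
#' Average power of a signal within a frequency band, estimated by Welch's
#' method (Hann-windowed overlapping segments, averaged periodograms).
#'
#' @param x numeric signal.
#' @param sampling_rate sampling rate in Hz.
#' @param band length-2 numeric band edges in Hz.
#' @param nperseg segment length in samples (default: 2 s worth, capped at
#'   the signal length).
#' @return Power (signal units squared) integrated over the band.
#' @export
band_power <- function(x, sampling_rate, band, nperseg = NULL) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, round(2 * sampling_rate))
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  scale <- sum(w^2)
  psd <- 0
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    psd <- psd + Mod(fft(seg))^2 / scale
  }
  psd <- psd / length(starts)
  freqs <- (seq_len(nperseg) - 1L) * sampling_rate / nperseg
  sel <- freqs >= band[1] & freqs <= band[2] & freqs <= sampling_rate / 2
  # one-sided: double everything except DC/Nyquist, then normalise to power
  fac <- ifelse(freqs[sel] == 0 | freqs[sel] == sampling_rate / 2, 1, 2)
  sum(psd[sel] * fac) / nperseg
}
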