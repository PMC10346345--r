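# Zero-phase filtering and ICA-based artifact removal.

test_that("band-pass keeps in-band content and removes DC and mains", {
  fs <- 1000
  t <- seq(1 / fs, 5, by = 1 / fs)
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * t),
                             sin(2 * pi * 60 * t),
                             rep(100, length(t))), fs,
                       c("C3", "C4", "Cz"))
  out <- bandpass_bandstop(rec)
  rms <- function(x) sqrt(mean(x^2))
  r10 <- rms(out$data[1, ]) / rms(rec$data[1, ])
  expect_gte(r10, 0.9)
  expect_lte(r10, 1.02)
  expect_lte(rms(out$data[2, ]) / rms(rec$data[2, ]), 0.1)
  expect_lte(abs(mean(out$data[3, ])), 1)
})

test_that("filter frequency ordering and rate limits are enforced", {
  rec <- eeg_recording(matrix(rnorm(2000), 2), 1000)
  expect_error(bandpass_bandstop(rec, hp = 60, stop = c(55, 65)), "ordering")
  expect_error(bandpass_bandstop(rec, stop = c(65, 55)), "ordering")
  low_rate <- eeg_recording(matrix(rnorm(260), 2), 130)
  expect_error(bandpass_bandstop(low_rate), "sampling rate")
})

test_that("filtering is linear", {
  set.seed(4)
  x <- rnorm(3000); y <- rnorm(3000)
  f <- function(v) bandpass_bandstop(eeg_recording(rbind(v), 1000))$data
  lhs <- f(2 * x + 3 * y)
  # relative to the signal scale; the 1 Hz high-pass stage is numerically
  # delicate in transfer-function form, so exact cancellation stops at
  # roundoff amplified by its near-singular coefficients
  expect_lt(max(abs(lhs - 2 * f(x) - 3 * f(y))) / max(abs(lhs)), 1e-7)
})

test_that("FastICA recovers independent sources up to sign/permutation", {
  set.seed(5)
  S <- rbind(runif(5000, -1, 1), runif(5000, -1, 1))
  X <- matrix(c(1, 0.5, 0.3, 1), 2) %*% S
  rec <- eeg_recording(X, 100, c("C3", "C4"))
  dec <- decompose_ica(rec, seed = 1)
  cc <- abs(cor(t(dec$sources), t(S)))
  expect_true(all(apply(cc, 2, max) > 0.95))
  # unmixing . mixing = identity
  expect_lt(max(abs(dec$unmixing %*% dec$mixing - diag(2))), 1e-6)
  # full reconstruction
  recon <- dec$mixing %*% dec$sources + dec$center
  expect_lt(max(abs(recon - X)) / max(abs(X)), 1e-6)
  # deterministic under seed
  dec2 <- decompose_ica(rec, seed = 1)
  expect_identical(dec$mixing, dec2$mixing)
  # sources have unit variance
  expect_equal(unname(apply(dec$sources, 1, sd)), c(1, 1), tolerance = 1e-8)
})

test_that("rank-deficient data reduce the component count with a warning", {
  set.seed(6)
  base <- rnorm(4000)
  X <- rbind(base, 2 * base, rnorm(4000))
  rec <- eeg_recording(X, 100, c("C3", "C4", "Cz"))
  expect_warning(dec <- decompose_ica(rec, seed = 1), "rank")
  expect_equal(nrow(dec$unmixing), 2)
})

test_that("ICA requires enough samples per channel", {
  rec <- eeg_recording(matrix(rnorm(4 * 60), 4), 100)
  expect_error(decompose_ica(rec), "20 samples")
})

test_that("component scoring identifies planted source types", {
  set.seed(7)
  fs <- 250
  n <- 60 * fs
  t <- seq_len(n) / fs
  labels <- c("Fp1", "Fp2", "Cz", "O1", "O2", "T7")
  # three planted sources: blink transients (frontal), 60 Hz line (all
  # channels), posterior alpha
  blink <- rep(0, n)
  for (b in seq(2, 58, by = 4)) {
    idx <- round(b * fs):(round(b * fs) + round(0.3 * fs))
    blink[idx] <- sin(pi * seq_along(idx) / length(idx))^2
  }
  line <- sin(2 * pi * 60 * t)
  alpha <- neurogait:::band_source(n, fs, c(8, 12))
  W <- cbind(c(1, 0.9, 0.1, 0, 0, 0.1),       # blink: frontal
             c(1, 1, 1, 1, 1, 1),             # line: everywhere
             c(0, 0, 0.2, 1, 0.9, 0.1))       # alpha: posterior
  X <- W %*% rbind(80 * blink, 10 * line, 20 * alpha) +
    matrix(rnorm(6 * n, sd = 2), 6)
  dec <- decompose_ica(eeg_recording(X, fs, labels), seed = 2)
  dec <- score_components(dec)
  argmax <- colnames(dec$component_scores)[
    apply(dec$component_scores, 1, which.max)]
  # identify each planted source's component by source correlation
  best <- function(src) which.max(abs(cor(t(dec$sources), src)))
  expect_equal(argmax[best(blink)], "eye")
  expect_equal(argmax[best(line)], "line_noise")
  expect_equal(argmax[best(alpha)], "brain")
  expect_equal(unname(rowSums(dec$component_scores)),
               rep(1, nrow(dec$component_scores)), tolerance = 1e-9)
})

test_that("artifact removal preserves shape, is idempotent and respects the threshold", {
  set.seed(8)
  X <- matrix(rnorm(4 * 4000), 4)
  rec <- eeg_recording(X, 200, c("Fp1", "Cz", "O1", "T7"))
  dec <- score_components(decompose_ica(rec, seed = 3))
  expect_error(remove_artifacts(dec, threshold = 0), "0, 1")
  expect_error(remove_artifacts(dec, threshold = 1.5), "0, 1")
  out <- remove_artifacts(dec, threshold = 0.9)
  expect_equal(dim(out$data), dim(rec$data))
  # threshold 1.0 with no score equal to 1: nothing removed, output is the
  # full reconstruction (= input for a full-rank decomposition)
  out1 <- remove_artifacts(dec, threshold = 1.0)
  expect_lt(max(abs(out1$data - rec$data)) / max(abs(rec$data)), 1e-6)
  # forcing all components to read as brain keeps the input unchanged
  dec_brain <- dec
  dec_brain$component_scores[] <- 0
  dec_brain$component_scores[, "brain"] <- 1
  out2 <- remove_artifacts(dec_brain, threshold = 0.9)
  expect_lt(max(abs(out2$data - rec$data)) / max(abs(rec$data)), 1e-6)
  # idempotence for fixed scores: removing twice equals removing once
  dec_again <- dec
  dec_again$sources <- dec$unmixing %*% (out$data - dec$center)
  out_twice <- remove_artifacts(dec_again, threshold = 0.9)
  expect_equal(out_twice$data, out$data, tolerance = 1e-8)
})
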