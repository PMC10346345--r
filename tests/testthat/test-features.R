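# Per-channel biomarkers: direct evaluations, brute-force agreement,
# scale/shift equivariance, and feature-vector assembly.

test_that("time-domain features match direct evaluations", {
  f <- time_domain_features(c(1, 2, 3))
  expect_equal(unname(f["mean"]), 2)
  expect_equal(unname(f["mad"]), 2 / 3)
  expect_equal(unname(f["rms"]), sqrt(14 / 3))
  expect_equal(unname(f["aac"]), 1)
  const <- suppressWarnings(time_domain_features(rep(5, 10)))
  expect_equal(unname(const[c("mad", "var", "aac", "skew", "kurt")]),
               c(0, 0, 0, 0, 0))
  expect_equal(unname(const["rms"]), 5)
  expect_warning(time_domain_features(rep(1, 4)), "zero-variance")
  expect_error(time_domain_features(c(1, NA, 3)), "finite")
  expect_error(time_domain_features(1), "2 samples")
})

test_that("large-sample moments of a standard normal are correct", {
  set.seed(11)
  f <- time_domain_features(rnorm(1e5))
  expect_lt(abs(f["skew"]), 0.1)
  expect_lt(abs(f["kurt"] - 3), 0.1)
})

test_that("Hjorth activity equals the variance and sinusoid complexity is 1", {
  set.seed(12)
  x <- rnorm(500)
  h <- hjorth_params(x)
  expect_equal(unname(h["activity"]), mean((x - mean(x))^2))
  s <- sin(2 * pi * 5 * (0:20000) / 1000)   # fs = 200 * f
  expect_lt(abs(hjorth_params(s)["complexity"] - 1), 0.01)
  expect_warning(h0 <- hjorth_params(rep(2, 10)), "zero-variance")
  expect_equal(unname(h0), c(0, 0, 0))
})

test_that("Hjorth parameters equal the brute-force finite differences", {
  set.seed(13)
  for (i in 1:5) {
    x <- rnorm(200)
    expect_equal(hjorth_params(x), naive_hjorth(x), tolerance = 1e-12)
  }
})

test_that("entropy features match their definitions", {
  e <- entropy_features(c(0.1, 0.5, 0.9), eps = 0.4)
  expect_equal(unname(e["threshold_entropy"]), 2)
  expect_equal(unname(e["sure_entropy"]),
               3 - 1 + (0.1^2 + 0.16 + 0.16))
  expect_equal(unname(e["norm_entropy"]), 0.1^1.5 + 0.5^1.5 + 0.9^1.5)
  # all samples in one histogram bin
  expect_equal(unname(entropy_features(rep(3, 10))["shannon_entropy"]), 0)
  # samples uniformly filling all 16 bins
  u <- rep(seq(0.5 / 16, 1 - 0.5 / 16, length.out = 16), 5)
  expect_equal(unname(entropy_features(u)["shannon_entropy"]), log(16))
  # zero samples contribute nothing to the log-energy
  expect_equal(unname(entropy_features(c(0, 2, 0))["log_entropy"]),
               log(4))
})

test_that("wavelet energies satisfy Parseval and map frequency to levels", {
  set.seed(14)
  x <- rnorm(1100)
  d <- dwt_db2(x, 8)
  rel <- abs(sum(d$energies) + sum(d$approximation^2) - sum(x^2)) / sum(x^2)
  expect_lt(rel, 1e-6)
  # zero signal
  w0 <- wavelet_features(rep(0, 1024), 8)
  expect_true(all(w0 == 0))
  # a 250 Hz sinusoid at fs 1000 lives in the first detail band
  s <- sin(2 * pi * 250 * (1:1000) / 1000)
  ws <- wavelet_features(s, 8)
  expect_gte(ws["wavelet_e1"] / sum(ws[paste0("wavelet_e", 1:8)]), 0.8)
  # infeasible level errors and names the maximum
  expect_error(dwt_db2(rnorm(100), 8), "maximum feasible level is 5")
})

test_that("wavelet energies match the explicit-matrix transform", {
  set.seed(15)
  for (n in c(700, 1024, 1311)) {
    x <- rnorm(n)
    mine <- wavelet_features(x, 6)
    ref <- naive_dwt_energies(x, 6)
    expect_equal(unname(mine[paste0("wavelet_e", 1:6)]), ref$energies,
                 tolerance = 1e-10)
    expect_equal(unname(mine["wavelet_energy_sd"]), ref$sd,
                 tolerance = 1e-10)
  }
})

test_that("features obey their scale and shift equivariances", {
  set.seed(16)
  x <- rnorm(100)
  a <- -2.7
  c0 <- 5.3
  f1 <- time_domain_features(x)
  fa <- time_domain_features(a * x)
  fc <- time_domain_features(x + c0)
  expect_equal(unname(fa["rms"]), abs(a) * unname(f1["rms"]))
  expect_equal(unname(fa["mad"]), abs(a) * unname(f1["mad"]))
  expect_equal(unname(fa["var"]), a^2 * unname(f1["var"]))
  expect_equal(unname(fc[c("mad", "var", "aac")]),
               unname(f1[c("mad", "var", "aac")]))
  h1 <- hjorth_params(x)
  ha <- hjorth_params(a * x)
  hc <- hjorth_params(x + c0)
  expect_equal(unname(ha[c("mobility", "complexity")]),
               unname(h1[c("mobility", "complexity")]), tolerance = 1e-12)
  expect_equal(unname(hc), unname(h1), tolerance = 1e-9)
  xr <- rnorm(1024)
  w1 <- wavelet_features(xr, 6)
  wa <- wavelet_features(a * xr, 6)
  expect_equal(unname(wa), a^2 * unname(w1), tolerance = 1e-10)
})

test_that("feature vectors have 29 features per channel with stable names", {
  cyc <- random_cycle_set(n_cycles = 1, n_channels = 3, seed = 20)
  v <- build_feature_vector(cyc, 1)
  expect_length(v, 3 * 29)
  expect_true(all(is.finite(v)))
  expect_equal(sum(startsWith(names(v), "Ch2__")), 29)
  # two identical channels give identical feature blocks
  cyc$raw[[1]][2, ] <- cyc$raw[[1]][1, ]
  cyc$normalized[2, , 1] <- cyc$normalized[1, , 1]
  v2 <- build_feature_vector(cyc, 1)
  expect_equal(unname(v2[startsWith(names(v2), "Ch1__")]),
               unname(v2[startsWith(names(v2), "Ch2__")]))
  # renaming channels permutes names, not values
  cyc3 <- random_cycle_set(n_cycles = 1, n_channels = 3, seed = 20)
  cyc4 <- cyc3
  cyc4$channel_labels <- c("X", "Y", "Z")
  expect_equal(unname(build_feature_vector(cyc3, 1)),
               unname(build_feature_vector(cyc4, 1)))
})

test_that("a 64-channel cycle yields 1856 features", {
  cyc <- random_cycle_set(n_cycles = 1, n_channels = 64, seed = 21)
  expect_length(build_feature_vector(cyc, 1), 1856)
})
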