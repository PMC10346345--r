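# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# a default-noise 60 s session used by the gait/ICA tests
fixture_session <- function() {
  memo("session60", function() {
    cfg <- session_config(trial_duration = 60, seed = 3)
    generate_session(cfg, "NW", subject_id = 1)
  })
}

# random normalized-cycle fixture: one cycle_set whose raw slices are long
# enough for the 8-level wavelet decomposition
random_cycle_set <- function(n_cycles = 1, n_channels = 2, fs = 1000,
                             seed = 1) {
  set.seed(seed)
  raw <- vector("list", n_cycles)
  norm <- array(NA_real_, c(n_channels, 100, n_cycles))
  spans <- matrix(NA_real_, n_cycles, 2)
  t0 <- 0
  for (k in seq_len(n_cycles)) {
    m <- sample(900:1300, 1)
    raw[[k]] <- matrix(rnorm(n_channels * m), n_channels)
    pos <- 1 + (0:99) / 100 * m
    j <- pmin(floor(pos), m); w <- pos - j; j2 <- pmin(j + 1, m)
    norm[, , k] <- raw[[k]][, j, drop = FALSE] *
      rep(1 - w, each = n_channels) +
      raw[[k]][, j2, drop = FALSE] * rep(w, each = n_channels)
    spans[k, ] <- c(t0, t0 + m / fs)
    t0 <- t0 + m / fs
  }
  cycle_set(norm, raw, spans, fs, paste0("Ch", seq_len(n_channels)),
            subject = 1, condition = "NW")
}

# small separable feature set for classifier tests
toy_features <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), length.out = n)
  X <- matrix(rnorm(n * 2, sd = 0.25), n, 2,
              dimnames = list(NULL, c("f1", "f2")))
  X[y == "b", 1] <- X[y == "b", 1] + 3
  list(X = X, y = y)
}

# small separable tensor set for the sequence models
toy_tensor <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), length.out = n)
  X <- array(rnorm(2 * 20 * n, sd = 0.3), c(2, 20, n))
  X[1, , y == "b"] <- X[1, , y == "b"] + 2
  list(X = X, y = y)
}

# the end-to-end corpus at the study's desk scale: 4 subjects x 4 conditions
# x 120 s, full preprocessing, segmentation and feature extraction
fixture_e2e <- function() {
  memo("e2e", function() {
    seed <- 1L
    cfg <- pipeline_config(seed = seed)
    gen <- do.call(session_config, c(cfg$simulate, list(seed = seed)))
    cycle_sets <- list()
    tabs <- list()
    for (sj in seq_len(gen$n_subjects)) {
      for (cond in c("NW", "STROOP", "COM", "MLP")) {
        ses <- generate_session(gen, cond, sj)
        rec <- preprocess_eeg(ses$eeg, cfg$preprocess,
                              seed = neurogait:::trial_seed(seed, sj, cond) +
                                7L)
        cyc <- segment_session(ses, rec, cfg$segment)
        key <- sprintf("s%d_%s", sj, cond)
        cycle_sets[[key]] <- cyc
        tabs[[key]] <- build_feature_table(cyc)
      }
    }
    ft <- do.call(rbind, c(tabs, make.row.names = FALSE))
    list(features = ft, stacked = neurogait:::stack_cycles(cycle_sets),
         seed = seed)
  })
}
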