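# The 29-per-channel digital biomarkers computed for every gait cycle:
# 9 time-domain statistics, 6 Hjorth parameters (alpha and beta band),
# 5 entropy measures and 9 Daubechies-2 wavelet energy features.

# Daubechies-2 decomposition filters (orthonormal quadrature mirror pair).
DB2_LO <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
DB2_HI <- rev(DB2_LO) * c(1, -1, 1, -1)

# One level of the periodized (circular) db2 transform. Odd-length inputs
# are zero-padded to even length, which leaves the signal energy unchanged;
# the circular transform with an orthonormal filter pair is orthogonal, so
# energy is partitioned exactly between approximation and detail.
dwt_step_db2 <- function(x) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- c(x, 0)
    n <- n + 1L
  }
  k <- seq(0L, n - 2L, by = 2L)
  a <- numeric(n / 2L)
  d <- numeric(n / 2L)
  for (m in 0:3) {
    xi <- x[(k + m) %% n + 1L]
    a <- a + DB2_LO[m + 1L] * xi
    d <- d + DB2_HI[m + 1L] * xi
  }
  list(approx = a, detail = d)
}

max_dwt_level <- function(n) max(0L, floor(log2(n / 3)))

#' Multi-level Daubechies-2 wavelet decomposition
#'
#' Recursively splits the signal into detail (high-pass) and approximation
#' (low-pass) coefficients. The periodized transform is orthogonal, so the
#' summed energies of all detail levels plus the final approximation equal
#' the signal energy (Parseval identity).
#'
#' @param x numeric signal.
#' @param levels decomposition depth; level `L` is feasible when
#'   `floor(log2(n/3)) >= L`. Requesting more is an error naming the maximum
#'   feasible level.
#' @return A list of class `dwt_db2` with `details` (list `d1..dL`),
#'   `approximation`, and `energies` (sum of squared coefficients per detail
#'   level).
#' @export
dwt_db2 <- function(x, levels = 8L) {
  n <- length(x)
  levels <- as.integer(levels)
  feasible <- max_dwt_level(n)
  if (levels > feasible) {
    stop("decomposition level ", levels, " infeasible for length ", n,
         ": maximum feasible level is ", feasible)
  }
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    st <- dwt_step_db2(a)
    details[[l]] <- st$detail
    a <- st$approx
  }
  names(details) <- paste0("d", seq_len(levels))
  structure(
    list(details = details, approximation = a,
         energies = vapply(details, function(d) sum(d^2), numeric(1))),
    class = "dwt_db2"
  )
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Time-domain features of a normalized cycle signal
#'
#' Mean absolute deviation (average distance of each sample from the mean),
#' root mean square (quadratic mean), maximum, minimum, mean, population
#' variance, skewness and kurtosis (standardized third and fourth central
#' moments), and average amplitude change
#' `AAC = sum(|x[i+1] - x[i]|) / (n - 1)`.
#'
#' @param x numeric signal with at least 2 finite samples.
#' @return Named numeric vector of the 9 features. Zero-variance input
#'   gives skewness and kurtosis of 0 with a degenerate-input warning.
#' @export
time_domain_features <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(x))) stop("input must be finite")
  n <- length(x)
  m <- mean(x)
  v <- pop_var(x)
  if (v == 0) {
    warning("zero-variance input: skewness and kurtosis reported as 0")
    skew <- 0
    kurt <- 0
  } else {
    skew <- mean((x - m)^3) / v^1.5
    kurt <- mean((x - m)^4) / v^2
  }
  c(mad = mean(abs(x - m)),
    rms = sqrt(mean(x^2)),
    max = max(x), min = min(x), mean = m, var = v,
    skew = skew, kurt = kurt,
    aac = sum(abs(diff(x))) / (n - 1L))
}

#' Hjorth parameters
#'
#' Activity (signal variance), mobility (ratio of the standard deviation of
#' the first difference to that of the signal) and complexity (mobility of
#' the first difference divided by the mobility of the signal). Derivatives
#' are unscaled first differences, shortening the signal by one sample per
#' order; variances use the population divisor.
#'
#' @param x numeric signal with at least 3 samples (band-filtered when used
#'   as an alpha/beta-band descriptor).
#' @return Named vector `c(activity, mobility, complexity)`. Zero variance
#'   gives zeros with a degenerate-input warning.
#' @export
hjorth_params <- function(x) {
  if (length(x) < 3L) stop("need at least 3 samples")
  v0 <- pop_var(x)
  if (v0 == 0) {
    warning("zero-variance input: Hjorth parameters reported as 0")
    return(c(activity = 0, mobility = 0, complexity = 0))
  }
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- pop_var(d1)
  v2 <- pop_var(d2)
  mob <- sqrt(v1 / v0)
  mob_d <- if (v1 == 0) 0 else sqrt(v2 / v1)
  c(activity = v0, mobility = mob,
    complexity = if (mob == 0) 0 else mob_d / mob)
}

#' Entropy features of a normalized cycle signal
#'
#' Shannon entropy of the 16-bin amplitude histogram (natural log, with
#' `0 * log 0 := 0`), plus the wavelet-family entropies on the raw samples:
#' log-energy `sum(log(x_i^2))` (zero samples contribute 0), threshold
#' entropy `#\{|x_i| > eps\}`, SURE entropy
#' `n - #\{|x_i| <= eps\} + sum(min(x_i^2, eps^2))`, and norm entropy
#' `sum(|x_i|^p)`.
#'
#' @param x numeric signal.
#' @param eps_k threshold scale: `eps = eps_k * sd(x)` (population sd)
#'   unless `eps` is given directly.
#' @param eps explicit threshold for the threshold/SURE entropies.
#' @param p exponent of the norm entropy.
#' @param bins histogram bin count for the Shannon entropy.
#' @return Named numeric vector of the 5 entropies.
#' @export
entropy_features <- function(x, eps_k = 0.2, eps = NULL, p = 1.5,
                             bins = 16L) {
  if (length(x) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(x))) stop("input must be finite")
  n <- length(x)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    shannon <- 0
  } else {
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
    counts <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                            bins), nbins = bins)
    pr <- counts / n
    pr <- pr[pr > 0]
    shannon <- -sum(pr * log(pr))
  }
  if (is.null(eps)) eps <- eps_k * sqrt(pop_var(x))
  nz <- x[x != 0]
  c(shannon_entropy = shannon,
    log_entropy = sum(log(nz^2)),
    threshold_entropy = sum(abs(x) > eps),
    sure_entropy = n - sum(abs(x) <= eps) + sum(pmin(x^2, eps^2)),
    norm_entropy = sum(abs(x)^p))
}

#' Wavelet energy features of a native-rate cycle signal
#'
#' Detail energies `E(d1)..E(dL)` of the Daubechies-2 decomposition (sum of
#' squared detail coefficients per level) and the standard deviation of the
#' wavelet energies, computed with the population divisor over the `L`
#' detail energies.
#'
#' @param x_raw numeric signal at the native sampling rate.
#' @param levels decomposition depth (default 8; see [dwt_db2()] for the
#'   feasibility rule).
#' @return Named vector `wavelet_e1..wavelet_eL, wavelet_energy_sd`.
#' @export
wavelet_features <- function(x_raw, levels = 8L) {
  dec <- dwt_db2(x_raw, levels)
  e <- dec$energies
  out <- c(e, sqrt(mean((e - mean(e))^2)))
  names(out) <- c(paste0("wavelet_e", seq_len(levels)), "wavelet_energy_sd")
  out
}

FEATURE_NAMES_PER_CHANNEL <- c(
  "mad", "rms", "max", "min", "mean", "var", "skew", "kurt", "aac",
  "hjorth_activity_alpha", "hjorth_mobility_alpha", "hjorth_complexity_alpha",
  "hjorth_activity_beta", "hjorth_mobility_beta", "hjorth_complexity_beta",
  "shannon_entropy", "log_entropy", "threshold_entropy", "sure_entropy",
  "norm_entropy",
  paste0("wavelet_e", 1:8), "wavelet_energy_sd")

#' Assemble the feature vector of one gait cycle
#'
#' Computes, per channel, 9 time-domain features and 5 entropies on the
#' 100-sample normalized signal, 3 Hjorth parameters on each of the alpha
#' (8-12 Hz) and beta (12-30 Hz) band-filtered native-rate slices, and 9
#' wavelet energy features on the raw native-rate slice -- 29 features per
#' channel, concatenated over channels in stable
#' `<channel>__<feature>` name order.
#'
#' @param cycles a [cycle_set()].
#' @param index which cycle of the set.
#' @param levels wavelet decomposition depth.
#' @param eps_k,p entropy parameters, see [entropy_features()].
#' @return Named numeric vector of `n_channels * 29` finite values.
#'   Degenerate channels are flagged with warnings but the vector is still
#'   emitted; any non-finite feature value is an error.
#' @export
build_feature_vector <- function(cycles, index = 1L, levels = 8L,
                                 eps_k = 0.2, p = 1.5) {
  stopifnot(inherits(cycles, "cycle_set"))
  norm <- cycles$normalized[, , index, drop = FALSE][, , 1L]
  if (is.null(dim(norm))) norm <- matrix(norm, nrow = 1L)
  raw <- cycles$raw[[index]]
  fs <- cycles$sampling_rate
  n_ch <- nrow(norm)
  labels <- cycles$channel_labels

  raw_alpha <- t(band_filter(t(raw), fs, "alpha"))
  raw_beta <- t(band_filter(t(raw), fs, "beta"))

  out <- numeric(n_ch * length(FEATURE_NAMES_PER_CHANNEL))
  nms <- character(length(out))
  for (ch in seq_len(n_ch)) {
    block <- c(
      time_domain_features(norm[ch, ]),
      setNames(hjorth_params(raw_alpha[ch, ]),
               c("hjorth_activity_alpha", "hjorth_mobility_alpha",
                 "hjorth_complexity_alpha")),
      setNames(hjorth_params(raw_beta[ch, ]),
               c("hjorth_activity_beta", "hjorth_mobility_beta",
                 "hjorth_complexity_beta")),
      entropy_features(norm[ch, ], eps_k = eps_k, p = p),
      wavelet_features(raw[ch, ], levels = levels))
    if (any(!is.finite(block))) {
      stop("non-finite feature value in channel ", labels[ch])
    }
    i0 <- (ch - 1L) * length(FEATURE_NAMES_PER_CHANNEL)
    out[i0 + seq_along(block)] <- block
    nms[i0 + seq_along(block)] <- paste0(labels[ch], "__", names(block))
  }
  names(out) <- nms
  out
}

#' Build the cycles x features table of a cycle set
#'
#' Applies [build_feature_vector()] to every cycle and prefixes the
#' metadata columns `subject`, `condition` and `cycle_index`.
#'
#' @inheritParams build_feature_vector
#' @param subject,condition metadata; default to the values stored in the
#'   cycle set.
#' @return A data frame with `3 + n_channels * 29` columns.
#' @export
build_feature_table <- function(cycles, levels = 8L, eps_k = 0.2, p = 1.5,
                                subject = cycles$subject,
                                condition = cycles$condition) {
  stopifnot(inherits(cycles, "cycle_set"))
  n_cyc <- length(cycles)
  if (n_cyc == 0L) {
    meta <- data.frame(subject = integer(0), condition = character(0),
                       cycle_index = integer(0))
    feat <- matrix(numeric(0), 0L,
                   length(cycles$channel_labels) *
                     length(FEATURE_NAMES_PER_CHANNEL))
    colnames(feat) <- as.vector(t(outer(cycles$channel_labels,
                                        FEATURE_NAMES_PER_CHANNEL,
                                        paste, sep = "__")))
    return(cbind(meta, as.data.frame(feat)))
  }
  rows <- lapply(seq_len(n_cyc), function(k) {
    build_feature_vector(cycles, k, levels = levels, eps_k = eps_k, p = p)
  })
  feat <- do.call(rbind, rows)
  data.frame(subject = rep(subject, n_cyc),
             condition = rep(condition, n_cyc),
             cycle_index = seq_len(n_cyc),
             feat, check.names = FALSE)
}
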