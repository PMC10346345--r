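# Independently coded brute-force oracles. These deliberately use naive
# loops and first-principles definitions, not the package's vectorized
# implementations.

naive_time_domain <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  mad <- 0; for (v in x) mad <- mad + abs(v - m)
  mad <- mad / n
  rms <- sqrt(sum(x^2) / n)
  v2 <- 0; v3 <- 0; v4 <- 0
  for (v in x) {
    v2 <- v2 + (v - m)^2; v3 <- v3 + (v - m)^3; v4 <- v4 + (v - m)^4
  }
  v2 <- v2 / n; v3 <- v3 / n; v4 <- v4 / n
  aac <- 0
  for (i in seq_len(n - 1)) aac <- aac + abs(x[i + 1] - x[i])
  c(mad = mad, rms = rms, max = max(x), min = min(x), mean = m, var = v2,
    skew = if (v2 == 0) 0 else v3 / v2^1.5,
    kurt = if (v2 == 0) 0 else v4 / v2^2,
    aac = aac / (n - 1))
}

naive_pop_var <- function(x) {
  m <- sum(x) / length(x)
  s <- 0; for (v in x) s <- s + (v - m)^2
  s / length(x)
}

naive_hjorth <- function(x) {
  d1 <- numeric(length(x) - 1)
  for (i in seq_along(d1)) d1[i] <- x[i + 1] - x[i]
  d2 <- numeric(length(d1) - 1)
  for (i in seq_along(d2)) d2[i] <- d1[i + 1] - d1[i]
  v0 <- naive_pop_var(x); v1 <- naive_pop_var(d1); v2 <- naive_pop_var(d2)
  mob <- sqrt(v1 / v0)
  c(activity = v0, mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

naive_entropies <- function(x, eps, p = 1.5, bins = 16) {
  n <- length(x)
  lo <- min(x); hi <- max(x)
  if (lo == hi) {
    shannon <- 0
  } else {
    counts <- integer(bins)
    for (v in x) {
      b <- floor((v - lo) / (hi - lo) * bins) + 1
      if (b > bins) b <- bins
      counts[b] <- counts[b] + 1
    }
    shannon <- 0
    for (cnt in counts) {
      if (cnt > 0) shannon <- shannon - (cnt / n) * log(cnt / n)
    }
  }
  loge <- 0; for (v in x) if (v != 0) loge <- loge + log(v^2)
  thr <- 0; for (v in x) if (abs(v) > eps) thr <- thr + 1
  sure <- n
  for (v in x) {
    if (abs(v) <= eps) sure <- sure - 1
    sure <- sure + min(v^2, eps^2)
  }
  nrm <- 0; for (v in x) nrm <- nrm + abs(v)^p
  c(shannon_entropy = shannon, log_entropy = loge, threshold_entropy = thr,
    sure_entropy = sure, norm_entropy = nrm)
}

# Periodized db2 analysis as an explicit orthogonal matrix product:
# row k of the analysis matrix holds the filter placed at circular offset 2k.
naive_dwt_energies <- function(x, levels) {
  lo <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  hi <- rev(lo) * c(1, -1, 1, -1)
  energies <- numeric(levels)
  a <- x
  for (l in seq_len(levels)) {
    if (length(a) %% 2 == 1) a <- c(a, 0)
    n <- length(a)
    half <- n / 2
    A <- matrix(0, half, n)
    D <- matrix(0, half, n)
    for (k in seq_len(half)) {
      for (m in 0:3) {
        pos <- (2 * (k - 1) + m) %% n + 1
        A[k, pos] <- A[k, pos] + lo[m + 1]
        D[k, pos] <- D[k, pos] + hi[m + 1]
      }
    }
    d <- as.vector(D %*% a)
    energies[l] <- sum(d^2)
    a <- as.vector(A %*% a)
  }
  list(energies = energies, approx = a,
       sd = sqrt(sum((energies - mean(energies))^2) / levels))
}

naive_wilcoxon_u <- function(x, y) {
  u <- 0
  for (xi in x) {
    for (yj in y) {
      if (xi > yj) u <- u + 1 else if (xi == yj) u <- u + 0.5
    }
  }
  u
}

naive_wilcoxon_z <- function(x, y) {
  u <- naive_wilcoxon_u(x, y)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  tie_term <- 0
  for (v in unique(c(x, y))) {
    t <- sum(c(x, y) == v)
    tie_term <- tie_term + t^3 - t
  }
  s2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (s2 <= 0) return(0)
  (u - n1 * n2 / 2) / sqrt(s2)
}

naive_auc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  tot <- 0
  for (p in pos) {
    for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

naive_binary_mcc <- function(tp, fn, fp, tn) {
  (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
}
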