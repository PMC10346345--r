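# FastICA decomposition, rule-based component scoring and artifact removal.
# Components are scored into the label set {eye, muscle, line_noise,
# channel_noise, brain, other}; components whose strongest non-brain label
# exceeds the probability threshold (0.90 by default) are zeroed before
# back-projection, so artifacts are removed while every channel is retained.

symmetric_decorrelate <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

fastica_symmetric <- function(Z, W, maxit, tol) {
  ns <- ncol(Z)
  for (it in seq_len(maxit)) {
    U <- W %*% Z
    G <- tanh(U)
    Gp <- rowMeans(1 - G^2)
    W_new <- (G %*% t(Z)) / ns - diag(Gp, nrow(W)) %*% W
    W_new <- symmetric_decorrelate(W_new)
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (delta < tol) return(list(W = W, converged = TRUE, iters = it))
  }
  list(W = W, converged = FALSE, iters = maxit)
}

fastica_deflation <- function(Z, W0, maxit, tol) {
  k <- nrow(W0)
  ns <- ncol(Z)
  W <- matrix(0, k, k)
  for (i in seq_len(k)) {
    w <- W0[i, ]
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(maxit)) {
      u <- drop(w %*% Z)
      g <- tanh(u)
      w_new <- drop(Z %*% g) / ns - mean(1 - g^2) * w
      if (i > 1L) {
        w_new <- w_new - drop(t(W[seq_len(i - 1L), , drop = FALSE]) %*%
                              (W[seq_len(i - 1L), , drop = FALSE] %*% w_new))
      }
      w_new <- w_new / sqrt(sum(w_new^2))
      conv <- abs(1 - abs(sum(w_new * w))) < tol
      w <- w_new
      if (conv) break
    }
    W[i, ] <- w
  }
  W
}

#' Independent component decomposition of an EEG recording
#'
#' Whitens the (centered) channel data by PCA and runs FastICA with the
#' logcosh contrast in symmetric mode, falling back to deflation if the
#' symmetric iteration does not converge. The decomposition is deterministic
#' under a fixed seed. Sources are returned with unit variance; the mixing
#' and unmixing matrices satisfy `unmixing %*% mixing = I` and
#' `mixing %*% sources + center` reconstructs the input (exactly, when no
#' components are dropped for rank deficiency).
#'
#' @param rec an [eeg_recording()], already high-pass filtered.
#' @param n_components number of components (default: channel count, reduced
#'   automatically with a warning if the data are rank-deficient).
#' @param seed integer seed for the random orthonormal start.
#' @param max_samples at most this many (evenly spaced) samples are used to
#'   estimate the unmixing matrix; sources are computed from all samples.
#' @param maxit,tol iteration cap and convergence tolerance.
#' @return An object of class `ica_decomposition` with elements `mixing`
#'   (channels x components), `unmixing` (components x channels), `sources`
#'   (components x samples), `center`, `component_scores` (`NULL` until
#'   [score_components()] is called), plus sampling metadata.
#' @export
decompose_ica <- function(rec, n_components = NULL, seed = 1L,
                          max_samples = 20000L, maxit = 200L, tol = 1e-4) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_ch <- n_channels(rec)
  n_s <- n_samples(rec)
  if (n_s < 20L * n_ch) {
    stop("ICA needs at least 20 samples per channel (have ",
         round(n_s / n_ch, 1), ")")
  }
  if (is.null(n_components)) n_components <- n_ch
  n_components <- min(n_components, n_ch)
  set.seed(as.integer(seed))

  center <- rowMeans(rec$data)
  Xc <- rec$data - center
  idx <- if (n_s > max_samples) {
    unique(round(seq(1L, n_s, length.out = max_samples)))
  } else seq_len(n_s)
  Xe <- Xc[, idx, drop = FALSE]

  C <- tcrossprod(Xe) / ncol(Xe)
  eig <- eigen(C, symmetric = TRUE)
  keep <- eig$values > max(eig$values) * 1e-9
  if (sum(keep) < n_components) {
    warning("rank-deficient data: reducing components from ", n_components,
            " to ", sum(keep))
    n_components <- sum(keep)
  }
  d <- eig$values[seq_len(n_components)]
  E <- eig$vectors[, seq_len(n_components), drop = FALSE]
  K <- diag(1 / sqrt(d), n_components) %*% t(E)     # whitening (comp x ch)

  Z <- K %*% Xe
  W0 <- symmetric_decorrelate(matrix(rnorm(n_components^2), n_components))
  fit <- fastica_symmetric(Z, W0, maxit, tol)
  W <- fit$W
  if (!fit$converged) {
    W <- fastica_deflation(Z, W, maxit, tol)
  }

  unmixing <- W %*% K
  sources <- unmixing %*% Xc
  # exact unit variance on the full data
  s_sd <- apply(sources, 1L, sd)
  s_sd[s_sd == 0] <- 1
  unmixing <- unmixing / s_sd
  sources <- sources / s_sd
  mixing <- t(unmixing) %*% solve(tcrossprod(unmixing))
  # with fewer components than channels, keep the part of the signal
  # outside the component subspace so artifact removal can return it
  residual <- if (n_components < n_ch) Xc - mixing %*% sources

  structure(
    list(mixing = mixing, unmixing = unmixing, sources = sources,
         center = center, residual = residual, component_scores = NULL,
         sampling_rate = rec$sampling_rate,
         channel_labels = rec$channel_labels,
         start_time = rec$start_time, converged = fit$converged),
    class = "ica_decomposition"
  )
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components of %d channels%s\n",
              nrow(x$unmixing), ncol(x$unmixing),
              if (is.null(x$component_scores)) " (unscored)" else " (scored)"))
  invisible(x)
}

ICA_LABELS <- c("eye", "muscle", "line_noise", "channel_noise", "brain",
                "other")

psd_welch <- function(x, fs, nperseg = NULL) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, round(2 * fs))
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  acc <- 0
  for (s in starts) {
    seg <- (x[s:(s + nperseg - 1L)] - mean(x[s:(s + nperseg - 1L)])) * w
    acc <- acc + Mod(fft(seg))^2
  }
  nhalf <- floor(nperseg / 2) + 1L
  list(freq = (seq_len(nhalf) - 1L) * fs / nperseg,
       psd = (acc / length(starts))[seq_len(nhalf)])
}

#' Score independent components with interpretable rules
#'
#' Fills each component's probability map over the labels eye, muscle,
#' line_noise, channel_noise, brain and other. Evidence scores are built
#' from the component spectrum and scalp pattern -- low-frequency power with
#' a frontal topography for eye, 55-65 Hz concentration for line noise,
#' high-frequency power times spectral flatness for muscle, single-channel
#' loading dominance for channel noise, with brain as the residual -- and
#' mapped to probabilities by a softmax, so each map sums to one.
#'
#' @param decomp an `ica_decomposition`.
#' @param rec the recording it was computed from (used for montage lookup).
#' @param sharpness softmax inverse temperature applied to evidence scores.
#' @return The decomposition with `component_scores` filled (components x
#'   labels matrix).
#' @export
score_components <- function(decomp, rec = NULL, sharpness = 12) {
  stopifnot(inherits(decomp, "ica_decomposition"))
  fs <- decomp$sampling_rate
  labels <- decomp$channel_labels
  k <- nrow(decomp$unmixing)
  w_front <- region_weights(labels, "frontal")
  scores <- matrix(0, k, length(ICA_LABELS),
                   dimnames = list(NULL, ICA_LABELS))
  # analyse at most ~60 s of source signal
  n_use <- min(ncol(decomp$sources), round(60 * fs))
  for (i in seq_len(k)) {
    sp <- psd_welch(decomp$sources[i, seq_len(n_use)], fs)
    inband <- sp$freq >= 0.5 & sp$freq <= min(70, fs / 2)
    p <- sp$psd[inband]
    f <- sp$freq[inband]
    tot <- sum(p)
    if (tot <= 0) tot <- 1
    p_low <- sum(p[f < 4]) / tot
    p_line <- sum(p[f >= 55 & f <= 65]) / tot
    p_high <- sum(p[f > 30]) / tot
    flat <- exp(mean(log(pmax(p, max(p) * 1e-12)))) / mean(p)

    a <- decomp$mixing[, i]
    aa <- abs(a) / sum(abs(a))
    frontal_frac <- sum(aa * w_front)
    conc <- max(a^2) / sum(a^2)

    e <- c(
      eye = p_low * min(1, frontal_frac / 0.6),
      muscle = p_high * min(1, flat / 0.5),
      line_noise = p_line,
      channel_noise = max(0, (conc - 0.4) / 0.6),
      brain = 0,   # filled as residual below
      other = 0.10)
    e["brain"] <- max(0, 1 - max(e[c("eye", "muscle", "line_noise",
                                     "channel_noise")]))
    pr <- exp(sharpness * e)
    scores[i, ] <- pr / sum(pr)
  }
  decomp$component_scores <- scores
  decomp
}

#' Remove artifact components and back-project
#'
#' Zeroes every component whose largest non-brain label probability exceeds
#' the threshold and reconstructs the channel signals from the remaining
#' components (plus, for reduced-rank decompositions, the signal part
#' outside the component subspace), preserving channel count and length.
#'
#' @param decomp a scored `ica_decomposition` (see [score_components()]).
#' @param threshold probability in (0, 1]; the classical setting is 0.90.
#' @return A cleaned [eeg_recording()]. The indices of removed components
#'   are attached as the `removed_components` element.
#' @export
remove_artifacts <- function(decomp, threshold = 0.90) {
  stopifnot(inherits(decomp, "ica_decomposition"))
  if (is.null(decomp$component_scores)) {
    stop("component scores missing: run score_components() first")
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  sc <- decomp$component_scores
  non_brain <- sc[, setdiff(ICA_LABELS, "brain"), drop = FALSE]
  drop_idx <- which(apply(non_brain, 1L, max) > threshold)
  keep <- setdiff(seq_len(nrow(sc)), drop_idx)
  X <- decomp$mixing[, keep, drop = FALSE] %*%
    decomp$sources[keep, , drop = FALSE] + decomp$center
  if (!is.null(decomp$residual)) X <- X + decomp$residual
  out <- eeg_recording(X, decomp$sampling_rate, decomp$channel_labels,
                       decomp$start_time)
  out$removed_components <- drop_idx
  out
}
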