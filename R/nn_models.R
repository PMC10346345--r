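# ChronoNet and stacked-LSTM sequence classifiers built on the autodiff
# engine. Both consume cycle tensors (channels x timesteps x cycles) and are
# trained with Adam on the softmax cross-entropy, recording per-epoch
# history; training is deterministic under a fixed seed.

#' ChronoNet architecture description
#'
#' Lays out the network: three inception-style blocks, each a concatenation
#' of three 1-D convolutions with exponentially increasing kernel lengths
#' (2, 4, 8), 32 filters each and stride 2; then four GRU layers of 32 units
#' densely connected in a feed-forward manner (each GRU receives the
#' concatenation of all preceding GRU outputs); finally a linear softmax
#' layer. The description is a plain list, serializable to JSON.
#'
#' @param n_channels EEG channels of the input tensor.
#' @param n_timesteps samples per cycle (default 100).
#' @param n_classes output classes.
#' @param filters convolution filters per kernel (default 32).
#' @param kernels kernel lengths (default `c(2, 4, 8)`).
#' @param gru_units GRU width (default 32).
#' @return A list describing every layer, including the temporal length
#'   after each block (ceiling division by the stride).
#' @export
build_chrononet <- function(n_channels, n_timesteps = 100L, n_classes,
                            filters = 32L, kernels = c(2L, 4L, 8L),
                            gru_units = 32L) {
  if (n_timesteps < 8L) {
    stop("n_timesteps must be >= 8 to support three stride-2 reductions")
  }
  lens <- integer(3)
  cur <- as.integer(n_timesteps)
  in_ch <- as.integer(n_channels)
  blocks <- vector("list", 3L)
  for (b in 1:3) {
    cur <- as.integer(ceiling(cur / 2))
    lens[b] <- cur
    blocks[[b]] <- list(
      type = "inception_conv1d", in_channels = in_ch,
      kernels = as.integer(kernels), filters_per_kernel = as.integer(filters),
      stride = 2L, out_channels = as.integer(filters * length(kernels)),
      out_length = cur, activation = "relu")
    in_ch <- as.integer(filters * length(kernels))
  }
  gru_in <- as.integer(c(in_ch, gru_units, 2L * gru_units, 3L * gru_units))
  grus <- lapply(1:4, function(l) {
    list(type = "gru", units = as.integer(gru_units),
         input_width = gru_in[l],
         input = if (l == 1L) "conv_output" else
           paste0("concat(", paste0("gru", seq_len(l - 1L),
                                    collapse = ","), ")"))
  })
  list(model = "chrononet", n_channels = as.integer(n_channels),
       n_timesteps = as.integer(n_timesteps),
       n_classes = as.integer(n_classes),
       blocks = blocks, block_lengths = lens, gru_layers = grus,
       head = list(type = "dense_softmax", in_width = as.integer(gru_units),
                   out_width = as.integer(n_classes)))
}

chrononet_init <- function(arch) {
  p <- list()
  in_ch <- arch$n_channels
  nf <- arch$blocks[[1]]$filters_per_kernel
  for (b in 1:3) {
    for (k in arch$blocks[[b]]$kernels) {
      p[[sprintf("b%d_k%d_W", b, k)]] <- glorot(nf, in_ch * k)
      p[[sprintf("b%d_k%d_b", b, k)]] <- matrix(0, nf, 1)
    }
    in_ch <- arch$blocks[[b]]$out_channels
  }
  H <- arch$gru_layers[[1]]$units
  for (l in 1:4) {
    D <- arch$gru_layers[[l]]$input_width
    for (gate in c("z", "r", "h")) {
      p[[sprintf("gru%d_W%s", l, gate)]] <- glorot(H, D)
      p[[sprintf("gru%d_U%s", l, gate)]] <- glorot(H, H)
      p[[sprintf("gru%d_b%s", l, gate)]] <- matrix(0, H, 1)
    }
  }
  p$out_W <- glorot(arch$n_classes, H)
  p$out_b <- matrix(0, arch$n_classes, 1)
  p
}

# one GRU layer over a list of per-timestep input node ids
gru_layer <- function(tp, xs, pid, l, H, B) {
  h <- t_input(tp, matrix(0, H, B))
  out <- vector("list", length(xs))
  Wz <- pid[[sprintf("gru%d_Wz", l)]]; Uz <- pid[[sprintf("gru%d_Uz", l)]]
  bz <- pid[[sprintf("gru%d_bz", l)]]
  Wr <- pid[[sprintf("gru%d_Wr", l)]]; Ur <- pid[[sprintf("gru%d_Ur", l)]]
  br <- pid[[sprintf("gru%d_br", l)]]
  Wh <- pid[[sprintf("gru%d_Wh", l)]]; Uh <- pid[[sprintf("gru%d_Uh", l)]]
  bh <- pid[[sprintf("gru%d_bh", l)]]
  for (t in seq_along(xs)) {
    x <- xs[[t]]
    z <- t_sigmoid(tp, t_add_bias(tp, t_add(tp, t_mm(tp, Wz, x),
                                            t_mm(tp, Uz, h)), bz))
    r <- t_sigmoid(tp, t_add_bias(tp, t_add(tp, t_mm(tp, Wr, x),
                                            t_mm(tp, Ur, h)), br))
    hh <- t_tanh(tp, t_add_bias(tp, t_add(tp, t_mm(tp, Wh, x),
                                          t_mm(tp, Uh, t_mul(tp, r, h))),
                                bh))
    h <- t_add(tp, t_mul(tp, t_one_minus(tp, z), h), t_mul(tp, z, hh))
    out[[t]] <- h
  }
  out
}

chrononet_forward <- function(params, x3d, y_onehot = NULL, arch,
                              dropout = 0) {
  tp <- tape_new()
  pid <- lapply(params, function(p) t_param(tp, p))
  B <- dim(x3d)[3]
  x <- t_input(tp, x3d)
  for (b in 1:3) {
    convs <- lapply(arch$blocks[[b]]$kernels, function(k) {
      t_conv1d(tp, x, pid[[sprintf("b%d_k%d_W", b, k)]],
               pid[[sprintf("b%d_k%d_b", b, k)]], k, stride = 2L)
    })
    x <- t_relu(tp, t_concat_channels(tp, convs))
  }
  Tn <- dim(tv(tp, x))[2]
  H <- arch$gru_layers[[1]]$units
  gru_pid <- function(l) {
    setNames(lapply(c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wh", "Uh", "bh"),
                    function(nm) pid[[sprintf("gru%d_%s", l, nm)]]),
             c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wh", "Uh", "bh"))
  }
  g1 <- t_gru_layer_fused(tp, x, gru_pid(1L))
  g2 <- t_gru_layer_fused(tp, g1, gru_pid(2L))
  g3 <- t_gru_layer_fused(tp, t_concat_channels(tp, c(g1, g2)), gru_pid(3L))
  g4 <- t_gru_layer_fused(tp, t_concat_channels(tp, c(g1, g2, g3)),
                          gru_pid(4L))
  last <- if (identical(arch$head$pool, "mean")) t_mean_time(tp, g4) else
    t_slice_time(tp, g4, Tn)
  mask <- if (dropout > 0) {
    matrix(rbinom(H * B, 1L, 1 - dropout), H, B) / (1 - dropout)
  }
  last <- t_dropout(tp, last, mask)
  logits <- t_add_bias(tp, t_mm(tp, pid$out_W, last), pid$out_b)
  if (is.null(y_onehot)) {
    return(list(probs = softmax_cols(tv(tp, logits))))
  }
  loss <- t_softmax_ce(tp, logits, y_onehot)
  list(tape = tp, loss = loss, pid = pid)
}

lstm_init <- function(n_channels, n_classes, units = 64L) {
  p <- list()
  D <- n_channels
  for (l in 1:2) {
    for (gate in c("i", "f", "o", "g")) {
      p[[sprintf("lstm%d_W%s", l, gate)]] <- glorot(units, D)
      p[[sprintf("lstm%d_U%s", l, gate)]] <- glorot(units, units)
      p[[sprintf("lstm%d_b%s", l, gate)]] <-
        matrix(if (gate == "f") 1 else 0, units, 1)
    }
    D <- units
  }
  p$out_W <- glorot(n_classes, units)
  p$out_b <- matrix(0, n_classes, 1)
  p
}

lstm_layer <- function(tp, xs, pid, l, H, B) {
  h <- t_input(tp, matrix(0, H, B))
  cc <- t_input(tp, matrix(0, H, B))
  out <- vector("list", length(xs))
  gate <- function(g, x, act) {
    pre <- t_add_bias(tp, t_add(tp,
      t_mm(tp, pid[[sprintf("lstm%d_W%s", l, g)]], x),
      t_mm(tp, pid[[sprintf("lstm%d_U%s", l, g)]], h)),
      pid[[sprintf("lstm%d_b%s", l, g)]])
    act(tp, pre)
  }
  for (t in seq_along(xs)) {
    x <- xs[[t]]
    i <- gate("i", x, t_sigmoid)
    f <- gate("f", x, t_sigmoid)
    o <- gate("o", x, t_sigmoid)
    g <- gate("g", x, t_tanh)
    cc <- t_add(tp, t_mul(tp, f, cc), t_mul(tp, i, g))
    h <- t_mul(tp, o, t_tanh(tp, cc))
    out[[t]] <- h
  }
  out
}

lstm_forward <- function(params, x3d, y_onehot = NULL, units = 64L,
                         dropout = 0) {
  tp <- tape_new()
  pid <- lapply(params, function(p) t_param(tp, p))
  B <- dim(x3d)[3]
  Tn <- dim(x3d)[2]
  x <- t_input(tp, x3d)
  xs <- lapply(seq_len(Tn), function(t) t_slice_time(tp, x, t))
  h1 <- lstm_layer(tp, xs, pid, 1L, units, B)
  mask1 <- if (dropout > 0) {
    matrix(rbinom(units * B, 1L, 1 - dropout), units, B) / (1 - dropout)
  }
  h1 <- lapply(h1, function(id) t_dropout(tp, id, mask1))
  h2 <- lstm_layer(tp, h1, pid, 2L, units, B)
  last <- h2[[Tn]]
  mask2 <- if (dropout > 0) {
    matrix(rbinom(units * B, 1L, 1 - dropout), units, B) / (1 - dropout)
  }
  last <- t_dropout(tp, last, mask2)
  logits <- t_add_bias(tp, t_mm(tp, pid$out_W, last), pid$out_b)
  if (is.null(y_onehot)) {
    return(list(probs = softmax_cols(tv(tp, logits))))
  }
  loss <- t_softmax_ce(tp, logits, y_onehot)
  list(tape = tp, loss = loss, pid = pid)
}

# Shared minibatch training loop with Adam, optional stratified validation
# split and early stopping on validation loss.
nn_train <- function(params, forward, X, y_int, n_classes, hp) {
  set.seed(hp$seed)
  N <- dim(X)[3]
  onehot <- function(idx) {
    Y <- matrix(0, n_classes, length(idx))
    Y[cbind(y_int[idx], seq_along(idx))] <- 1
    Y
  }
  val_idx <- integer(0)
  if (hp$val_frac > 0 && N >= 8L * n_classes) {
    for (cl in seq_len(n_classes)) {
      cl_idx <- which(y_int == cl)
      n_val <- max(1L, round(hp$val_frac * length(cl_idx)))
      val_idx <- c(val_idx, sample(cl_idx, n_val))
    }
  }
  tr_idx <- setdiff(seq_len(N), val_idx)
  opt <- adam_new(params, lr = hp$lr)
  history <- data.frame()
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(hp$epochs)) {
    perm <- sample(tr_idx)
    losses <- c()
    correct <- 0L
    for (s in seq(1L, length(perm), by = hp$batch_size)) {
      idx <- perm[s:min(s + hp$batch_size - 1L, length(perm))]
      xb <- X[, , idx, drop = FALSE]
      if ((hp$noise_sd %||% 0) > 0) {
        xb <- xb + array(rnorm(length(xb), 0, hp$noise_sd), dim(xb))
      }
      fw <- forward(params, xb, onehot(idx),
                    dropout = hp$dropout)
      tape_backward(fw$tape, fw$loss)
      grads <- lapply(fw$pid, function(id) fw$tape$grad[[id]])
      bad <- vapply(grads, is.null, logical(1))
      grads[bad] <- lapply(params[bad], function(p) p * 0)
      st <- adam_step(opt, params, grads, clip = hp$clip,
                      weight_decay = hp$weight_decay %||% 0)
      opt <- st$opt
      params <- st$params
      losses <- c(losses, tv(fw$tape, fw$loss))
      p <- fw$tape$aux[[fw$loss]]$p
      correct <- correct + sum(max.col(t(p), ties.method = "first") ==
                               y_int[idx])
    }
    ep <- data.frame(epoch = epoch, train_loss = mean(losses),
                     train_acc = correct / length(perm),
                     val_loss = NA_real_, val_acc = NA_real_)
    if (length(val_idx)) {
      pv <- nn_predict_probs(params, forward, X[, , val_idx, drop = FALSE])
      yl <- pmax(pv[cbind(seq_along(val_idx), y_int[val_idx])], 1e-12)
      ep$val_loss <- -mean(log(yl))
      ep$val_acc <- mean(max.col(pv, ties.method = "first") ==
                         y_int[val_idx])
      if (ep$val_loss < best$loss - 1e-6) {
        best <- list(loss = ep$val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= hp$patience) {
          history <- rbind(history, ep)
          break
        }
      }
    }
    history <- rbind(history, ep)
  }
  if (length(val_idx) && is.finite(best$loss)) params <- best$params
  list(params = params, history = history)
}

# forward pass in chunks, probabilities as samples x classes
nn_predict_probs <- function(params, forward, X, chunk = 256L) {
  N <- dim(X)[3]
  out <- NULL
  for (s in seq(1L, N, by = chunk)) {
    idx <- s:min(s + chunk - 1L, N)
    fw <- forward(params, X[, , idx, drop = FALSE], NULL, dropout = 0)
    out <- rbind(out, t(fw$probs))
  }
  out
}
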