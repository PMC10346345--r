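# Minimal reverse-mode automatic differentiation engine for the two
# sequence models (stacked LSTM and ChronoNet). Values are numeric matrices
# (features x batch) or 3-d arrays (channels x time x batch); the tape
# records one backward closure per operation.

tape_new <- function() {
  env <- new.env(parent = emptyenv())
  env$val <- vector("list", 256L)
  env$grad <- vector("list", 256L)
  env$back <- vector("list", 256L)
  env$aux <- vector("list", 256L)
  env$need <- logical(256L)
  env$n <- 0L
  env
}

# `parents` holds the ids this node was computed from; a node needs a
# gradient only if one of its parents does. Gradient work for nodes that do
# not need one (notably the input data tensor) is skipped entirely.
tape_node <- function(tp, value, back = NULL, aux = NULL,
                      parents = integer(0)) {
  # force the arguments first: evaluating `value` or `aux` may itself create
  # nodes (nested op calls), which must receive their ids before this one
  force(value); force(back); force(aux); force(parents)
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$val)) {
    grow <- function(x) c(x, vector("list", length(x)))
    tp$val <- grow(tp$val); tp$grad <- grow(tp$grad)
    tp$back <- grow(tp$back); tp$aux <- grow(tp$aux)
    tp$need <- c(tp$need, logical(length(tp$need)))
  }
  tp$val[[tp$n]] <- value
  tp$back[[tp$n]] <- back
  tp$aux[[tp$n]] <- aux
  tp$need[[tp$n]] <- length(parents) > 0L && any(tp$need[parents])
  tp$n
}

tv <- function(tp, id) {
  # force id before touching tp$val: evaluating a nested op call appends to
  # the tape, and the list must be read after that happens
  force(id)
  tp$val[[id]]
}

# data input: no gradient tracked
t_input <- function(tp, x) tape_node(tp, x)

# trainable parameter: gradient tracked
t_param <- function(tp, x) {
  id <- tape_node(tp, x)
  tp$need[[id]] <- TRUE
  id
}

acc_grad <- function(tp, id, g) {
  if (!tp$need[[id]]) return(invisible(NULL))
  cur <- tp$grad[[id]]
  tp$grad[[id]] <- if (is.null(cur)) g else cur + g
}

tape_backward <- function(tp, loss_id) {
  tp$grad[[loss_id]] <- 1
  for (id in seq(loss_id, 1L)) {
    bk <- tp$back[[id]]
    g <- tp$grad[[id]]
    if (!is.null(bk) && !is.null(g)) bk(tp, g, id)
  }
}

t_mm <- function(tp, a, b) {
  tape_node(tp, tv(tp, a) %*% tv(tp, b), aux = c(a, b), parents = c(a, b),
            back = function(tp, g, id) {
              p <- tp$aux[[id]]
              if (tp$need[[p[1]]]) {
                acc_grad(tp, p[1], tcrossprod(g, tv(tp, p[2])))
              }
              if (tp$need[[p[2]]]) {
                acc_grad(tp, p[2], crossprod(tv(tp, p[1]), g))
              }
            })
}

t_add <- function(tp, a, b) {
  tape_node(tp, tv(tp, a) + tv(tp, b), aux = c(a, b), parents = c(a, b),
            back = function(tp, g, id) {
              p <- tp$aux[[id]]
              acc_grad(tp, p[1], g)
              acc_grad(tp, p[2], g)
            })
}

# add a column-replicated bias (stored as a one-column matrix) to a matrix
t_add_bias <- function(tp, a, b) {
  tape_node(tp, tv(tp, a) + as.vector(tv(tp, b)), aux = c(a, b),
            parents = c(a, b),
            back = function(tp, g, id) {
              p <- tp$aux[[id]]
              acc_grad(tp, p[1], g)
              if (tp$need[[p[2]]]) acc_grad(tp, p[2], rowSums(g))
            })
}

t_mul <- function(tp, a, b) {
  tape_node(tp, tv(tp, a) * tv(tp, b), aux = c(a, b), parents = c(a, b),
            back = function(tp, g, id) {
              p <- tp$aux[[id]]
              if (tp$need[[p[1]]]) acc_grad(tp, p[1], g * tv(tp, p[2]))
              if (tp$need[[p[2]]]) acc_grad(tp, p[2], g * tv(tp, p[1]))
            })
}

t_one_minus <- function(tp, a) {
  tape_node(tp, 1 - tv(tp, a), aux = a, parents = a,
            back = function(tp, g, id) acc_grad(tp, tp$aux[[id]], -g))
}

t_sigmoid <- function(tp, a) {
  s <- 1 / (1 + exp(-tv(tp, a)))
  tape_node(tp, s, aux = a, parents = a,
            back = function(tp, g, id) {
              s <- tv(tp, id)
              acc_grad(tp, tp$aux[[id]], g * s * (1 - s))
            })
}

t_tanh <- function(tp, a) {
  tape_node(tp, tanh(tv(tp, a)), aux = a, parents = a,
            back = function(tp, g, id) {
              y <- tv(tp, id)
              acc_grad(tp, tp$aux[[id]], g * (1 - y^2))
            })
}

t_relu <- function(tp, a) {
  tape_node(tp, pmax(tv(tp, a), 0), aux = a, parents = a,
            back = function(tp, g, id) {
              acc_grad(tp, tp$aux[[id]], g * (tv(tp, id) > 0))
            })
}

# inverted dropout with a fixed pre-drawn mask (NULL = identity)
t_dropout <- function(tp, a, mask) {
  if (is.null(mask)) return(a)
  tape_node(tp, tv(tp, a) * mask, aux = list(a = a, mask = mask),
            parents = a,
            back = function(tp, g, id) {
              acc_grad(tp, tp$aux[[id]]$a, g * tp$aux[[id]]$mask)
            })
}

# row-wise concatenation of matrices
t_concat_rows <- function(tp, ids) {
  ids <- as.integer(unlist(ids))
  vals <- lapply(ids, function(i) tv(tp, i))
  rows <- vapply(vals, nrow, integer(1))
  tape_node(tp, do.call(rbind, vals), aux = list(ids = ids, rows = rows),
            parents = ids,
            back = function(tp, g, id) {
              a <- tp$aux[[id]]
              off <- 0L
              for (j in seq_along(a$ids)) {
                acc_grad(tp, a$ids[j], g[off + seq_len(a$rows[j]), ,
                                         drop = FALSE])
                off <- off + a$rows[j]
              }
            })
}

# channel-wise concatenation of (C x L x B) arrays
t_concat_channels <- function(tp, ids) {
  ids <- as.integer(unlist(ids))
  vals <- lapply(ids, function(i) tv(tp, i))
  chans <- vapply(vals, function(v) dim(v)[1], integer(1))
  d <- dim(vals[[1]])
  out <- array(0, c(sum(chans), d[2], d[3]))
  off <- 0L
  for (v in vals) {
    out[off + seq_len(dim(v)[1]), , ] <- v
    off <- off + dim(v)[1]
  }
  tape_node(tp, out, aux = list(ids = ids, chans = chans), parents = ids,
            back = function(tp, g, id) {
              a <- tp$aux[[id]]
              off <- 0L
              for (j in seq_along(a$ids)) {
                acc_grad(tp, a$ids[j],
                         g[off + seq_len(a$chans[j]), , , drop = FALSE])
                off <- off + a$chans[j]
              }
            })
}

# time-slice of a (C x L x B) array as a C x B matrix
t_slice_time <- function(tp, a, t_idx) {
  v <- tv(tp, a)
  d <- dim(v)
  tape_node(tp, matrix(v[, t_idx, ], d[1], d[3]),
            aux = list(a = a, t = t_idx, d = d), parents = a,
            back = function(tp, g, id) {
              x <- tp$aux[[id]]
              if (!tp$need[[x$a]]) return(invisible(NULL))
              gz <- array(0, x$d)
              gz[, x$t, ] <- g
              acc_grad(tp, x$a, gz)
            })
}

# strided same-padded 1-d convolution over a (Cin x L x B) array.
# W: filters x (Cin*k), b: filter bias. Output: (filters x Lout x B) with
# Lout = ceiling(L / stride).
t_conv1d <- function(tp, x, W, b, k, stride = 2L) {
  xv <- tv(tp, x)
  d <- dim(xv)
  lout <- ceiling(d[2] / stride)
  pad_total <- max((lout - 1L) * stride + k - d[2], 0L)
  pad_l <- pad_total %/% 2L
  pad_r <- pad_total - pad_l
  col <- cpp_im2col(xv, as.integer(k), as.integer(stride),
                    as.integer(pad_l), as.integer(pad_r))
  y <- tv(tp, W) %*% col + as.vector(tv(tp, b))
  f <- nrow(y)
  tape_node(tp, array(y, c(f, lout, d[3])),
            aux = list(x = x, W = W, b = b, col = col, d = d, k = k,
                       stride = stride, pad_l = pad_l, pad_r = pad_r,
                       lout = lout),
            parents = c(x, W, b),
            back = function(tp, g, id) {
              a <- tp$aux[[id]]
              gm <- matrix(g, dim(g)[1], a$lout * a$d[3])
              acc_grad(tp, a$W, tcrossprod(gm, a$col))
              acc_grad(tp, a$b, rowSums(gm))
              if (tp$need[[a$x]]) {
                gcol <- crossprod(tv(tp, a$W), gm)
                acc_grad(tp, a$x,
                         cpp_col2im(gcol, as.integer(a$d), as.integer(a$k),
                                    as.integer(a$stride),
                                    as.integer(a$pad_l),
                                    as.integer(a$pad_r)))
              }
            })
}

# fused softmax + cross-entropy over columns; y_onehot: classes x batch.
# Loss value is the batch-mean negative log-likelihood; the class
# probabilities are kept in the node's aux slot.
t_softmax_ce <- function(tp, logits, y_onehot) {
  z <- tv(tp, logits)
  z <- z - rep(apply(z, 2L, max), each = nrow(z))
  e <- exp(z)
  p <- e / rep(colSums(e), each = nrow(e))
  loss <- -mean(colSums(y_onehot * log(pmax(p, 1e-12))))
  tape_node(tp, loss, aux = list(logits = logits, p = p, y = y_onehot),
            parents = logits,
            back = function(tp, g, id) {
              a <- tp$aux[[id]]
              acc_grad(tp, a$logits, g * (a$p - a$y) / ncol(a$p))
            })
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2L, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

# ---- parameter initialisation and the Adam optimizer ----

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads, clip = 5, weight_decay = 0) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > clip) grads <- lapply(grads, `*`, clip / gn)
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - opt$beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - opt$beta2^opt$t)
    # decoupled weight decay (AdamW)
    params[[nm]] <- params[[nm]] -
      opt$lr * (mhat / (sqrt(vhat) + opt$eps) + weight_decay * params[[nm]])
  }
  list(opt = opt, params = params)
}

# temporal mean of a (C x T x B) array as a C x B matrix
t_mean_time <- function(tp, a) {
  v <- tv(tp, a)
  d <- dim(v)
  tape_node(tp, matrix(rowMeans(aperm(v, c(1, 3, 2)), dims = 2), d[1], d[3]),
            aux = list(a = a, d = d), parents = a,
            back = function(tp, g, id) {
              x <- tp$aux[[id]]
              acc_grad(tp, x$a, aperm(array(as.vector(g) / x$d[2],
                                            c(x$d[1], x$d[3], x$d[2])),
                                      c(1, 3, 2)))
            })
}

# Fused GRU layer over a (D x T x B) input, producing the (H x T x B)
# hidden-state sequence as a single tape node. The forward loop caches the
# gate activations; the backward closure is hand-derived truncated BPTT
# (exact, since the full sequence is kept). Fusing the layer avoids
# hundreds of small tape nodes per batch.
t_gru_layer_fused <- function(tp, x, W) {
  xv <- tv(tp, x)
  d <- dim(xv)
  D <- d[1]; Tn <- d[2]; B <- d[3]
  Wz <- tv(tp, W$Wz); Uz <- tv(tp, W$Uz); bz <- as.vector(tv(tp, W$bz))
  Wr <- tv(tp, W$Wr); Ur <- tv(tp, W$Ur); br <- as.vector(tv(tp, W$br))
  Wh <- tv(tp, W$Wh); Uh <- tv(tp, W$Uh); bh <- as.vector(tv(tp, W$bh))
  H <- nrow(Wz)
  # batched input projections for all timesteps at once
  xm <- matrix(xv, D, Tn * B)
  px_z <- Wz %*% xm + bz
  px_r <- Wr %*% xm + br
  px_h <- Wh %*% xm + bh
  h <- matrix(0, H, B)
  hs <- array(0, c(H, Tn, B))
  cz <- vector("list", Tn); cr <- vector("list", Tn)
  chh <- vector("list", Tn); chp <- vector("list", Tn)
  sel <- function(p, t) matrix(p[, ((seq_len(B) - 1L) * Tn) + t], H, B)
  for (t in seq_len(Tn)) {
    z <- 1 / (1 + exp(-(sel(px_z, t) + Uz %*% h)))
    r <- 1 / (1 + exp(-(sel(px_r, t) + Ur %*% h)))
    hh <- tanh(sel(px_h, t) + Uh %*% (r * h))
    chp[[t]] <- h
    h <- (1 - z) * h + z * hh
    cz[[t]] <- z; cr[[t]] <- r; chh[[t]] <- hh
    hs[, t, ] <- h
  }
  tape_node(tp, hs,
            aux = list(x = x, W = W, d = d, cz = cz, cr = cr, chh = chh,
                       chp = chp),
            parents = c(x, unlist(W)),
            back = function(tp, g, id) {
              a <- tp$aux[[id]]
              D <- a$d[1]; Tn <- a$d[2]; B <- a$d[3]
              Wz <- tv(tp, a$W$Wz); Uz <- tv(tp, a$W$Uz)
              Wr <- tv(tp, a$W$Wr); Ur <- tv(tp, a$W$Ur)
              Wh <- tv(tp, a$W$Wh); Uh <- tv(tp, a$W$Uh)
              H <- nrow(Wz)
              xv <- tv(tp, a$x)
              need_x <- tp$need[[a$x]]
              gW <- lapply(list(Wz = Wz, Uz = Uz, Wr = Wr, Ur = Ur,
                                Wh = Wh, Uh = Uh), function(m) m * 0)
              gb <- list(bz = numeric(H), br = numeric(H), bh = numeric(H))
              gx <- if (need_x) array(0, a$d)
              dh <- matrix(0, H, B)
              for (t in seq(Tn, 1L)) {
                dh <- dh + matrix(g[, t, ], H, B)
                z <- a$cz[[t]]; r <- a$cr[[t]]
                hh <- a$chh[[t]]; hp <- a$chp[[t]]
                dpz <- dh * (hh - hp) * z * (1 - z)
                dpre_h <- dh * z * (1 - hh^2)
                dh_next <- dh * (1 - z)
                drh <- crossprod(Uh, dpre_h)
                dpr <- drh * hp * r * (1 - r)
                xt <- matrix(xv[, t, ], D, B)
                gW$Wz <- gW$Wz + tcrossprod(dpz, xt)
                gW$Uz <- gW$Uz + tcrossprod(dpz, hp)
                gb$bz <- gb$bz + rowSums(dpz)
                gW$Wr <- gW$Wr + tcrossprod(dpr, xt)
                gW$Ur <- gW$Ur + tcrossprod(dpr, hp)
                gb$br <- gb$br + rowSums(dpr)
                gW$Wh <- gW$Wh + tcrossprod(dpre_h, xt)
                gW$Uh <- gW$Uh + tcrossprod(dpre_h, r * hp)
                gb$bh <- gb$bh + rowSums(dpre_h)
                dh <- dh_next + crossprod(Uz, dpz) + crossprod(Ur, dpr) +
                  drh * r
                if (need_x) {
                  gx[, t, ] <- crossprod(Wz, dpz) + crossprod(Wr, dpr) +
                    crossprod(Wh, dpre_h)
                }
              }
              acc_grad(tp, a$W$Wz, gW$Wz); acc_grad(tp, a$W$Uz, gW$Uz)
              acc_grad(tp, a$W$bz, gb$bz)
              acc_grad(tp, a$W$Wr, gW$Wr); acc_grad(tp, a$W$Ur, gW$Ur)
              acc_grad(tp, a$W$br, gb$br)
              acc_grad(tp, a$W$Wh, gW$Wh); acc_grad(tp, a$W$Uh, gW$Uh)
              acc_grad(tp, a$W$bh, gb$bh)
              if (need_x) acc_grad(tp, a$x, gx)
            })
}
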