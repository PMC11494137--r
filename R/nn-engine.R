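# Minimal neural-network engine: layer forward/backward passes, Adam, and a
# numerically stable binary cross-entropy on logits. Everything is plain R
# matrix algebra; batches are rows. Layers are lists with a `type`, a `params`
# list of arrays, and fixed shape metadata. The backward passes are verified
# against central-difference numerical gradients in the test suite.

.sigmoid <- function(z) 1 / (1 + exp(-z))

.softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

# mean BCE over logits z against labels y in {0,1}
.bce_loss <- function(z, y) mean(.softplus(z) - y * z)

.bce_grad <- function(z, y) (.sigmoid(z) - y) / length(z)

.glorot <- function(n_in, n_out, dims) {
  array(stats::runif(prod(dims), -1, 1) * sqrt(6 / (n_in + n_out)), dim = dims)
}

# ---- layer constructors -----------------------------------------------------

.layer_dense <- function(d_in, d_out, activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  list(
    type = "dense", activation = activation, d_in = d_in, d_out = d_out,
    params = list(W = .glorot(d_in, d_out, c(d_in, d_out)), b = matrix(0, 1, d_out))
  )
}

.layer_dropout <- function(rate) {
  list(type = "dropout", rate = rate, params = list())
}

# valid 1-D convolution; input n x L x c_in, output n x (L - k + 1) x c_out
.layer_conv1d <- function(k, c_in, c_out, l_in) {
  list(
    type = "conv1d", k = k, c_in = c_in, c_out = c_out,
    l_in = l_in, l_out = l_in - k + 1L,
    params = list(
      W = .glorot(k * c_in, c_out, c(k * c_in, c_out)),
      b = matrix(0, 1, c_out)
    )
  )
}

.layer_maxpool2 <- function(l_in, c_in) {
  list(
    type = "maxpool2", l_in = l_in, l_out = l_in %/% 2L, c_in = c_in,
    params = list()
  )
}

.layer_globalmaxpool <- function(l_in, c_in) {
  list(type = "globalmaxpool", l_in = l_in, c_in = c_in, params = list())
}

# matrix (n x L) -> array (n x steps x feat); L == steps * feat
.layer_reshape_seq <- function(steps, feat) {
  list(type = "reshape_seq", steps = steps, feat = feat, params = list())
}

.layer_reshape_channel <- function(l_in) {
  list(type = "reshape_channel", l_in = l_in, params = list())
}

.layer_recurrent <- function(kind = c("rnn", "lstm", "gru"), feat, hidden) {
  kind <- match.arg(kind)
  gates <- switch(kind, rnn = 1L, lstm = 4L, gru = 3L)
  list(
    type = "recurrent", cell = kind, feat = feat, hidden = hidden,
    params = list(
      Wx = .glorot(feat, hidden, c(feat, gates * hidden)),
      Wh = .glorot(hidden, hidden, c(hidden, gates * hidden)),
      b = matrix(0, 1, gates * hidden)
    )
  )
}

# ---- forward / backward -----------------------------------------------------

# X: matrix or 3-D array batch; returns list(out, cache)
.layer_forward <- function(layer, X, training = FALSE) {
  switch(layer$type,
    dense = {
      Z <- sweep(X %*% layer$params$W, 2L, layer$params$b, `+`)
      out <- if (layer$activation == "relu") pmax(Z, 0) else Z
      list(out = out, cache = list(X = X, Z = Z))
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- (array(stats::runif(length(X)), dim = dim(X)) >= layer$rate) /
          (1 - layer$rate)
        list(out = X * mask, cache = list(mask = mask))
      } else {
        list(out = X, cache = list(mask = NULL))
      }
    },
    reshape_channel = {
      list(out = array(X, dim = c(nrow(X), ncol(X), 1L)), cache = list(n = nrow(X)))
    },
    reshape_seq = {
      n <- nrow(X)
      # row-major fill per sample: step index varies slowest within a sample
      arr <- array(X, dim = c(n, layer$feat, layer$steps))
      list(out = aperm(arr, c(1L, 3L, 2L)), cache = list(n = n))
    },
    conv1d = .conv1d_forward(layer, X),
    maxpool2 = .maxpool2_forward(layer, X),
    globalmaxpool = .globalmaxpool_forward(layer, X),
    recurrent = switch(layer$cell,
      rnn = .rnn_forward(layer, X),
      lstm = .lstm_forward(layer, X),
      gru = .gru_forward(layer, X)
    ),
    stop("unknown layer type: ", layer$type)
  )
}

# dY matches the layer output shape; returns list(dX, grads)
.layer_backward <- function(layer, cache, dY) {
  switch(layer$type,
    dense = {
      dZ <- if (layer$activation == "relu") dY * (cache$Z > 0) else dY
      list(
        dX = dZ %*% t(layer$params$W),
        grads = list(W = crossprod(cache$X, dZ), b = colSums(dZ))
      )
    },
    dropout = {
      if (is.null(cache$mask)) {
        list(dX = dY, grads = list())
      } else {
        list(dX = dY * cache$mask, grads = list())
      }
    },
    reshape_channel = {
      list(dX = matrix(dY, nrow = cache$n), grads = list())
    },
    reshape_seq = {
      arr <- aperm(dY, c(1L, 3L, 2L))
      list(dX = matrix(arr, nrow = cache$n), grads = list())
    },
    conv1d = .conv1d_backward(layer, cache, dY),
    maxpool2 = .maxpool2_backward(layer, cache, dY),
    globalmaxpool = .globalmaxpool_backward(layer, cache, dY),
    recurrent = switch(layer$cell,
      rnn = .rnn_backward(layer, cache, dY),
      lstm = .lstm_backward(layer, cache, dY),
      gru = .gru_backward(layer, cache, dY)
    ),
    stop("unknown layer type: ", layer$type)
  )
}

# im2col: n x L x C array -> (n * l_out) x (k * C) matrix, rows ordered with
# sample index fastest, then output position
.im2col <- function(X, k, l_out) {
  n <- dim(X)[1]
  c_in <- dim(X)[3]
  cols <- vector("list", k)
  for (j in seq_len(k)) {
    slab <- X[, j:(j + l_out - 1L), , drop = FALSE]
    cols[[j]] <- matrix(slab, nrow = n * l_out, ncol = c_in)
  }
  do.call(cbind, cols)
}

.conv1d_forward <- function(layer, X) {
  n <- dim(X)[1]
  Xcol <- .im2col(X, layer$k, layer$l_out)
  Zmat <- sweep(Xcol %*% layer$params$W, 2L, layer$params$b, `+`)
  Amat <- pmax(Zmat, 0)
  out <- array(Amat, dim = c(n, layer$l_out, layer$c_out))
  list(out = out, cache = list(Xcol = Xcol, Zmat = Zmat, n = n, dimX = dim(X)))
}

.conv1d_backward <- function(layer, cache, dY) {
  n <- cache$n
  dA <- matrix(dY, nrow = n * layer$l_out, ncol = layer$c_out)
  dZ <- dA * (cache$Zmat > 0)
  dW <- crossprod(cache$Xcol, dZ)
  db <- colSums(dZ)
  dXcol <- dZ %*% t(layer$params$W)
  dX <- array(0, dim = cache$dimX)
  c_in <- layer$c_in
  for (j in seq_len(layer$k)) {
    slab <- array(dXcol[, ((j - 1L) * c_in + 1L):(j * c_in)],
      dim = c(n, layer$l_out, c_in)
    )
    dX[, j:(j + layer$l_out - 1L), ] <-
      dX[, j:(j + layer$l_out - 1L), , drop = FALSE] + slab
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

.maxpool2_forward <- function(layer, X) {
  l_out <- layer$l_out
  a <- X[, seq_len(l_out) * 2L - 1L, , drop = FALSE]
  b <- X[, seq_len(l_out) * 2L, , drop = FALSE]
  take_a <- a >= b
  list(
    out = ifelse(take_a, a, b),
    cache = list(take_a = take_a, dimX = dim(X))
  )
}

.maxpool2_backward <- function(layer, cache, dY) {
  dX <- array(0, dim = cache$dimX)
  l_out <- layer$l_out
  dX[, seq_len(l_out) * 2L - 1L, ] <- dY * cache$take_a
  dX[, seq_len(l_out) * 2L, ] <- dY * !cache$take_a
  list(dX = dX, grads = list())
}

.globalmaxpool_forward <- function(layer, X) {
  n <- dim(X)[1]
  L <- dim(X)[2]
  C <- dim(X)[3]
  X2 <- matrix(aperm(X, c(2L, 1L, 3L)), nrow = L) # L x (n*C)
  idx <- max.col(t(X2), ties.method = "first")
  vals <- X2[cbind(idx, seq_along(idx))]
  list(
    out = matrix(vals, nrow = n, ncol = C),
    cache = list(idx = idx, n = n, L = L, C = C)
  )
}

.globalmaxpool_backward <- function(layer, cache, dY) {
  dX2 <- matrix(0, nrow = cache$L, ncol = cache$n * cache$C)
  dX2[cbind(cache$idx, seq_along(cache$idx))] <- as.vector(dY)
  dX <- aperm(array(dX2, dim = c(cache$L, cache$n, cache$C)), c(2L, 1L, 3L))
  list(dX = dX, grads = list())
}

# ---- recurrent cells (batch-first, output = last hidden state) --------------

.rnn_forward <- function(layer, X) {
  n <- dim(X)[1]
  Tn <- dim(X)[2]
  H <- layer$hidden
  p <- layer$params
  hs <- array(0, dim = c(n, H, Tn + 1L))
  for (t in seq_len(Tn)) {
    Z <- matrix(X[, t, ], nrow = n) %*% p$Wx + matrix(hs[, , t], nrow = n) %*% p$Wh
    Z <- sweep(Z, 2L, p$b, `+`)
    hs[, , t + 1L] <- tanh(Z)
  }
  list(out = matrix(hs[, , Tn + 1L], nrow = n), cache = list(X = X, hs = hs, n = n, Tn = Tn))
}

.rnn_backward <- function(layer, cache, dY) {
  p <- layer$params
  X <- cache$X
  hs <- cache$hs
  Tn <- cache$Tn
  dWx <- array(0, dim = dim(p$Wx))
  dWh <- array(0, dim = dim(p$Wh))
  db <- numeric(ncol(p$b))
  dX <- array(0, dim = dim(X))
  dh <- if (is.matrix(dY)) dY else matrix(dY, nrow = cache$n)
  for (t in rev(seq_len(Tn))) {
    h_t <- matrix(hs[, , t + 1L], nrow = cache$n)
    dZ <- dh * (1 - h_t^2)
    dWx <- dWx + crossprod(matrix(X[, t, ], nrow = cache$n), dZ)
    dWh <- dWh + crossprod(matrix(hs[, , t], nrow = cache$n), dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- dZ %*% t(p$Wx)
    dh <- dZ %*% t(p$Wh)
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

.lstm_forward <- function(layer, X) {
  n <- dim(X)[1]
  Tn <- dim(X)[2]
  H <- layer$hidden
  p <- layer$params
  hs <- array(0, dim = c(n, H, Tn + 1L))
  cs <- array(0, dim = c(n, H, Tn + 1L))
  gates <- array(0, dim = c(n, 4L * H, Tn))
  for (t in seq_len(Tn)) {
    Z <- matrix(X[, t, ], nrow = n) %*% p$Wx + matrix(hs[, , t], nrow = n) %*% p$Wh
    Z <- sweep(Z, 2L, p$b, `+`)
    i <- .sigmoid(Z[, 1:H, drop = FALSE])
    f <- .sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
    o <- .sigmoid(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    cs[, , t + 1L] <- f * cs[, , t] + i * g
    hs[, , t + 1L] <- o * tanh(cs[, , t + 1L])
    gates[, , t] <- cbind(i, f, o, g)
  }
  list(
    out = matrix(hs[, , Tn + 1L], nrow = n),
    cache = list(X = X, hs = hs, cs = cs, gates = gates, n = n, Tn = Tn, H = H)
  )
}

.lstm_backward <- function(layer, cache, dY) {
  p <- layer$params
  X <- cache$X
  hs <- cache$hs
  cs <- cache$cs
  Tn <- cache$Tn
  H <- cache$H
  n <- cache$n
  dWx <- array(0, dim = dim(p$Wx))
  dWh <- array(0, dim = dim(p$Wh))
  db <- numeric(ncol(p$b))
  dX <- array(0, dim = dim(X))
  dh <- if (is.matrix(dY)) dY else matrix(dY, nrow = n)
  dc <- matrix(0, n, H)
  for (t in rev(seq_len(Tn))) {
    g4 <- matrix(cache$gates[, , t], nrow = n)
    i <- g4[, 1:H, drop = FALSE]
    f <- g4[, (H + 1):(2 * H), drop = FALSE]
    o <- g4[, (2 * H + 1):(3 * H), drop = FALSE]
    g <- g4[, (3 * H + 1):(4 * H), drop = FALSE]
    c_t <- cs[, , t + 1L]
    tc <- tanh(c_t)
    do_ <- dh * tc
    dc <- dc + dh * o * (1 - tc^2)
    di <- dc * g
    df <- dc * cs[, , t]
    dg <- dc * i
    dZ <- cbind(
      di * i * (1 - i),
      df * f * (1 - f),
      do_ * o * (1 - o),
      dg * (1 - g^2)
    )
    dWx <- dWx + crossprod(matrix(X[, t, ], nrow = n), dZ)
    dWh <- dWh + crossprod(matrix(hs[, , t], nrow = n), dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- dZ %*% t(p$Wx)
    dh <- dZ %*% t(p$Wh)
    dc <- dc * f
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

.gru_forward <- function(layer, X) {
  n <- dim(X)[1]
  Tn <- dim(X)[2]
  H <- layer$hidden
  p <- layer$params
  hs <- array(0, dim = c(n, H, Tn + 1L))
  zs <- array(0, dim = c(n, H, Tn))
  rs <- array(0, dim = c(n, H, Tn))
  ns <- array(0, dim = c(n, H, Tn))
  for (t in seq_len(Tn)) {
    x_t <- matrix(X[, t, ], nrow = n)
    h_prev <- matrix(hs[, , t], nrow = n)
    Zx <- sweep(x_t %*% p$Wx, 2L, p$b, `+`)
    Zh <- h_prev %*% p$Wh
    z <- .sigmoid(Zx[, 1:H, drop = FALSE] + Zh[, 1:H, drop = FALSE])
    r <- .sigmoid(Zx[, (H + 1):(2 * H), drop = FALSE] + Zh[, (H + 1):(2 * H), drop = FALSE])
    nn <- tanh(Zx[, (2 * H + 1):(3 * H), drop = FALSE] + r * Zh[, (2 * H + 1):(3 * H), drop = FALSE])
    hs[, , t + 1L] <- (1 - z) * nn + z * h_prev
    zs[, , t] <- z
    rs[, , t] <- r
    ns[, , t] <- nn
  }
  list(
    out = matrix(hs[, , Tn + 1L], nrow = n),
    cache = list(X = X, hs = hs, zs = zs, rs = rs, ns = ns, n = n, Tn = Tn, H = H)
  )
}

.gru_backward <- function(layer, cache, dY) {
  p <- layer$params
  X <- cache$X
  hs <- cache$hs
  Tn <- cache$Tn
  H <- cache$H
  n <- cache$n
  dWx <- array(0, dim = dim(p$Wx))
  dWh <- array(0, dim = dim(p$Wh))
  db <- numeric(ncol(p$b))
  dX <- array(0, dim = dim(X))
  dh <- if (is.matrix(dY)) dY else matrix(dY, nrow = n)
  for (t in rev(seq_len(Tn))) {
    h_prev <- matrix(hs[, , t], nrow = n)
    z <- matrix(cache$zs[, , t], nrow = n)
    r <- matrix(cache$rs[, , t], nrow = n)
    nn <- matrix(cache$ns[, , t], nrow = n)
    x_t <- matrix(X[, t, ], nrow = n)
    Zh_n <- h_prev %*% p$Wh[, (2 * H + 1):(3 * H), drop = FALSE]
    dz <- dh * (h_prev - nn)
    dn <- dh * (1 - z)
    dh_direct <- dh * z
    dZn <- dn * (1 - nn^2)        # pre-activation of candidate
    dr <- dZn * Zh_n
    dZz <- dz * z * (1 - z)
    dZr <- dr * r * (1 - r)
    dZ_x <- cbind(dZz, dZr, dZn)  # grads wrt the three Wx blocks + bias
    dWx <- dWx + crossprod(x_t, dZ_x)
    db <- db + colSums(dZ_x)
    dX[, t, ] <- dZ_x %*% t(p$Wx)
    dZ_h <- cbind(dZz, dZr, dZn * r)
    dWh <- dWh + crossprod(h_prev, dZ_h)
    dh <- dh_direct + dZ_h %*% t(p$Wh)
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- whole-network passes ---------------------------------------------------

.net_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  out <- X
  for (i in seq_along(layers)) {
    fw <- .layer_forward(layers[[i]], out, training = training)
    out <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = out, caches = caches)
}

.net_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  d <- dOut
  for (i in rev(seq_along(layers))) {
    bw <- .layer_backward(layers[[i]], caches[[i]], d)
    d <- bw$dX
    grads[[i]] <- bw$grads
  }
  grads
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(layers) {
  lapply(layers, function(l) {
    lapply(l$params, function(p) {
      list(m = array(0, dim = dim(as.array(p))), v = array(0, dim = dim(as.array(p))))
    })
  })
}

.adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    for (nm in names(grads[[i]])) {
      p <- layers[[i]]$params[[nm]]
      pd <- dim(as.array(p))
      g <- array(as.vector(grads[[i]][[nm]]), dim = pd)
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]]$params[[nm]] <- p - array(lr * mhat / (sqrt(vhat) + eps), dim = pd)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

.n_params <- function(layers) {
  sum(vapply(layers, function(l) {
    sum(vapply(l$params, length, 1L))
  }, 1L))
}
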