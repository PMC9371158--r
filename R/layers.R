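## Internal 1D CNN engine: batched forward/backward passes built on im2col
## gather + BLAS matrix products. Arrays flow as (batch, length, channels)
## until flattening. Convolutions are length-preserving ("same" zero
## padding); max pooling halves length in ceiling mode (size 2, stride 2).

layer_conv <- function(kernel, in_ch, out_ch) {
  list(type = "conv", kernel = as.integer(kernel),
       in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
       W = matrix(0, kernel * in_ch, out_ch), b = numeric(out_ch))
}

init_layer_params <- function(layer) {
  if (layer$type == "conv") {
    fan_in <- layer$kernel * layer$in_ch
    fan_out <- layer$kernel * layer$out_ch
    lim <- sqrt(6 / (fan_in + fan_out))
    layer$W <- matrix(stats::runif(length(layer$W), -lim, lim),
                      nrow(layer$W), ncol(layer$W))
    layer$b <- numeric(layer$out_ch)
  } else if (layer$type == "dense") {
    lim <- sqrt(6 / (nrow(layer$W) + ncol(layer$W)))
    layer$W <- matrix(stats::runif(length(layer$W), -lim, lim),
                      nrow(layer$W), ncol(layer$W))
    layer$b <- numeric(ncol(layer$W))
  }
  layer
}

## im2col gather: (B, L, C) with same padding -> (B*L, K*C)
im2col <- function(X, K) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  left <- (K - 1L) %/% 2L
  Xpad <- array(0, dim = c(B, L + K - 1L, C))
  Xpad[, (left + 1L):(left + L), ] <- X
  X2 <- matrix(0, B * L, K * C)
  for (k in seq_len(K)) {
    Xs <- Xpad[, k:(k + L - 1L), , drop = FALSE]
    dim(Xs) <- c(B * L, C)
    X2[, ((k - 1L) * C + 1L):(k * C)] <- Xs
  }
  X2
}

## col2im scatter-add: (B*L, K*C) -> (B, L, C)
col2im <- function(dX2, B, L, C, K) {
  left <- (K - 1L) %/% 2L
  dXpad <- array(0, dim = c(B, L + K - 1L, C))
  for (k in seq_len(K)) {
    blk <- dX2[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
    dim(blk) <- c(B, L, C)
    dXpad[, k:(k + L - 1L), ] <- dXpad[, k:(k + L - 1L), , drop = FALSE] + blk
  }
  dXpad[, (left + 1L):(left + L), , drop = FALSE]
}

forward_layer <- function(layer, X, train = FALSE) {
  switch(layer$type,
    conv = {
      d <- dim(X)
      X2 <- im2col(X, layer$kernel)
      Y <- X2 %*% layer$W
      Y <- sweep(Y, 2, layer$b, `+`)
      dim(Y) <- c(d[1], d[2], layer$out_ch)
      list(Y = Y, cache = list(X2 = X2, dims = d))
    },
    relu = {
      mask <- X > 0
      Y <- X * mask
      list(Y = Y, cache = list(mask = mask))
    },
    pool = {
      d <- dim(X); B <- d[1]; L <- d[2]; F_ <- d[3]
      Lout <- ceiling(L / 2)
      Xp <- if (L %% 2L == 1L) {
        tmp <- array(-Inf, dim = c(B, L + 1L, F_)); tmp[, 1:L, ] <- X; tmp
      } else X
      a <- Xp[, seq(1L, 2L * Lout, 2L), , drop = FALSE]
      b2 <- Xp[, seq(2L, 2L * Lout, 2L), , drop = FALSE]
      m <- a >= b2                                   # ties go to the first
      list(Y = pmax(a, b2), cache = list(m = m, dims = d, Lout = Lout))
    },
    flatten = {
      d <- dim(X)
      Y <- X
      dim(Y) <- c(d[1], d[2] * d[3])
      list(Y = Y, cache = list(dims = d))
    },
    dropout = {
      if (train && layer$rate > 0) {
        keep <- 1 - layer$rate
        mask <- (matrix(stats::runif(length(X)), nrow(X)) < keep) / keep
        list(Y = X * mask, cache = list(mask = mask))
      } else {
        list(Y = X, cache = list(mask = NULL))
      }
    },
    dense = {
      Y <- X %*% layer$W
      Y <- sweep(Y, 2, layer$b, `+`)
      list(Y = Y, cache = list(X = X))
    },
    stop("unknown layer type: ", layer$type)
  )
}

backward_layer <- function(layer, cache, dY) {
  switch(layer$type,
    conv = {
      d <- cache$dims
      dYm <- dY
      dim(dYm) <- c(d[1] * d[2], layer$out_ch)
      dW <- crossprod(cache$X2, dYm)
      db <- colSums(dYm)
      dX2 <- dYm %*% t(layer$W)
      dX <- col2im(dX2, d[1], d[2], layer$in_ch, layer$kernel)
      list(dX = dX, grads = list(W = dW, b = db))
    },
    relu = list(dX = dY * cache$mask, grads = NULL),
    pool = {
      d <- cache$dims; B <- d[1]; L <- d[2]; F_ <- d[3]
      Lout <- cache$Lout
      dXp <- array(0, dim = c(B, 2L * Lout, F_))
      dXp[, seq(1L, 2L * Lout, 2L), ] <- dY * cache$m
      dXp[, seq(2L, 2L * Lout, 2L), ] <- dY * !cache$m
      list(dX = dXp[, 1:L, , drop = FALSE], grads = NULL)
    },
    flatten = {
      dX <- dY
      dim(dX) <- cache$dims
      list(dX = dX, grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(dX = dY, grads = NULL)
      else list(dX = dY * cache$mask, grads = NULL)
    },
    dense = list(dX = dY %*% t(layer$W),
                 grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
  )
}

## Forward through layers [from, to]; returns final output and per-layer caches.
net_forward <- function(layers, X, train = FALSE, from = 1L,
                        to = length(layers)) {
  caches <- vector("list", length(layers))
  for (j in seq.int(from, to)) {
    fr <- forward_layer(layers[[j]], X, train = train)
    X <- fr$Y
    caches[[j]] <- fr$cache
  }
  list(out = X, caches = caches)
}

## Backward from layer `from` down to layer `to`; accumulates parameter
## gradients and returns the gradient w.r.t. the input of layer `to`.
net_backward <- function(layers, caches, dY, from = length(layers), to = 1L) {
  grads <- vector("list", length(layers))
  for (j in seq.int(from, to)) {
    br <- backward_layer(layers[[j]], caches[[j]], dY)
    dY <- br$dX
    grads[j] <- list(br$grads)
  }
  list(dX = dY, grads = grads)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

## Adam optimizer state/update over the layer list.
adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (l$type %in% c("conv", "dense")) {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    } else NULL
  })
}

adam_step <- function(layers, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (j in seq_along(layers)) {
    g <- grads[[j]]
    if (is.null(g)) next
    s <- state[[j]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    layers[[j]]$W <- layers[[j]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    layers[[j]]$b <- layers[[j]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[j]] <- s
  }
  list(layers = layers, state = state)
}
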