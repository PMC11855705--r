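# Vectorized neural-network primitives with analytic backprop.
#
# Parameters are nested named lists whose leaves are numeric arrays; leaf
# names starting with "W" receive L2 weight decay. Gradient structures
# mirror the parameter structures. Correctness of every backward pass is
# enforced by finite-difference checks in the test suite.

xavier_matrix <- function(fan_in, fan_out, nrow = fan_in, ncol = fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -limit, limit), nrow, ncol)
}

# ---- elementwise activations -------------------------------------------------

act_forward <- function(x, act) {
  switch(act,
    relu = pmax(x, 0),
    linear = x,
    sigmoid = 1 / (1 + exp(-x)),
    stop("unknown activation: ", act)
  )
}

act_backward <- function(dy, y, act) {
  switch(act,
    relu = dy * (y > 0),
    linear = dy,
    sigmoid = dy * y * (1 - y),
    stop("unknown activation: ", act)
  )
}

# ---- dense layer -------------------------------------------------------------

dense_forward <- function(X, W, b) {
  sweep(X %*% W, 2L, b, `+`)
}

dense_backward <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# ---- 1-D convolution (single input channel, "same" zero padding) -------------

# X: batch x L; W: k x F; b: length F. Output: batch x (F*L) flattened
# feature map (channel-major: column (f-1)*L + t holds filter f, position t),
# plus the im2col matrix needed for the backward pass.
conv1d_forward <- function(X, W, b) {
  batch <- nrow(X); L <- ncol(X)
  k <- nrow(W); F <- ncol(W)
  p <- (k - 1L) %/% 2L
  Xp <- cbind(
    matrix(0, batch, p), X, matrix(0, batch, p)
  )
  Xcol <- matrix(0, batch * L, k)
  for (j in seq_len(k)) {
    Xcol[, j] <- as.vector(Xp[, (seq_len(L)) + j - 1L, drop = FALSE])
  }
  out <- sweep(Xcol %*% W, 2L, b, `+`) # (batch*L) x F
  list(out = matrix(out, batch, L * F), Xcol = Xcol, dims = c(batch, L, k, F))
}

conv1d_backward <- function(dOut, Xcol, W, dims) {
  batch <- dims[1L]; L <- dims[2L]; k <- dims[3L]; F <- dims[4L]
  p <- (k - 1L) %/% 2L
  dOut_mat <- matrix(dOut, batch * L, F)
  dW <- crossprod(Xcol, dOut_mat)
  db <- colSums(dOut_mat)
  dXcol <- dOut_mat %*% t(W)
  dXp <- matrix(0, batch, L + 2L * p)
  for (j in seq_len(k)) {
    idx <- seq_len(L) + j - 1L
    dXp[, idx] <- dXp[, idx] + matrix(dXcol[, j], batch, L)
  }
  list(dX = dXp[, (p + 1L):(p + L), drop = FALSE], dW = dW, db = db)
}

# ---- batch normalization -----------------------------------------------------

bn_forward <- function(X, gamma, beta, buffers, train, momentum = 0.9, eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2L, mu)^2) # population variance over the batch
    buffers$rmean <- momentum * buffers$rmean + (1 - momentum) * mu
    buffers$rvar <- momentum * buffers$rvar + (1 - momentum) * v
  } else {
    mu <- buffers$rmean
    v <- buffers$rvar
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2L, mu), 2L, inv_sd, `*`)
  Y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(Y = Y, xhat = xhat, inv_sd = inv_sd, buffers = buffers)
}

bn_backward <- function(dY, cache, gamma) {
  m <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, `*`)
  # dX = inv_sd/m * (m*dxhat - colSums(dxhat) - xhat * colSums(dxhat*xhat))
  dX <- sweep(
    m * dxhat - matrix(colSums(dxhat), m, ncol(dY), byrow = TRUE) -
      xhat * matrix(colSums(dxhat * xhat), m, ncol(dY), byrow = TRUE),
    2L, cache$inv_sd / m, `*`
  )
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- dropout (inverted) ------------------------------------------------------

dropout_forward <- function(X, rate, train) {
  if (!train || rate <= 0) {
    return(list(Y = X, mask = NULL))
  }
  mask <- matrix(
    (stats::runif(length(X)) >= rate) / (1 - rate),
    nrow(X), ncol(X)
  )
  list(Y = X * mask, mask = mask)
}

dropout_backward <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

# ---- plain multi-layer perceptron -------------------------------------------

# sizes: c(input, hidden..., output); acts: one activation per non-input layer
mlp_init <- function(sizes, acts) {
  stopifnot(length(acts) == length(sizes) - 1L)
  layers <- vector("list", length(acts))
  for (i in seq_along(acts)) {
    layers[[i]] <- list(
      W = xavier_matrix(sizes[i], sizes[i + 1L]),
      b = rep(0, sizes[i + 1L])
    )
  }
  list(layers = layers, acts = acts)
}

mlp_forward <- function(X, mlp) {
  caches <- vector("list", length(mlp$layers))
  H <- X
  for (i in seq_along(mlp$layers)) {
    lin <- dense_forward(H, mlp$layers[[i]]$W, mlp$layers[[i]]$b)
    Y <- act_forward(lin, mlp$acts[i])
    caches[[i]] <- list(X = H, Y = Y)
    H <- Y
  }
  list(out = H, caches = caches)
}

# Returns dX and a grads structure mirroring mlp$layers.
mlp_backward <- function(dOut, fwd, mlp) {
  grads <- vector("list", length(mlp$layers))
  d <- dOut
  for (i in rev(seq_along(mlp$layers))) {
    cache <- fwd$caches[[i]]
    dlin <- act_backward(d, cache$Y, mlp$acts[i])
    bk <- dense_backward(dlin, cache$X, mlp$layers[[i]]$W)
    grads[[i]] <- list(W = bk$dW, b = bk$db)
    d <- bk$dX
  }
  list(dX = d, grads = list(layers = grads))
}

# ---- RMSprop -----------------------------------------------------------------

# One optimizer step over an arbitrary nested parameter list. `cache` may be
# NULL on the first call; weight decay applies to leaves named "W*" only.
rmsprop_step <- function(params, grads, cache, lr, rho = 0.9, eps = 1e-8,
                         weight_decay = 0) {
  walk <- function(p, g, c, nm) {
    if (is.list(p)) {
      cc <- if (is.null(c)) stats::setNames(vector("list", length(p)), names(p)) else c
      for (k in seq_along(p)) {
        key <- if (!is.null(names(p)) && nzchar(names(p)[k])) names(p)[k] else nm
        gk <- if (is.null(g)) {
          NULL
        } else if (!is.null(names(p)) && nzchar(names(p)[k])) {
          if (names(p)[k] %in% names(g)) g[[names(p)[k]]] else NULL
        } else if (k <= length(g)) {
          g[[k]]
        } else {
          NULL
        }
        r <- walk(p[[k]], gk, if (k <= length(cc)) cc[[k]] else NULL, key)
        p[k] <- list(r$p)
        cc[k] <- list(r$c) # keep NULL slots (leaves without gradients)
      }
      list(p = p, c = cc)
    } else if (is.numeric(p)) {
      if (is.null(g)) return(list(p = p, c = c))
      if (weight_decay > 0 && startsWith(nm, "W")) g <- g + weight_decay * p
      c <- if (is.null(c)) (1 - rho) * g^2 else rho * c + (1 - rho) * g^2
      list(p = p - lr * g / (sqrt(c) + eps), c = c)
    } else {
      list(p = p, c = c) # non-numeric leaves (activation tags etc.) untouched
    }
  }
  walk(params, grads, cache, "")
}

clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)
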