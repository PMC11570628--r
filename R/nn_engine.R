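# Minimal feed-forward network engine used by the twin models.
#
# A network is a list of layers forming a DAG: each layer consumes the
# column-wise concatenation of the outputs of its `inputs` (0 denotes the
# network input), applies a linear map, then optionally batch
# normalization and a ReLU. This covers both the plain MLP encoder and the
# densely connected encoder, whose layers consume all previous outputs of
# their block. All math is plain R matrix algebra so that runs are exactly
# reproducible under a fixed seed.
#
# Layer fields:
#   W           in x out weight matrix
#   b           length-out bias (linear-only layers)
#   gamma,beta  batch-norm scale/shift (bn layers)
#   rmean,rvar  batch-norm running statistics (bn layers)
#   inputs      integer vector of source layer ids (0 = network input)
#   bn, relu    logicals

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

nn_init_layer <- function(n_in, n_out, inputs, bn = TRUE, relu = TRUE) {
  # He-style fan-in initialization, suited to ReLU nonlinearities
  W <- matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  layer <- list(W = W, inputs = inputs, bn = bn, relu = relu)
  if (bn) {
    layer$gamma <- rep(1, n_out)
    layer$beta <- rep(0, n_out)
    layer$rmean <- rep(0, n_out)
    layer$rvar <- rep(1, n_out)
  } else {
    layer$b <- rep(0, n_out)
  }
  layer
}

nn_gather_input <- function(outs, X, inputs) {
  pieces <- lapply(inputs, function(s) if (s == 0L) X else outs[[s]])
  if (length(pieces) == 1L) pieces[[1L]] else do.call(cbind, pieces)
}

# Forward pass. `training` selects batch statistics (and updates running
# statistics in the returned layers) versus frozen running statistics.
nn_forward <- function(layers, X, training = FALSE) {
  n_layers <- length(layers)
  outs <- vector("list", n_layers)
  caches <- if (training) vector("list", n_layers) else NULL
  B <- nrow(X)
  for (k in seq_len(n_layers)) {
    ly <- layers[[k]]
    A_in <- nn_gather_input(outs, X, ly$inputs)
    Z <- A_in %*% ly$W
    if (ly$bn) {
      if (training) {
        mu <- colMeans(Z)
        Zc <- sweep(Z, 2L, mu)
        v <- colMeans(Zc^2)               # biased batch variance
        inv_sd <- 1 / sqrt(v + BN_EPS)
        xhat <- sweep(Zc, 2L, inv_sd, `*`)
        H <- sweep(sweep(xhat, 2L, ly$gamma, `*`), 2L, ly$beta, `+`)
        unbias <- if (B > 1L) B / (B - 1L) else 1
        layers[[k]]$rmean <- (1 - BN_MOMENTUM) * ly$rmean + BN_MOMENTUM * mu
        layers[[k]]$rvar <- (1 - BN_MOMENTUM) * ly$rvar + BN_MOMENTUM * v * unbias
      } else {
        inv_sd <- 1 / sqrt(ly$rvar + BN_EPS)
        xhat <- sweep(sweep(Z, 2L, ly$rmean), 2L, inv_sd, `*`)
        H <- sweep(sweep(xhat, 2L, ly$gamma, `*`), 2L, ly$beta, `+`)
      }
    } else {
      H <- sweep(Z, 2L, ly$b, `+`)
    }
    A <- if (ly$relu) pmax(H, 0) else H
    outs[[k]] <- A
    if (training) {
      caches[[k]] <- list(A_in = A_in,
                          Zc = if (ly$bn) Zc else NULL,
                          inv_sd = if (ly$bn) inv_sd else NULL,
                          xhat = if (ly$bn) xhat else NULL,
                          mask = if (ly$relu) (H > 0) else NULL)
    }
  }
  list(out = outs[[n_layers]], outs = outs, caches = caches, layers = layers)
}

# Backward pass. `dOut` is the gradient of the scalar loss w.r.t. the final
# layer's output. Returns per-layer parameter gradients.
nn_backward <- function(layers, fwd, X, dOut) {
  n_layers <- length(layers)
  grads <- vector("list", n_layers)
  dA <- vector("list", n_layers)           # pending output gradients
  dA[[n_layers]] <- dOut
  dX_cols <- lapply(layers, function(ly) NULL)
  for (k in rev(seq_len(n_layers))) {
    ly <- layers[[k]]
    cache <- fwd$caches[[k]]
    g <- dA[[k]]
    if (is.null(g)) g <- matrix(0, nrow(X), ncol(ly$W))  # unused output
    if (ly$relu) g <- g * cache$mask
    if (ly$bn) {
      B <- nrow(g)
      dgamma <- colSums(g * cache$xhat)
      dbeta <- colSums(g)
      dxhat <- sweep(g, 2L, ly$gamma, `*`)
      # standard batch-norm backward (through batch mean and variance)
      t1 <- sweep(dxhat, 2L, colMeans(dxhat))
      t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), `*`)
      dZ <- sweep(t1 - t2, 2L, cache$inv_sd, `*`)
      grads[[k]] <- list(W = crossprod(cache$A_in, dZ), gamma = dgamma, beta = dbeta)
    } else {
      dZ <- g
      grads[[k]] <- list(W = crossprod(cache$A_in, dZ), b = colSums(dZ))
    }
    dA_in <- tcrossprod(dZ, ly$W)
    # split the input gradient across the concatenated sources
    col0 <- 0L
    for (s in ly$inputs) {
      w <- if (s == 0L) ncol(X) else ncol(fwd$outs[[s]])
      piece <- dA_in[, (col0 + 1L):(col0 + w), drop = FALSE]
      col0 <- col0 + w
      if (s == 0L) next                     # gradient w.r.t. data not needed
      dA[[s]] <- if (is.null(dA[[s]])) piece else dA[[s]] + piece
    }
  }
  grads
}

# Adam optimizer (coupled L2 weight decay added to the gradient, as in the
# torch Adam convention). State is a parallel list of first/second moments.
adam_init <- function(layers) {
  lapply(layers, function(ly) {
    fields <- intersect(c("W", "b", "gamma", "beta"), names(ly))
    st <- lapply(fields, function(f) list(m = ly[[f]] * 0, v = ly[[f]] * 0))
    names(st) <- fields
    st
  })
}

adam_step <- function(layers, grads, state, t, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in seq_along(layers)) {
    for (f in names(state[[k]])) {
      g <- grads[[k]][[f]]
      if (is.null(g)) next
      if (weight_decay > 0) g <- g + weight_decay * layers[[k]][[f]]
      st <- state[[k]][[f]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[k]][[f]] <- layers[[k]][[f]] - lr * mhat / (sqrt(vhat) + eps)
      state[[k]][[f]] <- st
    }
  }
  list(layers = layers, state = state)
}
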