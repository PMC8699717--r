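# Minimal neural-network engine in base R matrix algebra.
#
# Activations are stored channel-fastest: a layer's input is a (C*L) x B
# matrix where element ((l-1)*C + c, b) is channel c at position l of
# example b. 1D convolutions are im2col + GEMM with zero 'same' padding
# (stride 1); max-pooling is size 2 / stride 2 with floor truncation;
# batch norm normalizes per channel over (position, batch) and keeps
# running moments for batch-independent inference. All of this exists so
# the dual-branch classifier trains on a single CPU without an external
# deep-learning framework.

.idx_cache <- new.env(parent = emptyenv())

nn_conv1d <- function(C, filters, kernel) {
  stopifnot(kernel %% 2 == 1)
  fan_in <- C * kernel
  list(type = "conv", C = C, F = filters, K = kernel,
       W = matrix(stats::rnorm(filters * fan_in, sd = sqrt(2 / fan_in)),
                  filters, fan_in),
       b = numeric(filters))
}

nn_bn <- function(C, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", C = C, momentum = momentum, eps = eps,
       gamma = rep(1, C), beta = numeric(C),
       rmean = numeric(C), rvar = rep(1, C))
}

nn_relu <- function() list(type = "relu")

nn_pool <- function(C, size = 2L) {
  stopifnot(size == 2L)  # pool backprop indexing assumes pairs
  list(type = "pool", C = C, size = size)
}

nn_dense <- function(d_in, d_out) {
  list(type = "dense", d_in = d_in, d_out = d_out,
       W = matrix(stats::rnorm(d_out * d_in, sd = sqrt(2 / d_in)),
                  d_out, d_in),
       b = numeric(d_out))
}

.fw_layer <- function(ly, x, training) {
  switch(ly$type,
    conv = {
      z <- .cpp_conv1d_fw(x, ly$C, ly$K, ly$W, ly$b)
      list(out = z, cache = x)
    },
    relu = {
      mask <- x > 0
      x[!mask] <- 0
      list(out = x, cache = mask)
    },
    bn = {
      C <- ly$C
      d <- dim(x)
      xr <- x
      dim(xr) <- c(C, length(x) %/% C)
      if (training) {
        mu <- rowMeans(xr)
        v <- rowMeans(xr * xr) - mu^2
      } else {
        mu <- ly$rmean
        v <- ly$rvar
      }
      invstd <- 1 / sqrt(v + ly$eps)
      xhat <- (xr - mu) * invstd
      out <- ly$gamma * xhat + ly$beta
      dim(out) <- d
      list(out = out,
           cache = list(xhat = xhat, invstd = invstd, d = d,
                        mu = mu, v = v))
    },
    pool = {
      C <- ly$C
      B <- ncol(x)
      L <- nrow(x) %/% C
      L2 <- L %/% ly$size
      pkey <- paste("p", C, L, sep = "_")
      base <- .idx_cache[[pkey]]
      if (is.null(base)) {
        base <- rep((seq_len(L2) - 1L) * 2L * C, each = C) + seq_len(C)
        .idx_cache[[pkey]] <- base
      }
      r1 <- base
      r2 <- base + C
      a1 <- x[r1, , drop = FALSE]
      a2 <- x[r2, , drop = FALSE]
      take1 <- a1 >= a2
      out <- a1
      out[!take1] <- a2[!take1]
      list(out = out, cache = list(r1 = r1, r2 = r2, take1 = take1,
                                   nrow_in = nrow(x)))
    },
    dense = {
      z <- ly$W %*% x + ly$b
      list(out = z, cache = x)
    },
    stop("unknown layer type: ", ly$type))
}

.bw_layer <- function(ly, cache, dout) {
  switch(ly$type,
    conv = {
      r <- .cpp_conv1d_bw(cache, dout, ly$C, ly$K, ly$W)
      list(dx = r$dx, grads = list(W = r$dW, b = as.numeric(r$db)))
    },
    relu = {
      dout[!cache] <- 0
      list(dx = dout, grads = NULL)
    },
    bn = {
      dr <- dout
      dim(dr) <- dim(cache$xhat)
      N <- ncol(cache$xhat)
      dgamma <- rowSums(dr * cache$xhat)
      dbeta <- rowSums(dr)
      dxhat <- dr * ly$gamma
      dx <- (cache$invstd / N) *
        (N * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
      dim(dx) <- cache$d
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    pool = {
      dx <- matrix(0, cache$nrow_in, ncol(dout))
      d1 <- dout
      d1[!cache$take1] <- 0
      d2 <- dout
      d2[cache$take1] <- 0
      dx[cache$r1, ] <- d1
      dx[cache$r2, ] <- d2
      list(dx = dx, grads = NULL)
    },
    dense = {
      dW <- tcrossprod(dout, cache)
      db <- rowSums(dout)
      dx <- crossprod(ly$W, dout)
      list(dx = dx, grads = list(W = dW, b = db))
    })
}

# forward a layer list; returns output + caches + updated layers (BN
# running moments move during training)
nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- .fw_layer(layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    if (training && layers[[i]]$type == "bn") {
      ly <- layers[[i]]
      m <- ly$momentum
      layers[[i]]$rmean <- m * ly$rmean + (1 - m) * r$cache$mu
      layers[[i]]$rvar <- m * ly$rvar + (1 - m) * r$cache$v
    }
  }
  list(out = x, caches = caches, layers = layers)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- .bw_layer(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)
  }
  list(dx = dout, grads = grads)
}

.softmax <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

# mean cross-entropy and gradient wrt logits; y is a one-hot (K, B) matrix
nn_softmax_xent <- function(logits, y) {
  p <- .softmax(logits)
  B <- ncol(logits)
  loss <- -sum(y * log(pmax(p, 1e-12))) / B
  list(loss = loss, probs = p, dlogits = (p - y) / B)
}

# Adam -----------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    nm <- switch(ly$type, conv = c("W", "b"), dense = c("W", "b"),
                 bn = c("gamma", "beta"), NULL)
    if (is.null(nm)) return(NULL)
    st <- lapply(nm, function(p) list(m = ly[[p]] * 0, v = ly[[p]] * 0))
    names(st) <- nm
    st
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}
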