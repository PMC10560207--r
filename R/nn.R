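# Minimal neural-network primitives for the Siamese encoder: 1-D
# convolution ("same" padding), batch normalization, max pooling, ReLU,
# dropout and dense layers, each with an explicit backward pass. Activations
# are stored as (channels, length, batch) arrays so every layer reduces to
# dense matrix products over a (C, L*B) view. Gradient correctness is
# checked against finite differences in the test suite.

# ---- array helpers ---------------------------------------------------------

as_clb <- function(x) {
  # matrix (L, B) -> array (1, L, B)
  if (is.matrix(x)) array(x, dim = c(1L, nrow(x), ncol(x))) else x
}

flat_cl <- function(a) {
  # (C, L, B) -> matrix (C*L, B), channel-major within a time step kept
  # consistent between forward use and backward scatter
  d <- dim(a)
  dim(a) <- c(d[1] * d[2], d[3])
  a
}

# ---- 1-D convolution, "same" padding ---------------------------------------

conv1d_init <- function(in_ch, out_ch, kernel, rng_scale = NULL) {
  # He-style fan-in initialization
  fan_in <- in_ch * kernel
  sd <- sqrt(2 / fan_in)
  list(W = array(stats::rnorm(out_ch * in_ch * kernel, 0, sd),
                 dim = c(out_ch, in_ch, kernel)),
       b = numeric(out_ch))
}

conv1d_forward <- function(par, x) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  K <- dim(par$W)[3]; O <- dim(par$W)[1]
  pl <- (K - 1L) %/% 2L
  xp <- array(0, dim = c(C, L + K - 1L, B))
  xp[, pl + seq_len(L), ] <- x
  ym <- matrix(par$b, nrow = O, ncol = L * B)
  for (k in seq_len(K)) {
    xk <- xp[, k:(k + L - 1L), , drop = FALSE]
    dim(xk) <- c(C, L * B)
    ym <- ym + matrix(par$W[, , k], O, C) %*% xk
  }
  y <- array(ym, dim = c(O, L, B))
  list(out = y, cache = list(xp = xp, L = L, K = K, pl = pl, dims = d))
}

conv1d_backward <- function(par, cache, dy) {
  d <- cache$dims; C <- d[1]; L <- cache$L; B <- d[3]
  K <- cache$K; O <- dim(par$W)[1]
  dym <- dy; dim(dym) <- c(O, L * B)
  dW <- array(0, dim = dim(par$W))
  dxp <- array(0, dim = dim(cache$xp))
  for (k in seq_len(K)) {
    xk <- cache$xp[, k:(k + L - 1L), , drop = FALSE]
    dim(xk) <- c(C, L * B)
    dW[, , k] <- dym %*% t(xk)
    dxk <- t(matrix(par$W[, , k], O, C)) %*% dym
    dim(dxk) <- c(C, L, B)
    dxp[, k:(k + L - 1L), ] <- dxp[, k:(k + L - 1L), , drop = FALSE] + dxk
  }
  dx <- dxp[, cache$pl + seq_len(L), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = rowSums(dym)))
}

# ---- batch normalization ----------------------------------------------------

bn_init <- function(channels) {
  list(gamma = rep(1, channels), beta = numeric(channels),
       run_mean = numeric(channels), run_var = rep(1, channels))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Normalizes per channel over all (length, batch) positions. `x` may also be
# a plain feature matrix (F, B) for the dense layers.
bn_forward <- function(par, x, training) {
  is_arr <- !is.matrix(x)
  if (is_arr) {
    d <- dim(x); C <- d[1]
    xm <- x; dim(xm) <- c(C, d[2] * d[3])
  } else {
    C <- nrow(x); xm <- x
  }
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    new_state <- list(
      run_mean = (1 - BN_MOMENTUM) * par$run_mean + BN_MOMENTUM * mu,
      run_var = (1 - BN_MOMENTUM) * par$run_var + BN_MOMENTUM * v)
  } else {
    mu <- par$run_mean
    v <- par$run_var
    xc <- xm - mu
    new_state <- NULL
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * inv_sd
  ym <- par$gamma * xhat + par$beta
  y <- if (is_arr) array(ym, dim = d) else ym
  list(out = y,
       cache = list(xhat = xhat, inv_sd = inv_sd, is_arr = is_arr,
                    dims = if (is_arr) d else dim(x), training = training),
       new_state = new_state)
}

bn_backward <- function(par, cache, dy) {
  if (cache$is_arr) {
    d <- cache$dims
    dym <- dy; dim(dym) <- c(d[1], d[2] * d[3])
  } else {
    dym <- dy
  }
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * par$gamma
  if (cache$training) {
    m <- ncol(dxhat)
    dxm <- cache$inv_sd *
      (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  } else {
    dxm <- dxhat * cache$inv_sd
  }
  dx <- if (cache$is_arr) array(dxm, dim = cache$dims) else dxm
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- max pooling (width 2, stride 2) ----------------------------------------

maxpool2_forward <- function(x) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  Lo <- L %/% 2L
  abort_if(Lo < 1, "sequence too short for max pooling")
  a <- x[, seq(1L, 2L * Lo, by = 2L), , drop = FALSE]
  b <- x[, seq(2L, 2L * Lo, by = 2L), , drop = FALSE]
  take_first <- a >= b  # ties take the earlier position
  y <- ifelse(take_first, a, b)
  dim(y) <- c(C, Lo, B)
  list(out = y, cache = list(take_first = take_first, L = L, dims = d))
}

maxpool2_backward <- function(cache, dy) {
  d <- cache$dims; C <- d[1]; L <- cache$L; B <- d[3]
  Lo <- L %/% 2L
  dx <- array(0, dim = d)
  dx[, seq(1L, 2L * Lo, by = 2L), ] <- ifelse(cache$take_first, dy, 0)
  dx[, seq(2L, 2L * Lo, by = 2L), ] <- ifelse(cache$take_first, 0, dy)
  dx
}

# ---- pointwise layers -------------------------------------------------------

relu_forward <- function(x) {
  mask <- x > 0
  list(out = ifelse(mask, x, 0), cache = mask)
}

relu_backward <- function(cache, dy) ifelse(cache, dy, 0)

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = x, cache = NULL))
  }
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = mask)
}

dropout_backward <- function(cache, dy) {
  if (is.null(cache)) dy else dy * cache
}

# ---- dense layer ------------------------------------------------------------

linear_init <- function(fan_in, fan_out) {
  sd <- sqrt(2 / fan_in)
  list(W = matrix(stats::rnorm(fan_out * fan_in, 0, sd), fan_out, fan_in),
       b = numeric(fan_out))
}

linear_forward <- function(par, x) {
  list(out = par$W %*% x + par$b, cache = x)
}

linear_backward <- function(par, cache, dy) {
  list(dx = t(par$W) %*% dy,
       grads = list(W = dy %*% t(cache), b = rowSums(dy)))
}
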