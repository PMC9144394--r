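# Minimal neural-network core: parameter initialisation, forward/backward
# passes for the layer types the denoising and classification networks
# need (1-D/2-D convolution, batch normalization, activations, linear),
# and the Adam optimizer. Parameters, gradients and optimizer moments are
# nested named lists of numeric arrays with identical structure; all
# heavy lifting is im2col + BLAS matrix multiplication.
#
# Conventions:
#   conv1d activations: array (channels, length, batch)
#   conv2d activations: array (channels, height, width, batch)
#   forward functions return list(out = ..., cache = ...)
#   backward functions return list(dx = ..., grads = <same shape as params>)

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

## ---- 1-D convolution (dilated, zero-padded to same length) ----
#
# Activations flow as plain matrices (channels x (length * batch),
# column-major over within-clip position then batch). The heavy loops
# run in compiled code (src/fast_ops.cpp).

conv1d_init <- function(cin, cout, k) {
  list(W = glorot(cin * k, cout, c(cout, cin * k)), b = numeric(cout))
}

# X: matrix (cin, L*B); dims = c(L, B)
conv1d_fwd <- function(p, X, dims, dilation = 1L, k) {
  list(out = cpp_conv1d_fwd(p$W, p$b, X, dims[1], dims[2], dilation, k),
       cache = list(X = X, dims = dims, k = k, d = dilation))
}

conv1d_bwd <- function(p, cache, dY) {
  r <- cpp_conv1d_bwd(p$W, cache$X, dY, cache$dims[1], cache$dims[2],
                      cache$d, cache$k)
  list(dx = r$dX, grads = list(W = r$W, b = r$b))
}

## ---- batch normalization over channels ----

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c))
}

bn_stats_init <- function(c) {
  list(mean = numeric(c), var = rep(1, c))
}

# X: matrix with channels as rows; normalisation is per channel over
# columns (positions x batch for conv1d activations).
bn_fwd <- function(p, X, stats, training = TRUE, momentum = 0.1,
                   eps = 1e-5) {
  if (training) {
    r <- cpp_bn_fwd(X, p$gamma, p$beta, eps)
    stats$mean <- (1 - momentum) * stats$mean + momentum * as.numeric(r$mu)
    v <- 1 / as.numeric(r$invstd)^2 - eps
    stats$var <- (1 - momentum) * stats$var + momentum * v
    list(out = r$out, stats = stats,
         cache = list(xhat = r$xhat, inv = as.numeric(r$invstd),
                      training = TRUE))
  } else {
    inv <- 1 / sqrt(stats$var + eps)
    g <- p$gamma * inv
    out <- X * g + (p$beta - stats$mean * g)
    list(out = out, stats = stats,
         cache = list(inv = inv, training = FALSE))
  }
}

bn_bwd <- function(p, cache, dY) {
  if (cache$training) {
    r <- cpp_bn_bwd(dY, cache$xhat, p$gamma, cache$inv)
    list(dx = r$dx, grads = list(gamma = as.numeric(r$gamma),
                                 beta = as.numeric(r$beta)))
  } else {
    stop("backward through eval-mode batch norm is not supported")
  }
}

## ---- activations ----

lrelu_fwd <- function(X, slope = 0.01) {
  out <- cpp_lrelu_fwd(X, slope)
  list(out = out, cache = list(out = out, slope = slope))
}

lrelu_bwd <- function(cache, dY) {
  cpp_lrelu_bwd(dY, cache$out, cache$slope)
}

relu_fwd <- function(X) {
  list(out = pmax(X, 0), cache = X > 0)
}

relu_bwd <- function(cache, dY) dY * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- linear layer (row-major batches: X is N x Din) ----

linear_init <- function(din, dout) {
  list(W = glorot(din, dout, c(din, dout)), b = numeric(dout))
}

linear_fwd <- function(p, X) {
  list(out = X %*% p$W + matrix(p$b, nrow(X), length(p$b), byrow = TRUE),
       cache = X)
}

linear_bwd <- function(p, cache, dY) {
  list(dx = tcrossprod(dY, p$W), grads = list(W = crossprod(cache, dY),
                                              b = colSums(dY)))
}

## ---- 2-D convolution (stride, zero padding) ----

conv2d_init <- function(cin, cout, k) {
  list(W = glorot(cin * k * k, cout, c(cout, cin * k * k)), b = numeric(cout))
}

conv2d_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# X: (cin, H, W, B) array; heavy loops run in compiled code
conv2d_fwd <- function(p, X, k, stride = 1L, pad = 0L) {
  dm <- dim(X)
  Ho <- conv2d_out_dim(dm[2], k, stride, pad)
  Wo <- conv2d_out_dim(dm[3], k, stride, pad)
  Xm <- X
  dim(Xm) <- c(dm[1], prod(dm[-1]))
  Y <- cpp_conv2d_fwd(p$W, p$b, Xm, dm[1], dm[2], dm[3], dm[4],
                      k, stride, pad)
  list(out = array(Y, dim = c(nrow(p$W), Ho, Wo, dm[4])),
       cache = list(X = Xm, dims = dm, k = k, stride = stride, pad = pad))
}

conv2d_bwd <- function(p, cache, dY) {
  dm <- cache$dims
  dYm <- dY
  dim(dYm) <- c(dim(dY)[1], prod(dim(dY)[-1]))
  r <- cpp_conv2d_bwd(p$W, cache$X, dYm, dm[1], dm[2], dm[3], dm[4],
                      cache$k, cache$stride, cache$pad)
  list(dx = array(r$dX, dim = dm), grads = list(W = r$W, b = r$b))
}

## ---- Adam ----

# apply f elementwise over two identically-structured nested lists
map2_params <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- map2_params(f, a[[nm]], b[[nm]])
    out
  } else {
    f(a, b)
  }
}

map_params <- function(f, a) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- map_params(f, a[[nm]])
    out
  } else {
    f(a)
  }
}

adam_init <- function(params) {
  list(m = map_params(function(x) x * 0, params),
       v = map_params(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(function(m, g) beta1 * m + (1 - beta1) * g,
                         state$m, grads)
  state$v <- map2_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                         state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map2_params(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                     state$m, state$v)
  params <- map2_params(`-`, params, upd)
  list(params = params, state = state)
}

# elementwise sum of two identically structured gradient lists
add_grads <- function(a, b) map2_params(`+`, a, b)
scale_grads <- function(a, s) map_params(function(x) x * s, a)
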