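# Minimal CNN engine: batched valid 1D convolutions over (time x feature)
# inputs, batch normalization, ReLU, inverted dropout, global max-pooling,
# fully connected layers, and an Adam optimizer. Forward passes cache
# exactly what backpropagation needs; gradients with respect to the input
# are available for attribution.
#
# Convolutions use a shift-GEMM formulation: with batch-fastest row layout
# a temporal shift is a contiguous row offset, so a kernel of k time steps
# is one BLAS multiply by the stacked weight matrix followed by k shifted
# block accumulations. This avoids materializing im2col patch matrices,
# whose memory traffic would dominate at these shapes.
#
# Batch layout conventions:
#   * network input: array (T, F, B) = (padded length, input columns, batch)
#   * between layers: matrix (B*T) x C with row order b fastest, then t
#   * after pooling: matrix B x C
#   * conv weights: F x (k*C), column block dt holding the F x C weight
#     slice of temporal offset dt

# (T, F, B) array -> (B*T) x F matrix, rows ordered b fastest
arr_to_mat <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(3L, 1L, 2L)), nrow = d[3L] * d[1L], ncol = d[2L])
}

# (B*T) x F matrix -> (T, F, B) array
mat_to_arr <- function(Xmat, T_in, B) {
  aperm(array(Xmat, dim = c(B, T_in, ncol(Xmat))), c(2L, 3L, 1L))
}

conv_fwd <- function(Xmat, T_in, B, W, bias, k) {
  C <- ncol(W) %/% k
  stopifnot(ncol(W) == k * C, nrow(W) == ncol(Xmat))
  Y <- cpp_conv_fwd(Xmat, T_in, B, W, bias, k)
  list(Y = Y, cache = list(X = Xmat, T_in = T_in, B = B, k = k, C = C))
}

conv_bwd <- function(cache, W, dY, need_dx = TRUE) {
  out <- cpp_conv_bwd(cache$X, W, dY, cache$B, cache$k, need_dx)
  list(dW = out$dW, db = as.numeric(out$db), dX = out$dX)
}

bn_fwd <- function(Y, gamma, beta, rm, rv, train, momentum = 0.1,
                   eps = 1e-5) {
  r <- cpp_bn_fwd(Y, gamma, beta, rm, rv, train, momentum, eps)
  list(out = r$out, rm = as.numeric(r$rm), rv = as.numeric(r$rv),
       cache = list(xhat = r$xhat, invstd = as.numeric(r$invstd),
                    train = train))
}

bn_bwd <- function(cache, gamma, dY) {
  r <- cpp_bn_bwd(cache$xhat, cache$invstd, gamma, dY, cache$train)
  list(dX = r$dX, dgamma = as.numeric(r$dgamma),
       dbeta = as.numeric(r$dbeta))
}

relu_fwd <- function(Y) {
  mask <- Y > 0
  Y[!mask] <- 0
  list(out = Y, cache = mask)
}

relu_bwd <- function(mask, dY) {
  dY[!mask] <- 0
  dY
}

# Inverted dropout: active only in training mode, scales kept units by
# 1/(1-p) so the eval-mode forward needs no rescaling.
dropout_fwd <- function(Y, p, train) {
  if (!train || p <= 0) return(list(out = Y, cache = NULL))
  mask <- (stats::runif(length(Y)) >= p) / (1 - p)
  dim(mask) <- dim(Y)
  list(out = Y * mask, cache = mask)
}

dropout_bwd <- function(mask, dY) {
  if (is.null(mask)) dY else dY * mask
}

# Global max-pool over the temporal axis: (B*T) x C -> B x C. Ties are
# broken by the earliest position for determinism.
pool_fwd <- function(Y, T_in, B) {
  C <- ncol(Y)
  out <- matrix(0, nrow = B, ncol = C)
  am <- matrix(0L, nrow = B, ncol = C)
  for (cc in seq_len(C)) {
    m <- matrix(Y[, cc], nrow = B)           # B x T
    a <- max.col(m, ties.method = "first")
    am[, cc] <- a
    out[, cc] <- m[cbind(seq_len(B), a)]
  }
  list(out = out, cache = list(am = am, T_in = T_in, B = B, C = C))
}

pool_bwd <- function(cache, dOut) {
  B <- cache$B; C <- cache$C
  dY <- matrix(0, nrow = B * cache$T_in, ncol = C)
  rows <- (cache$am - 1L) * B + seq_len(B)   # recycles over columns
  dY[cbind(as.vector(rows), rep(seq_len(C), each = B))] <- as.vector(dOut)
  dY
}

fc_fwd <- function(X, W, bias) {
  Y <- X %*% W
  Y <- Y + rep(bias, each = nrow(Y))
  list(Y = Y, cache = list(X = X))
}

fc_bwd <- function(cache, W, dY) {
  list(dW = crossprod(cache$X, dY), db = colSums(dY),
       dX = tcrossprod(dY, W))
}

# Xavier/Glorot uniform initialization. Draws consume the current RNG
# stream, so the caller fixes the seed.
xavier_uniform <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}
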