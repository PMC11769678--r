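# The structure-aware TF prediction architecture: three parallel
# convolutional subnetworks over the padded one-hot input, channel-wise
# concatenation, a post-concatenation convolution, global max-pooling and a
# two-layer fully connected head ending in a sigmoid TF score. A 21-column
# configuration of the same topology serves as the sequence-only comparator.

#' Temporal output length of a convolutional subnetwork
#'
#' All convolutions use stride 1 and no padding (valid convolution), so a
#' stack with time-kernel sizes `k_1..k_m` maps `L` input rows to
#' `L - sum(k_i - 1)` rows. The three subnetworks' kernel stacks
#' (4,4,16), (12,8,4) and (16,4,4) share the same total shrinkage of 21
#' rows, so their feature maps align temporally (979 rows at L = 1000).
#'
#' @param L Number of input rows.
#' @param kernels Integer vector of time-kernel sizes.
#' @return Integer output length.
#' @export
#' @examples
#' subnetwork_output_length(1000, c(4, 4, 16))  # 979
subnetwork_output_length <- function(L, kernels) {
  out <- L - sum(kernels - 1L)
  if (out < 1L) stop("input of length ", L,
                     " is shorter than the receptive field (",
                     sum(kernels - 1L) + 1L, ")")
  as.integer(out)
}

#' Model configuration
#'
#' Architecture hyperparameters. The kernel stacks of the three subnetworks
#' are fixed ((4,c),(4,1),(16,1) / (12,c),(8,1),(4,1) / (16,c),(4,1),(4,1),
#' the first kernel of each spanning all `input_cols` columns); channel
#' width, fully-connected width and the post-concatenation (tail)
#' convolution are configurable because they are not fixed by the published
#' architecture description.
#'
#' @param input_cols 63 (structure mode) or 21 (sequence-only comparator).
#' @param pad_length Padded input rows (default 1000).
#' @param channels Channels of every subnetwork convolution (default 128).
#' @param fc_hidden Width of the first fully connected layer (default 512).
#' @param dropout Dropout rate inside the subnetworks (default 0.1).
#' @param tail_kernel Time-kernel of the post-concatenation convolution
#'   (default 4).
#' @param tail_channels Channels of the post-concatenation convolution
#'   (default = `channels`).
#' @param seed Seed for Xavier-uniform weight initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(input_cols = 63L, pad_length = 1000L,
                         channels = 128L, fc_hidden = 512L, dropout = 0.1,
                         tail_kernel = 4L, tail_channels = channels,
                         seed = 1L) {
  if (!input_cols %in% c(21L, 63L)) {
    stop("input_cols must be 63 (structure) or 21 (sequence)")
  }
  stopifnot(channels >= 1L, fc_hidden >= 1L, dropout >= 0, dropout < 1,
            tail_kernel >= 1L, tail_channels >= 1L)
  kernels <- list(a = c(4L, 4L, 16L), b = c(12L, 8L, 4L), c = c(16L, 4L, 4L))
  sub_len <- vapply(kernels, function(k)
    subnetwork_output_length(pad_length, k), integer(1L))
  if (length(unique(sub_len)) != 1L) {
    stop("subnetwork output lengths differ: ",
         paste(sub_len, collapse = ", "))
  }
  tail_len <- sub_len[[1L]] - (tail_kernel - 1L)
  if (tail_len < 1L) stop("pad_length too small for the tail convolution")
  structure(list(input_cols = as.integer(input_cols),
                 pad_length = as.integer(pad_length),
                 channels = as.integer(channels),
                 fc_hidden = as.integer(fc_hidden),
                 dropout = dropout,
                 tail_kernel = as.integer(tail_kernel),
                 tail_channels = as.integer(tail_channels),
                 kernels = kernels,
                 sub_len = sub_len[[1L]],
                 tail_len = as.integer(tail_len),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build an untrained model
#'
#' Instantiates the network: three parallel subnetworks (three
#' convolution + batch-norm + ReLU + dropout blocks each, the first kernel
#' spanning all input columns), channel-wise concatenation of the
#' temporally aligned feature maps, one further convolution with batch
#' norm and ReLU, global max-pooling over the temporal axis, a hidden fully
#' connected layer (batch norm, ReLU) and a final fully connected layer
#' (batch norm) feeding a sigmoid. Convolution and fully-connected weights
#' are Xavier-uniform initialized from `cfg$seed`; biases start at zero.
#'
#' @param cfg A [model_config()].
#' @return A `structf_model` (untrained; see [train_model()]).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  ch <- cfg$channels
  params <- list()
  stats <- list()
  add_bn <- function(nm, width) {
    params[[paste0(nm, "_g")]] <<- rep(1, width)
    params[[paste0(nm, "_be")]] <<- rep(0, width)
    stats[[paste0(nm, "_rm")]] <<- rep(0, width)
    stats[[paste0(nm, "_rv")]] <<- rep(1, width)
  }
  with_seed(derive_seed(cfg$seed, "init"), {
    for (br in c("a", "b", "c")) {
      ks <- cfg$kernels[[br]]
      f_in <- cfg$input_cols
      for (i in 1:3) {
        nm <- paste0(br, i)
        k <- ks[i]
        # first layer: 1 input channel, kernel k x input_cols;
        # later layers: `ch` input channels, kernel k x 1
        kernel_elems <- if (i == 1L) k * cfg$input_cols else k
        params[[paste0(nm, "_W")]] <-
          xavier_uniform(k * f_in, ch * kernel_elems, c(f_in, k * ch))
        params[[paste0(nm, "_b")]] <- rep(0, ch)
        add_bn(nm, ch)
        f_in <- ch
      }
    }
    params$t_W <- xavier_uniform(cfg$tail_kernel * 3L * ch,
                                 cfg$tail_channels * cfg$tail_kernel,
                                 c(3L * ch,
                                   cfg$tail_kernel * cfg$tail_channels))
    params$t_b <- rep(0, cfg$tail_channels)
    add_bn("t", cfg$tail_channels)
    params$f1_W <- xavier_uniform(cfg$tail_channels, cfg$fc_hidden,
                                  c(cfg$tail_channels, cfg$fc_hidden))
    params$f1_b <- rep(0, cfg$fc_hidden)
    add_bn("f1", cfg$fc_hidden)
    params$f2_W <- xavier_uniform(cfg$fc_hidden, 1L, c(cfg$fc_hidden, 1L))
    params$f2_b <- 0
    add_bn("f2", 1L)
  })
  structure(list(cfg = cfg, params = params, stats = stats,
                 history = NULL), class = "structf_model")
}

# Full forward pass. X is a (pad_length, input_cols, B) array. In training
# mode batch statistics are used (and returned updated as running stats)
# and dropout is active; in eval mode running statistics are used and the
# pass is deterministic. With keep_cache = TRUE the returned cache supports
# nn_backward().
nn_forward <- function(model, X, train = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  st <- model$stats
  d <- dim(X)
  if (length(d) != 3L || d[1L] != cfg$pad_length || d[2L] != cfg$input_cols) {
    stop("input must be a ", cfg$pad_length, " x ", cfg$input_cols,
         " x B array")
  }
  B <- d[3L]
  Xmat <- arr_to_mat(X)
  cache <- if (keep_cache) list(B = B) else NULL
  run_bn <- function(Y, nm) {
    r <- bn_fwd(Y, p[[paste0(nm, "_g")]], p[[paste0(nm, "_be")]],
                st[[paste0(nm, "_rm")]], st[[paste0(nm, "_rv")]], train)
    if (train) {
      st[[paste0(nm, "_rm")]] <<- r$rm
      st[[paste0(nm, "_rv")]] <<- r$rv
    }
    r
  }
  branch_out <- list()
  for (br in c("a", "b", "c")) {
    ks <- cfg$kernels[[br]]
    cur <- Xmat
    Tc <- cfg$pad_length
    for (i in 1:3) {
      nm <- paste0(br, i)
      cv <- conv_fwd(cur, Tc, B, p[[paste0(nm, "_W")]],
                     p[[paste0(nm, "_b")]], ks[i])
      Tc <- Tc - ks[i] + 1L
      bn <- run_bn(cv$Y, nm)
      rl <- relu_fwd(bn$out)
      dp <- dropout_fwd(rl$out, cfg$dropout, train)
      cur <- dp$out
      if (keep_cache) {
        cache[[nm]] <- list(conv = cv$cache, bn = bn$cache,
                            relu = rl$cache, drop = dp$cache)
      }
    }
    branch_out[[br]] <- cur
  }
  Yc <- cbind(branch_out$a, branch_out$b, branch_out$c)
  cv <- conv_fwd(Yc, cfg$sub_len, B, p$t_W, p$t_b, cfg$tail_kernel)
  bn <- run_bn(cv$Y, "t")
  rl <- relu_fwd(bn$out)
  pl <- pool_fwd(rl$out, cfg$tail_len, B)
  f1 <- fc_fwd(pl$out, p$f1_W, p$f1_b)
  b1 <- run_bn(f1$Y, "f1")
  r1 <- relu_fwd(b1$out)
  f2 <- fc_fwd(r1$out, p$f2_W, p$f2_b)
  b2 <- run_bn(f2$Y, "f2")
  z <- b2$out
  if (keep_cache) {
    cache$t <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache)
    cache$pool <- pl$cache
    cache$f1 <- list(fc = f1$cache, bn = b1$cache, relu = r1$cache)
    cache$f2 <- list(fc = f2$cache, bn = b2$cache)
  }
  list(prob = as.vector(stats::plogis(z)), logit = as.vector(z),
       cache = cache, stats = st)
}

# Backpropagation through a cached forward pass. dz is dLoss/dlogit as a
# B x 1 matrix (for training, (prob - y)/B under mean BCE; for attribution,
# dprob/dlogit). Returns parameter gradients and, if requested, the
# gradient with respect to the input as a (pad_length, input_cols, B)
# array.
nn_backward <- function(model, fw, dz, need_input_grad = FALSE) {
  cfg <- model$cfg
  p <- model$params
  cache <- fw$cache
  if (is.null(cache)) stop("forward pass was run without keep_cache")
  B <- cache$B
  grads <- list()
  bnb <- function(nm, sub, dY) {
    r <- bn_bwd(sub$bn, p[[paste0(nm, "_g")]], dY)
    grads[[paste0(nm, "_g")]] <<- r$dgamma
    grads[[paste0(nm, "_be")]] <<- r$dbeta
    r$dX
  }
  dz <- matrix(dz, nrow = B, ncol = 1L)
  d <- bnb("f2", cache$f2, dz)
  fb <- fc_bwd(cache$f2$fc, p$f2_W, d)
  grads$f2_W <- fb$dW; grads$f2_b <- fb$db
  d <- relu_bwd(cache$f1$relu, fb$dX)
  d <- bnb("f1", cache$f1, d)
  fb <- fc_bwd(cache$f1$fc, p$f1_W, d)
  grads$f1_W <- fb$dW; grads$f1_b <- fb$db
  d <- pool_bwd(cache$pool, fb$dX)
  d <- relu_bwd(cache$t$relu, d)
  d <- bnb("t", cache$t, d)
  cb <- conv_bwd(cache$t$conv, p$t_W, d, need_dx = TRUE)
  grads$t_W <- cb$dW; grads$t_b <- cb$db
  ch <- cfg$channels
  d_branch <- list(a = cb$dX[, 1:ch, drop = FALSE],
                   b = cb$dX[, (ch + 1L):(2L * ch), drop = FALSE],
                   c = cb$dX[, (2L * ch + 1L):(3L * ch), drop = FALSE])
  dX_total <- NULL
  for (br in c("a", "b", "c")) {
    d <- d_branch[[br]]
    for (i in 3:1) {
      nm <- paste0(br, i)
      sub <- cache[[nm]]
      d <- dropout_bwd(sub$drop, d)
      d <- relu_bwd(sub$relu, d)
      d <- bnb(nm, sub, d)
      cb <- conv_bwd(sub$conv, p[[paste0(nm, "_W")]], d,
                     need_dx = (i > 1L) || need_input_grad)
      grads[[paste0(nm, "_W")]] <- cb$dW
      grads[[paste0(nm, "_b")]] <- cb$db
      d <- cb$dX
    }
    if (need_input_grad) {
      dX_total <- if (is.null(dX_total)) d else dX_total + d
    }
  }
  dX <- NULL
  if (need_input_grad) {
    dX <- mat_to_arr(dX_total, cfg$pad_length, B)
  }
  list(grads = grads, dX = dX)
}

#' Predict TF scores
#'
#' Deterministic eval-mode forward pass (running batch-norm statistics,
#' dropout off). Scores are sigmoid outputs in (0, 1), interpreted as the
#' probability that a protein is a TF.
#'
#' @param model A `structf_model`.
#' @param X One encoded matrix (`pad_length` x `input_cols`) or an array
#'   (`pad_length`, `input_cols`, n).
#' @param batch_size Internal chunk size (default 128).
#' @return Numeric vector of scores.
#' @export
predict_scores <- function(model, X, batch_size = 128L) {
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  n <- dim(X)[3L]
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx] <- nn_forward(model, X[, , idx, drop = FALSE],
                           train = FALSE)$prob
  }
  out
}

#' Save / load a trained model
#'
#' Checkpoints hold the configuration, all weights, batch-norm running
#' statistics and the training history.
#'
#' @param model A `structf_model`.
#' @param path File path (`.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "structf_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "structf_model"))
  model
}

#' @export
print.structf_model <- function(x, ...) {
  cfg <- x$cfg
  n_par <- sum(vapply(x$params, length, numeric(1L)))
  cat("structf CNN model\n",
      "  input: ", cfg$pad_length, " x ", cfg$input_cols,
      if (cfg$input_cols == 63L) " (structure encoding)" else
        " (sequence encoding)", "\n",
      "  channels: ", cfg$channels, ", fc hidden: ", cfg$fc_hidden,
      ", dropout: ", cfg$dropout, "\n",
      "  parameters: ", format(n_par, big.mark = ","),
      if (is.null(x$history)) " (untrained)\n" else
        paste0("; trained ", nrow(x$history), " epochs\n"), sep = "")
  invisible(x)
}
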