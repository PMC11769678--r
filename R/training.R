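# Optimization protocol and experiment-grid orchestration: binary
# cross-entropy with an Adam optimizer at the study's constant
# hyperparameters (learning rate 0.001, batch size 128, 50 epochs), model
# selection by minimum validation loss, and the method x dataset x split
# grid enumeration (3 x 12 x 5 = 180 cells at full scale).

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 128).
#' @param epochs Number of epochs (default 50); no early stopping and no
#'   learning-rate schedule.
#' @param selection `"best_val"` (return the epoch checkpoint with minimal
#'   validation loss, the default) or `"final"` (last epoch).
#' @param seed Seed governing shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 128L,
                         epochs = 50L, selection = c("best_val", "final"),
                         seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 selection = match.arg(selection),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Mean binary cross-entropy of sigmoid scores against 0/1 labels.
bce_loss <- function(prob, y) {
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(prob) + (1 - y) * log(1 - prob))
}

# Eval-mode loss over a (possibly large) index set, chunked.
validation_loss <- function(model, X, y, idx, batch_size) {
  total <- 0
  for (start in seq(1L, length(idx), by = batch_size)) {
    take <- idx[start:min(start + batch_size - 1L, length(idx))]
    prob <- nn_forward(model, X[, , take, drop = FALSE], train = FALSE)$prob
    total <- total + bce_loss(prob, y[take]) * length(take)
  }
  total / length(idx)
}

#' Train a model
#'
#' Minimizes mean binary cross-entropy with Adam. Each epoch shuffles the
#' training indices (seeded), runs minibatch forward/backward passes in
#' training mode (batch statistics, dropout) and then records the
#' eval-mode validation loss. Depending on `cfg$selection` the returned
#' model carries the weights of the best-validation epoch or of the final
#' epoch. The run is fully reproducible from `cfg$seed`.
#'
#' @param model An untrained (or previously trained) `structf_model`.
#' @param X Encoded array (`pad_length`, `input_cols`, n).
#' @param y Numeric/logical labels of length n (1 = TF).
#' @param train_idx,val_idx Disjoint index vectors into the third dimension
#'   of `X`.
#' @param cfg A [train_config()].
#' @return The trained `structf_model`; `$history` is a data frame with
#'   per-epoch `train_loss` and `val_loss`.
#' @export
train_model <- function(model, X, y, train_idx, val_idx, cfg = train_config()) {
  stopifnot(inherits(model, "structf_model"), inherits(cfg, "train_config"))
  y <- as.numeric(y)
  if (length(intersect(train_idx, val_idx)) > 0L) {
    stop("train and validation indices overlap")
  }
  if (length(train_idx) == 0L || length(val_idx) == 0L) {
    stop("empty training or validation split")
  }
  if (length(unique(y[train_idx])) < 2L) {
    warning("training labels are single-class; proceeding")
  }
  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(val = Inf, params = model$params, stats = model$stats)
  with_seed(derive_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$epochs)) {
      order_idx <- sample(train_idx)
      epoch_loss <- 0
      for (start in seq(1L, length(order_idx), by = cfg$batch_size)) {
        take <- order_idx[start:min(start + cfg$batch_size - 1L,
                                    length(order_idx))]
        fw <- nn_forward(model, X[, , take, drop = FALSE], train = TRUE,
                         keep_cache = TRUE)
        model$stats <- fw$stats
        epoch_loss <- epoch_loss + bce_loss(fw$prob, y[take]) * length(take)
        dz <- (fw$prob - y[take]) / length(take)
        bw <- nn_backward(model, fw, dz)
        upd <- adam_step(model$params, bw$grads, state, cfg$learning_rate)
        model$params <- upd$params
        state <- upd$state
      }
      val <- validation_loss(model, X, y, val_idx, cfg$batch_size)
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = epoch_loss / length(order_idx),
                                  val_loss = val))
      if (val < best$val) {
        best <- list(val = val, params = model$params, stats = model$stats)
      }
    }
  })
  if (cfg$selection == "best_val") {
    model$params <- best$params
    model$stats <- best$stats
  }
  model$history <- history
  model
}

#' Enumerate the experiment grid
#'
#' Full factorial enumeration of methods x datasets x split indices; at the
#' study's full scale 3 methods x 12 datasets x 5 splits = 180 cells. Each
#' cell receives a deterministic seed derived from `master_seed`, so grids
#' are reproducible and individually re-runnable.
#'
#' @param methods Character vector of method names.
#' @param datasets Character vector of dataset names.
#' @param splits Integer vector of test-fold indices.
#' @param master_seed Master seed.
#' @return Data frame with columns `method`, `dataset`, `split`, `seed`,
#'   one row per cell.
#' @export
experiment_grid <- function(methods, datasets, splits, master_seed = 1L) {
  grid <- expand.grid(split = splits, dataset = datasets, method = methods,
                      stringsAsFactors = FALSE)[, c("method", "dataset",
                                                    "split")]
  grid$seed <- vapply(seq_len(nrow(grid)), function(i)
    derive_seed(master_seed, grid$method[i], grid$dataset[i], grid$split[i]),
    integer(1L))
  grid
}

#' Train and evaluate every cell of an experiment grid
#'
#' For each (method, dataset, split) cell: materialize the split from the
#' dataset's fold plan, train the method's model on the training portion
#' with validation-based checkpointing, score the held-out test fold and
#' compute AU-ROC, AU-PRC and MCC. All per-cell seeds derive from the
#' grid's master seed.
#'
#' @param grid Data frame from [experiment_grid()].
#' @param datasets Named list; each element a list with `manifest` (a
#'   fold-assigned `dataset_manifest`) and `encodings` (named list mapping
#'   encoding name to an (`pad_length`, cols, n) array whose third
#'   dimension is aligned with `manifest$ids`).
#' @param methods Named list; each element a list with `encoding` (name
#'   into `encodings`) and `cfg_fn`, a `function(seed)` returning a
#'   [model_config()].
#' @param train_cfg_fn `function(seed)` returning a [train_config()].
#' @return Data frame: one row per cell with the three metrics and the
#'   confusion counts at threshold 0.5.
#' @export
run_grid <- function(grid, datasets, methods, train_cfg_fn) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    ds <- datasets[[cell$dataset]]
    if (is.null(ds)) stop("dataset not materialized: ", cell$dataset)
    meth <- methods[[cell$method]]
    if (is.null(meth)) stop("unknown method: ", cell$method)
    manifest <- ds$manifest
    X <- ds$encodings[[meth$encoding]]
    slot <- stats::setNames(seq_along(manifest$ids), manifest$ids)
    split <- make_split(manifest, cell$split, seed = cell$seed)
    y <- as.numeric(manifest$labels[manifest$ids])
    model <- build_model(meth$cfg_fn(cell$seed))
    model <- train_model(model, X, y,
                         train_idx = unname(slot[split$train_ids]),
                         val_idx = unname(slot[split$val_ids]),
                         cfg = train_cfg_fn(cell$seed))
    test_idx <- unname(slot[split$test_ids])
    scores <- predict_scores(model, X[, , test_idx, drop = FALSE])
    res <- evaluate_scores(y[test_idx], scores)
    cbind(cell, as.data.frame(res[c("au_roc", "au_prc", "mcc", "tp", "fp",
                                    "tn", "fn")]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
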