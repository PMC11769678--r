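# Optimization behaviour, seeded determinism, checkpoint selection and
# experiment-grid orchestration.

test_that("training reduces the loss on a separable toy task", {
  task <- toy_task(seed = 61L)
  m <- build_model(tiny_model_config(seed = 61L))
  m <- train_model(m, task$X, task$y, task$train_idx, task$val_idx,
                   train_config(epochs = 12L, batch_size = 8L, seed = 61L))
  h <- m$history
  expect_identical(nrow(h), 12L)
  expect_lt(h$train_loss[12L], h$train_loss[1L])
  expect_lt(min(h$val_loss), 0.5)
})

test_that("identical seeds give identical histories and weights", {
  task <- toy_task(seed = 62L)
  run <- function() {
    m <- build_model(tiny_model_config(seed = 62L))
    train_model(m, task$X, task$y, task$train_idx, task$val_idx,
                train_config(epochs = 4L, batch_size = 8L, seed = 62L))
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("checkpoint selection returns the minimum-validation-loss epoch", {
  task <- toy_task(seed = 63L)
  m0 <- build_model(tiny_model_config(seed = 63L))
  cfg <- train_config(epochs = 6L, batch_size = 8L, seed = 63L)
  best <- train_model(m0, task$X, task$y, task$train_idx, task$val_idx, cfg)
  val_best <- structf:::validation_loss(best, task$X, task$y, task$val_idx,
                                        8L)
  expect_equal(val_best, min(best$history$val_loss), tolerance = 1e-10)

  final <- train_model(m0, task$X, task$y, task$train_idx, task$val_idx,
                       train_config(epochs = 6L, batch_size = 8L,
                                    selection = "final", seed = 63L))
  expect_identical(final$history, best$history)
})

test_that("degenerate splits are rejected or warned about", {
  task <- toy_task(seed = 64L)
  m <- build_model(tiny_model_config(seed = 64L))
  expect_error(train_model(m, task$X, task$y, task$train_idx,
                           task$train_idx[1L], train_config(epochs = 1L)),
               "overlap")
  pos <- which(task$y == 1)
  expect_warning(
    train_model(m, task$X, task$y, pos[1:6], pos[7:8],
                train_config(epochs = 1L, batch_size = 4L, seed = 1L)),
    "single-class")
})

test_that("the experiment grid enumerates method x dataset x split cells", {
  methods <- c("structure", "sequence", "sequence-rnn")
  combos <- expand.grid(x = c("rl", "a"), z = c("nr", "r"), s = c(3, 5, 10))
  datasets <- sprintf("D(%s,%s,%d)", combos$x, combos$z, combos$s)
  grid <- experiment_grid(methods, datasets, 0:4, master_seed = 1L)
  expect_identical(nrow(grid), 180L)
  expect_identical(nrow(unique(grid[, 1:3])), 180L)  # duplicate-free
  smoke <- experiment_grid("structure", "D(rl,nr,3)", 0:4)
  expect_identical(nrow(smoke), 5L)
  # deterministic enumeration and seeds
  expect_identical(experiment_grid(methods, datasets, 0:4, master_seed = 1L),
                   grid)
  expect_true(all(grid$seed > 0 & grid$seed < 2^31))
})

test_that("run_grid trains and scores every cell reproducibly", {
  set.seed(66)
  records <- c(
    lapply(1:10, function(i) list(protein_id = sprintf("T%02d", i),
                                  sequence = strrep("A", 30L),
                                  ssg = strrep("a", 30L), tf_label = TRUE)),
    lapply(1:30, function(i) list(protein_id = sprintf("N%02d", i),
                                  sequence = strrep("G", 30L),
                                  ssg = strrep("c", 30L), tf_label = FALSE)))
  enc <- encode_records(records, "sequence", pad_length = 40L)
  man <- sample_ratio(enc$ids[enc$labels], enc$ids[!enc$labels], 3L,
                      seed = 66L, name = "toy")
  man <- stratified_folds(man, k = 5L, seed = 66L)
  # align encoding order with manifest order
  ord <- match(man$ids, enc$ids)
  datasets <- list(toy = list(manifest = man,
                              encodings = list(sequence =
                                                 enc$X[, , ord])))
  methods <- list(seqmodel = list(
    encoding = "sequence",
    cfg_fn = function(seed) tiny_model_config(seed = seed)))
  grid <- experiment_grid("seqmodel", "toy", 0:1, master_seed = 5L)
  res <- run_grid(grid, datasets, methods,
                  function(seed) train_config(epochs = 2L, batch_size = 8L,
                                              seed = seed))
  expect_identical(nrow(res), 2L)
  expect_true(all(c("au_roc", "au_prc", "mcc") %in% names(res)))
  expect_true(all(res$au_roc >= 0 & res$au_roc <= 1))
  res2 <- run_grid(grid, datasets, methods,
                   function(seed) train_config(epochs = 2L, batch_size = 8L,
                                               seed = seed))
  expect_identical(res, res2)
  bad <- experiment_grid("seqmodel", "missing", 0L)
  expect_error(run_grid(bad, datasets, methods,
                        function(seed) train_config(epochs = 1L)),
               "not materialized")
})
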