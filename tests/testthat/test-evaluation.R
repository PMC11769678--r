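# Metrics against hand enumeration and independent oracles.

test_that("confusion counts use a strict > threshold for TF calls", {
  cm <- confusion_at_threshold(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2))
  expect_identical(cm, c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  # a score of exactly 0.5 is a non-TF call
  expect_identical(confusion_at_threshold(1, 0.5)[["fn"]], 1L)
  expect_identical(confusion_at_threshold(0, 0.5)[["tn"]], 1L)
  cm2 <- confusion_at_threshold(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_identical(cm2[["fp"]] + cm2[["fn"]], 0L)
  expect_error(confusion_at_threshold(numeric(0), numeric(0)), "empty")
})

test_that("MCC matches the closed form and is undefined on zero marginals", {
  expect_equal(mcc(3, 1, 5, 1), 14 / 24)
  expect_identical(mcc(2, 0, 3, 0), 1)
  # all-negative predictions on mixed labels: TP + FP = 0 -> NaN
  cm <- confusion_at_threshold(c(1, 1, 0), c(0.2, 0.3, 0.1))
  expect_true(is.nan(mcc(cm["tp"], cm["fp"], cm["tn"], cm["fn"])))
  set.seed(71)
  for (rep in 1:25) {
    cm <- as.list(sample(0:6, 4L, replace = TRUE))
    names(cm) <- c("tp", "fp", "tn", "fn")
    v <- mcc(cm$tp, cm$fp, cm$tn, cm$fn)
    if (!is.nan(v)) {
      expect_lte(abs(v), 1)
      oracle <- (cm$tp * cm$tn - cm$fp * cm$fn) /
        sqrt(prod(c(cm$tp + cm$fp, cm$tp + cm$fn,
                    cm$tn + cm$fp, cm$tn + cm$fn)))
      expect_equal(v, oracle)
    }
  }
})

test_that("AU-ROC equals the pairwise ordering oracle, ties counted half", {
  pair_oracle <- function(labels, scores) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    total <- 0
    for (p in pos) for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
    total / (length(pos) * length(neg))
  }
  expect_identical(au_roc(c(1, 0), c(0.2, 0.8)), 0)   # complete inversion
  expect_identical(au_roc(c(1, 0), c(0.8, 0.2)), 1)
  set.seed(72)
  for (rep in 1:20) {
    n <- sample(6:25, 1L)
    labels <- c(1, 0, sample(0:1, n - 2L, replace = TRUE))
    scores <- round(runif(n), 1)   # coarse grid forces ties
    expect_equal(au_roc(labels, scores), pair_oracle(labels, scores))
  }
  expect_error(au_roc(rep(1, 4), runif(4)), "both classes")
})

test_that("AU-ROC agrees with an established implementation", {
  set.seed(73)
  labels <- sample(0:1, 60L, replace = TRUE, prob = c(0.7, 0.3))
  labels[1:2] <- 0:1
  scores <- runif(60L)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(au_roc(labels, scores), ref, tolerance = 1e-12)
})

test_that("AU-PRC is step-wise average precision with tie grouping", {
  ap_oracle <- function(labels, scores) {
    # independent formulation: walk distinct thresholds from high to low
    th <- sort(unique(scores), decreasing = TRUE)
    prev_recall <- 0; ap <- 0; n_pos <- sum(labels == 1)
    for (t in th) {
      called <- scores >= t
      prec <- sum(labels[called] == 1) / sum(called)
      recall <- sum(labels[called] == 1) / n_pos
      ap <- ap + (recall - prev_recall) * prec
      prev_recall <- recall
    }
    ap
  }
  expect_identical(au_prc(c(1, 0), c(0.8, 0.2)), 1)
  set.seed(74)
  for (rep in 1:20) {
    n <- sample(6:30, 1L)
    labels <- c(1, 0, sample(0:1, n - 2L, replace = TRUE))
    scores <- round(runif(n), 1)
    expect_equal(au_prc(labels, scores), ap_oracle(labels, scores))
  }
})

test_that("metrics are invariant under joint permutation", {
  set.seed(75)
  labels <- c(1, 0, sample(0:1, 28L, replace = TRUE))
  scores <- runif(30L)
  perm <- sample(30L)
  expect_equal(au_roc(labels[perm], scores[perm]), au_roc(labels, scores))
  expect_equal(au_prc(labels[perm], scores[perm]), au_prc(labels, scores))
  expect_identical(confusion_at_threshold(labels[perm], scores[perm]),
                   confusion_at_threshold(labels, scores))
})

test_that("paired Wilcoxon follows the exact small-sample distribution", {
  expect_identical(paired_wilcoxon(1:10, 1:10), 1)           # identical
  a <- 0.5 + (1:15) / 100                                    # all positive,
  b <- rep(0.5, 15)                                          # distinct diffs
  expect_equal(paired_wilcoxon(a, b), 2 / 2^15, tolerance = 1e-12)
  expect_equal(paired_wilcoxon(b, a), paired_wilcoxon(a, b)) # antisymmetry
  set.seed(76)
  x <- runif(12); y <- x + rnorm(12, 0, 0.05)
  expect_equal(paired_wilcoxon(x, y), paired_wilcoxon(y, x))
  expect_gt(paired_wilcoxon(x, y), 0)
})

test_that("evaluate_scores bundles measures and aggregate tables track NaN", {
  labels <- c(1, 1, 0, 0, 0)
  scores <- c(0.9, 0.2, 0.4, 0.1, 0.3)
  res <- evaluate_scores(labels, scores)
  expect_identical(res$n_pos, 2L)
  expect_identical(res$tp, 1L)
  expect_equal(res$au_roc, au_roc(labels, scores))
  df <- data.frame(method = "m", dataset = "d",
                   au_roc = c(0.8, 0.9), au_prc = c(0.5, 0.6),
                   mcc = c(NaN, 0.4))
  agg <- aggregate_results(df)
  expect_true(is.nan(agg$mean_mcc))       # undefined propagates as missing
  expect_equal(agg$mean_au_roc, 0.85)
})
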