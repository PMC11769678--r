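# Dataset curation: cluster tables, representative selection, ratio
# sampling, stratified folds and the 72/8/20 split geometry.

test_that("cluster TSVs parse with implied self-membership", {
  p <- withr::local_tempfile(lines = c("A\tA", "A\tB", "C\tC"))
  ct <- read_cluster_tsv(p)
  expect_identical(unclass(ct), list(A = c("A", "B"), C = "C"))

  p2 <- withr::local_tempfile(lines = "A\tB")
  expect_identical(unclass(read_cluster_tsv(p2)), list(A = c("A", "B")))

  p3 <- withr::local_tempfile(lines = c("A\tB", "C\tB"))
  expect_error(read_cluster_tsv(p3), "two clusters")
})

test_that("representative selection prefers TFs per the curation rule", {
  p <- withr::local_tempfile(lines = c(
    "A\tA", "A\tB",        # no TF -> representative A
    "D\tD", "D\tE",        # representative D is a TF -> D
    "F\tF", "F\tG"))       # F non-TF, G the only TF -> G
  ct <- read_cluster_tsv(p)
  labels <- c(A = FALSE, B = FALSE, D = TRUE, E = TRUE, F = FALSE, G = TRUE)
  expect_identical(select_representatives(ct, labels, seed = 5L),
                   c("A", "D", "G"))
  expect_error(select_representatives(ct, labels[-1L]), "unlabeled")
})

test_that("selection keeps one protein per cluster and a TF whenever present", {
  set.seed(41)
  for (rep in 1:10) {
    members <- paste0("P", seq_len(sample(15:30, 1L)))
    assign <- sample(sample(3:8, 1L), length(members), replace = TRUE)
    clusters <- split(members, assign)
    n_clusters <- length(clusters)
    names(clusters) <- vapply(clusters, `[[`, "", 1L)  # first member = rep
    class(clusters) <- "cluster_table"
    labels <- stats::setNames(runif(length(members)) < 0.3, members)
    sel <- select_representatives(clusters, labels, seed = rep)
    expect_length(sel, n_clusters)
    for (i in seq_along(clusters)) {
      expect_true(sel[i] %in% clusters[[i]])
      if (any(labels[clusters[[i]]])) expect_true(labels[[sel[i]]])
    }
  }
})

test_that("ratio sampling reproduces the study's dataset arithmetic", {
  tfs <- sprintf("T%04d", 1:635)
  nontfs <- sprintf("N%05d", 1:20249)
  for (s in c(3L, 5L, 10L)) {
    man <- sample_ratio(tfs, nontfs, s, seed = 7L)
    expect_identical(length(man$ids), 635L + s * 635L)
    expect_identical(sum(man$labels), 635L)
    expect_identical(sum(!man$labels), s * 635L)
  }
  expect_identical(length(sample_ratio(tfs, nontfs, 3L, seed = 7L)$ids), 2540L)
  expect_identical(length(sample_ratio(tfs, nontfs, 5L, seed = 7L)$ids), 3810L)
  expect_identical(length(sample_ratio(tfs, nontfs, 10L, seed = 7L)$ids), 6985L)
})

test_that("ratio sampling is exact, exhaustive when possible, and guarded", {
  man <- sample_ratio(paste0("T", 1:10), paste0("N", 1:30), 3L, seed = 1L)
  expect_setequal(man$ids, c(paste0("T", 1:10), paste0("N", 1:30)))
  expect_error(sample_ratio(paste0("T", 1:10), paste0("N", 1:29), 3L),
               "insufficient")
  set.seed(42)
  for (rep in 1:10) {
    n_tf <- sample(3:20, 1L)
    s <- sample(c(3L, 5L, 10L), 1L)
    man <- sample_ratio(paste0("T", seq_len(n_tf)),
                        paste0("N", seq_len(s * n_tf + sample(0:50, 1L))),
                        s, seed = rep)
    expect_identical(sum(!man$labels), s * sum(man$labels))
  }
})

test_that("stratified folds preserve the class ratio within one protein", {
  man <- sample_ratio(paste0("T", 1:4), paste0("N", 1:12), 3L, seed = 2L)
  man <- stratified_folds(man, k = 4L, seed = 2L)
  for (f in 0:3) {
    ids <- man$ids[man$fold[man$ids] == f]
    expect_identical(sum(man$labels[ids]), 1L)
    expect_identical(sum(!man$labels[ids]), 3L)
  }

  man2 <- sample_ratio(sprintf("T%04d", 1:635), sprintf("N%05d", 1:2000),
                       3L, seed = 3L)
  man2 <- stratified_folds(man2, k = 5L, seed = 3L)
  for (f in 0:4) {
    ids <- man2$ids[man2$fold[man2$ids] == f]
    expect_identical(sum(man2$labels[ids]), 127L)
    expect_identical(sum(!man2$labels[ids]), 381L)
  }

  # general +/-1 property
  set.seed(43)
  for (rep in 1:5) {
    n_tf <- sample(7:30, 1L)
    man3 <- sample_ratio(paste0("T", seq_len(n_tf)),
                         paste0("N", seq_len(5L * n_tf)), 5L, seed = rep)
    man3 <- stratified_folds(man3, k = 5L, seed = rep)
    counts <- table(man3$fold, man3$labels[man3$ids])
    expect_true(all(apply(counts, 2L, function(x) diff(range(x)) <= 1L)))
    expect_identical(sort(unique(man3$fold)), 0:4)
  }
  expect_error(stratified_folds(sample_ratio(paste0("T", 1:3),
                                             paste0("N", 1:9), 3L), k = 5L),
               "cannot fill")
})

test_that("splits realize the 20/72/8 test/train/validation geometry", {
  man <- sample_ratio(paste0("T", 1:25), paste0("N", 1:75), 3L, seed = 4L)
  man <- stratified_folds(man, k = 5L, seed = 4L)
  sp <- make_split(man, test_fold = 0L, seed = 4L)
  expect_length(sp$test_ids, 20L)
  expect_length(sp$train_ids, 72L)
  expect_length(sp$val_ids, 8L)
  expect_length(intersect(sp$train_ids, sp$val_ids), 0L)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  expect_length(intersect(sp$val_ids, sp$test_ids), 0L)
  expect_setequal(c(sp$train_ids, sp$val_ids, sp$test_ids), man$ids)

  # rotation: each protein is tested exactly once across the five splits
  tested <- unlist(lapply(0:4, function(f)
    make_split(man, f, seed = 4L)$test_ids))
  expect_identical(sort(tested), sort(man$ids))
  expect_error(make_split(man, 5L), "test_fold")
})

test_that("manifests are byte-reproducible and round-trip", {
  build <- function() {
    man <- sample_ratio(paste0("T", 1:12), paste0("N", 1:60), 3L, seed = 9L)
    stratified_folds(man, k = 4L, seed = 9L)
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_manifest(build(), file.path(d1, "m"))
  write_manifest(build(), file.path(d2, "m"))
  for (ext in c(".json", ".tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, paste0("m", ext)))),
                     unname(tools::md5sum(file.path(d2, paste0("m", ext)))))
  }
  back <- read_manifest(file.path(d1, "m"))
  orig <- build()
  expect_identical(back$ids, orig$ids)
  expect_identical(back$labels, orig$labels)
  expect_identical(back$fold, orig$fold)
  expect_identical(back$name, orig$name)
})

test_that("dataset names follow the D(x,z,s) convention", {
  expect_identical(dataset_name("rl", "nr", 3), "D(rl,nr,3)")
  expect_identical(dataset_name("a", "r", 10), "D(a,r,10)")
  expect_error(dataset_name("rl", "nr", 4), "3, 5 or 10")
})
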