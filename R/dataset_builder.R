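# Dataset curation: representative selection from sequence clusters,
# class-ratio sampling into the D(x,z,s) datasets, and stratified 5-fold
# split plans with a 72/8/20 train/validation/test geometry.

#' Compose a D(x,z,s) dataset name
#'
#' Naming convention for the twelve study datasets: `x` marks structure
#' reliability (`rl` = reliable structures only, `a` = all), `z` sequence
#' redundancy (`nr` = non-redundant, `r` = redundant) and `s` the non-TF:TF
#' class-assignment ratio (3, 5 or 10).
#'
#' @param x `"rl"` or `"a"`.
#' @param z `"nr"` or `"r"`.
#' @param s 3, 5 or 10.
#' @return String like `"D(rl,nr,3)"`.
#' @export
dataset_name <- function(x = c("rl", "a"), z = c("nr", "r"), s = 3L) {
  x <- match.arg(x); z <- match.arg(z)
  if (!s %in% c(3L, 5L, 10L)) stop("ratio s must be 3, 5 or 10")
  sprintf("D(%s,%s,%d)", x, z, as.integer(s))
}

#' Read an MMSeqs2 easy-cluster membership table
#'
#' Parses the two-column TSV written by `mmseqs easy-cluster` (each line
#' `representative<TAB>member`). The representative's self-membership line is
#' optional; membership of a representative in its own cluster is implied.
#' A member claimed by two different representatives is an error.
#'
#' @param path Path to the cluster TSV (no header).
#' @return A `cluster_table`: named list mapping representative id to the
#'   character vector of member ids (representative first).
#' @export
read_cluster_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) != 2L) stop("cluster TSV must have exactly two columns")
  reps <- df[[1L]]; members <- df[[2L]]
  # implied self-membership of every representative
  reps <- c(reps, unique(df[[1L]]))
  members <- c(members, unique(df[[1L]]))
  keep <- !duplicated(paste0(reps, "\r", members))
  reps <- reps[keep]; members <- members[keep]
  n_owner <- tapply(reps, members, function(r) length(unique(r)))
  if (any(n_owner > 1L)) {
    stop("member(s) claimed by two clusters: ",
         paste(names(n_owner)[n_owner > 1L], collapse = ", "))
  }
  out <- split(members, factor(reps, levels = unique(df[[1L]])))
  out <- lapply(names(out), function(r) unique(c(r, out[[r]])))
  names(out) <- unique(df[[1L]])
  structure(out, class = "cluster_table")
}

#' Select one protein per sequence cluster
#'
#' Implements the redundancy-removal rule: a cluster without TFs keeps its
#' clustering-tool representative; a cluster whose representative is a TF
#' keeps the representative; a cluster containing TFs but with a non-TF
#' representative contributes one uniformly drawn TF member, so that as much
#' TF data as possible survives redundancy removal.
#'
#' @param clusters A `cluster_table` from [read_cluster_tsv()].
#' @param labels Named logical vector: TF label per protein id (must cover
#'   every member).
#' @param seed Integer seed for the random TF draw.
#' @return Character vector of selected protein ids, one per cluster.
#' @export
select_representatives <- function(clusters, labels, seed = 1L) {
  stopifnot(inherits(clusters, "cluster_table"))
  all_members <- unlist(clusters, use.names = FALSE)
  missing <- setdiff(all_members, names(labels))
  if (length(missing) > 0L) {
    stop("unlabeled member(s): ", paste(utils::head(missing, 5L),
                                        collapse = ", "))
  }
  with_seed(seed, vapply(names(clusters), function(rep_id) {
    members <- clusters[[rep_id]]
    tfs <- members[labels[members]]
    if (length(tfs) == 0L || labels[[rep_id]]) {
      rep_id
    } else if (length(tfs) == 1L) {
      tfs
    } else {
      sample(tfs, 1L)
    }
  }, character(1L), USE.NAMES = FALSE))
}

#' Sample non-TFs to a fixed class-assignment ratio
#'
#' Keeps every TF and draws exactly `s` times as many non-TFs uniformly
#' without replacement, the class-imbalance handling used to build each
#' D(x,z,s) dataset.
#'
#' @param tf_ids Character vector of TF protein ids.
#' @param nontf_ids Character vector of non-TF protein ids (at least
#'   `s * length(tf_ids)`).
#' @param s Non-TF:TF ratio (3, 5 or 10 in the study; any positive integer
#'   accepted).
#' @param seed Integer seed for the draw.
#' @param name Dataset name (default from [dataset_name()] is up to the
#'   caller; any label accepted).
#' @return A `dataset_manifest`: list with `name`, `ids`, `labels` (named
#'   logical), `s`, `seed` and an unassigned `fold` slot.
#' @export
sample_ratio <- function(tf_ids, nontf_ids, s, seed = 1L,
                         name = sprintf("ratio-%d", s)) {
  s <- as.integer(s)
  stopifnot(s >= 1L, length(tf_ids) >= 1L)
  n_need <- s * length(tf_ids)
  if (length(nontf_ids) < n_need) {
    stop("insufficient non-TFs: need ", n_need, ", have ", length(nontf_ids))
  }
  drawn <- with_seed(derive_seed(seed, "ratio", s),
                     sample(nontf_ids, n_need))
  ids <- c(tf_ids, drawn)
  labels <- stats::setNames(c(rep(TRUE, length(tf_ids)),
                              rep(FALSE, n_need)), ids)
  structure(list(name = name, ids = ids, labels = labels, s = s,
                 seed = as.integer(seed),
                 fold = stats::setNames(rep(NA_integer_, length(ids)), ids)),
            class = "dataset_manifest")
}

#' Assign stratified cross-validation folds
#'
#' Partitions a dataset into `k` folds such that each fold reproduces the
#' dataset's non-TF:TF ratio up to one protein per class: each class is
#' shuffled and split into folds of size `floor(n/k)`, with the remainder
#' distributed one protein each to seeded-randomly chosen folds.
#'
#' @param manifest A `dataset_manifest`.
#' @param k Number of folds (default 5); both classes must have at least `k`
#'   members.
#' @param seed Integer seed.
#' @return The manifest with its `fold` slot filled (fold indices
#'   `0:(k-1)`).
#' @export
stratified_folds <- function(manifest, k = 5L, seed = 1L) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  k <- as.integer(k)
  fold <- manifest$fold
  with_seed(derive_seed(seed, "folds", manifest$name), {
    for (cls in c(TRUE, FALSE)) {
      ids <- manifest$ids[manifest$labels[manifest$ids] == cls]
      n <- length(ids)
      if (n < k) stop("class with ", n, " members cannot fill ", k, " folds")
      ids <- sample(ids)
      sizes <- rep(n %/% k, k)
      r <- n %% k
      if (r > 0L) {
        bump <- sample(k, r)
        sizes[bump] <- sizes[bump] + 1L
      }
      fold[ids] <- rep(0:(k - 1L), times = sizes)
    }
  })
  manifest$fold <- fold
  manifest$k <- k
  manifest
}

#' Materialize one train/validation/test combination
#'
#' The chosen fold (20% of the dataset at k = 5) becomes the independent
#' test set; the remaining folds are split, stratified by class, into
#' training and validation data in proportion 9:1, i.e. 72% and 8% of the
#' complete dataset.
#'
#' @param manifest A fold-assigned `dataset_manifest`.
#' @param test_fold Fold index to hold out (in `0:(k-1)`).
#' @param seed Integer seed for the train/validation subdivision.
#' @return A `split_combination`: list with `test_fold`, `train_ids`,
#'   `val_ids`, `test_ids`.
#' @export
make_split <- function(manifest, test_fold, seed = 1L) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  if (anyNA(manifest$fold)) stop("manifest has no fold assignment")
  k <- manifest$k %||% (max(manifest$fold) + 1L)
  test_fold <- as.integer(test_fold)
  if (test_fold < 0L || test_fold >= k) {
    stop("test_fold must be in 0:", k - 1L)
  }
  test_ids <- manifest$ids[manifest$fold[manifest$ids] == test_fold]
  rest <- manifest$ids[manifest$fold[manifest$ids] != test_fold]
  train_ids <- character(0); val_ids <- character(0)
  with_seed(derive_seed(seed, "split", manifest$name, test_fold), {
    for (cls in c(TRUE, FALSE)) {
      ids <- sample(rest[manifest$labels[rest] == cls])
      n_val <- round(length(ids) / 10)
      val_ids <- c(val_ids, ids[seq_len(n_val)])
      train_ids <- c(train_ids, ids[seq.int(n_val + 1L,
                                            length.out = length(ids) - n_val)])
    }
  })
  structure(list(test_fold = test_fold, train_ids = train_ids,
                 val_ids = val_ids, test_ids = test_ids),
            class = "split_combination")
}

#' Serialize a dataset manifest
#'
#' Writes `<prefix>.json` (name, ratio, seed, class counts, fold sizes) and
#' `<prefix>.tsv` (protein_id, tf_label, fold). Identical manifests always
#' produce byte-identical files.
#'
#' @param manifest A `dataset_manifest`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_manifest <- function(manifest, prefix) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  ids <- manifest$ids
  tsv <- file.path(paste0(prefix, ".tsv"))
  json <- file.path(paste0(prefix, ".json"))
  df <- data.frame(protein_id = ids,
                   tf_label = as.integer(manifest$labels[ids]),
                   fold = manifest$fold[ids])
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  hdr <- list(name = manifest$name, s = manifest$s, seed = manifest$seed,
              n_tf = sum(manifest$labels), n_nontf = sum(!manifest$labels),
              k = manifest$k %||% NA,
              fold_sizes = if (!anyNA(manifest$fold))
                as.vector(table(manifest$fold)) else NULL)
  jsonlite::write_json(hdr, json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(json = json, tsv = tsv))
}

#' Read back a serialized dataset manifest
#'
#' @param prefix Path prefix used in [write_manifest()].
#' @return A `dataset_manifest`.
#' @export
read_manifest <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  df <- utils::read.delim(paste0(prefix, ".tsv"), stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer"))
  structure(list(name = hdr$name, ids = df$protein_id,
                 labels = stats::setNames(df$tf_label == 1L, df$protein_id),
                 s = hdr$s, seed = hdr$seed,
                 fold = stats::setNames(df$fold, df$protein_id),
                 k = if (is.null(hdr$k) || is.na(hdr$k)) NULL else hdr$k),
            class = "dataset_manifest")
}
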