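# The planted-motif cohort generator and its round trips through the
# pipeline's parsers.

small_cohort <- function(seed = 1L, ...) {
  synthetic_cohort(n_tf = 5L, n_nontf = 10L, min_length = 30L,
                   max_length = 60L, seed = seed, ...)
}

test_that("cohort composition follows the specification", {
  gen <- generate_cohort(small_cohort(seed = 91L), motif_spec())
  labs <- vapply(gen$records, `[[`, NA, "tf_label")
  expect_identical(sum(labs), 5L)
  expect_identical(sum(!labs), 10L)
  lens <- nchar(vapply(gen$records, `[[`, "", "sequence"))
  expect_true(all(lens >= 30L & lens <= 60L))
  empty <- generate_cohort(synthetic_cohort(n_tf = 0L, n_nontf = 4L,
                                            min_length = 30L,
                                            max_length = 40L, seed = 1L),
                           motif_spec())
  expect_false(any(vapply(empty$records, `[[`, NA, "tf_label")))
  expect_error(generate_cohort(synthetic_cohort(min_length = 5L,
                                                max_length = 10L),
                               motif_spec()),
               "motif longer")
})

test_that("every TF's DBD interval is the motif's position; SSGs differ by class", {
  mt <- motif_spec()
  gen <- generate_cohort(small_cohort(seed = 92L), mt)
  mlen <- nchar(mt$aa_motif)
  for (r in gen$records) {
    hit <- regexpr(mt$aa_motif, r$sequence, fixed = TRUE)[1L]
    if (r$tf_label) {
      expect_identical(nrow(r$dbd_intervals), 1L)
      expect_identical(hit, r$dbd_intervals[1L, "start"][[1L]])
      expect_identical(r$dbd_intervals[1L, "end"][[1L]] -
                         r$dbd_intervals[1L, "start"][[1L]] + 1L, mlen)
      ssg_at <- substr(r$ssg, hit, hit + mlen - 1L)
      expect_identical(ssg_at, mt$ssg_motif)        # alpha rendering
    } else if (hit > 0L) {
      ssg_at <- substr(r$ssg, hit, hit + mlen - 1L)
      expect_identical(ssg_at, strrep("c", mlen))   # coil confound
      expect_identical(nrow(r$dbd_intervals), 0L)
    }
  }
  # confound fraction: half of the non-TFs carry the motif
  n_conf <- sum(vapply(gen$records, function(r)
    !r$tf_label && grepl(mt$aa_motif, r$sequence, fixed = TRUE), NA))
  expect_identical(n_conf, 5L)
})

test_that("generated GO annotations are consistent with the labeling rule", {
  gen <- generate_cohort(small_cohort(seed = 93L), motif_spec())
  cfg <- synthetic_go_config()
  for (r in gen$records) {
    expect_identical(label_tf(r$go_terms, cfg), r$tf_label)
  }
})

test_that("identical seeds write byte-identical fixture directories", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(small_cohort(seed = 94L), motif_spec(), dir = d1)
  generate_cohort(small_cohort(seed = 94L), motif_spec(), dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("pLDDT generation drives the reliability filter by construction", {
  set.seed(95)
  rel <- vapply(1:50, function(i)
    is_reliable(generate_plddt(sample(50:200, 1L), reliable = TRUE)),
    NA)
  expect_true(all(rel))
  unrel <- vapply(1:50, function(i)
    is_reliable(generate_plddt(sample(50:200, 1L), reliable = FALSE)),
    NA)
  expect_false(any(unrel))
  expect_false(any(generate_plddt(500L, TRUE, seed = 9L) == 70))
  expect_identical(generate_plddt(80L, TRUE, seed = 5L),
                   generate_plddt(80L, TRUE, seed = 5L))
})

test_that("written fixtures round-trip through every parser", {
  dir <- withr::local_tempdir()
  gen <- generate_cohort(small_cohort(seed = 96L), motif_spec(), dir = dir)
  recs <- gen$records

  fasta <- Biostrings::readAAStringSet(gen$files["fasta"])
  expect_identical(unname(as.character(fasta)),
                   vapply(recs, `[[`, "", "sequence"))

  sidecar <- read_ss_sidecar(gen$files["sidecar"])
  for (r in recs) {
    expect_identical(sidecar[[r$protein_id]], r$dssp)
    dssp <- parse_dssp(file.path(dir, "dssp",
                                 paste0(r$protein_id, ".dssp")))
    expect_identical(dssp, r$dssp)
    expect_identical(dssp_to_ssg_string(dssp), r$ssg)
    pdb <- read_alphafold_pdb(file.path(dir, "pdb",
                                        paste0(r$protein_id, ".pdb")))
    expect_identical(pdb$sequence, r$sequence)
    expect_equal(pdb$confidences, r$confidences)
  }

  ann <- read_annotations(gen$files["annotations"], synthetic_go_config())
  expect_identical(vapply(ann, `[[`, NA, "tf_label"),
                   vapply(recs, `[[`, NA, "tf_label"))

  clusters <- read_cluster_tsv(gen$files["clusters"])
  expect_length(clusters, length(recs))   # singletons by default
})

test_that("redundant mode builds shared clusters that selection resolves", {
  gen <- generate_cohort(small_cohort(seed = 97L, redundant = TRUE),
                         motif_spec())
  sizes <- lengths(gen$clusters)
  expect_gt(sum(sizes > 1L), 0L)
  labels <- stats::setNames(vapply(gen$records, `[[`, NA, "tf_label"),
                            vapply(gen$records, `[[`, "", "protein_id"))
  sel <- select_representatives(gen$clusters, labels, seed = 97L)
  expect_length(sel, length(gen$clusters))
  for (i in seq_along(gen$clusters)) {
    members <- gen$clusters[[i]]
    if (any(labels[members])) expect_true(labels[[sel[i]]])
  }
})
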