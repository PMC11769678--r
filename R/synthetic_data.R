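# Synthetic-fixture generator: cohorts of proteins with a planted,
# secondary-structure-dependent TF signal, written out in every format the
# pipeline consumes (FASTA, classic DSSP files, AlphaFold-style PDBs with
# pLDDT in the B-factor column, annotation TSV, cluster TSV).
#
# The discriminative signal lives deliberately in the joint amino-acid x
# SSG channel: every TF carries the amino-acid motif rendered in alpha
# helix, while a configurable fraction of non-TFs carries the *same*
# amino-acid motif in coil conformation. A sequence-only model therefore
# faces an irreducible ambiguity on confounded non-TFs, while the
# structure-aware encoding can separate the classes completely - making
# the structure-vs-sequence comparison falsifiable at desk scale.

#' Planted motif specification
#'
#' @param aa_motif Amino-acid motif planted in every TF (default a fixed
#'   12-mer over standard residues).
#' @param ssg_motif SSG rendering of the motif in TFs, as an `a`/`b`/`c`
#'   string of the same length (default all alpha).
#' @param confound_fraction Fraction of non-TFs that carry `aa_motif` in
#'   coil conformation (default 0.5).
#' @return A `motif_spec` list.
#' @export
motif_spec <- function(aa_motif = "KRHWAVLYENQM",
                       ssg_motif = strrep("a", nchar(aa_motif)),
                       confound_fraction = 0.5) {
  stopifnot(nchar(aa_motif) == nchar(ssg_motif),
            confound_fraction >= 0, confound_fraction <= 1)
  if (!all(str_chars(aa_motif) %in% setdiff(residue_alphabet(), "X"))) {
    stop("aa_motif must use the 20 standard residues")
  }
  ssg_index(str_chars(ssg_motif))  # validates letters
  structure(list(aa_motif = aa_motif, ssg_motif = ssg_motif,
                 confound_fraction = confound_fraction),
            class = "motif_spec")
}

#' Synthetic cohort specification
#'
#' Study conditions of the desk-scale cohort: class sizes, protein length
#' range, background composition and structure-confidence behaviour.
#'
#' @param n_tf Number of TFs (default 150).
#' @param n_nontf Number of non-TFs (default 450, i.e. class ratio 3).
#' @param min_length,max_length Protein length range (default 80-300).
#' @param mean_segment Mean secondary-structure segment length of the
#'   background (geometric run lengths, default 6 residues).
#' @param reliable If `TRUE` (default) generated pLDDT profiles pass the
#'   reliability filter by construction; if `FALSE` they all fail it.
#' @param redundant If `TRUE`, a fraction of proteins receive mutated
#'   duplicates sharing their sequence cluster (exercises representative
#'   selection); default `FALSE` (every protein a singleton cluster).
#' @param seed Master seed; cohorts are byte-reproducible from it.
#' @return A `synthetic_cohort` list.
#' @export
synthetic_cohort <- function(n_tf = 150L, n_nontf = 450L,
                             min_length = 80L, max_length = 300L,
                             mean_segment = 6, reliable = TRUE,
                             redundant = FALSE, seed = 1L) {
  stopifnot(n_tf >= 0L, n_nontf >= 0L, min_length >= 1L,
            max_length >= min_length, mean_segment >= 1)
  structure(list(n_tf = as.integer(n_tf), n_nontf = as.integer(n_nontf),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 mean_segment = mean_segment, reliable = reliable,
                 redundant = redundant, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' Generate a per-residue pLDDT profile
#'
#' Reliable profiles place exactly `floor(0.02 n)` residues (at most 2%,
#' comfortably below the 10% allowance) in a low-confidence band drawn
#' from U(35, 60) and the remainder in U(75, 98), so [is_reliable()] is
#' `TRUE` by construction. Unreliable profiles put `ceiling(0.2 n)`
#' residues (20%) in the low band, so the filter rejects them. No score
#' ever equals the 70 threshold exactly, keeping boundary behaviour out of
#' stochastic fixtures.
#'
#' @param n_residues Number of residues.
#' @param reliable Logical.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Numeric vector of length `n_residues`.
#' @export
generate_plddt <- function(n_residues, reliable = TRUE, seed = NULL) {
  stopifnot(n_residues >= 1L)
  gen <- function() {
    n_low <- if (reliable) floor(0.02 * n_residues) else
      ceiling(0.2 * n_residues)
    scores <- stats::runif(n_residues, 75, 98)
    if (n_low > 0L) {
      low_at <- sample(n_residues, n_low)
      scores[low_at] <- stats::runif(n_low, 35, 60)
    }
    round(scores, 2)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Background SSG string: alternating segments with geometric run lengths
# (mean `mean_segment`), successive segments never repeating a state --
# mimics secondary-structure run statistics without any sequence coupling.
random_ssg_string <- function(len, mean_segment) {
  out <- character(0)
  prev <- 0L
  while (length(out) < len) {
    state <- sample(setdiff(1:3, prev), 1L)
    run <- stats::rgeom(1L, 1 / mean_segment) + 1L
    out <- c(out, rep(ssg_letters()[state], run))
    prev <- state
  }
  paste(out[seq_len(len)], collapse = "")
}

# Render a 3-letter SSG string as an 8-state DSSP string (chooses among the
# DSSP categories of each group so the full mapping table is exercised);
# collapses back to the same SSG string by construction.
ssg_to_dssp_string <- function(ssg_string) {
  idx <- ssg_index(str_chars(ssg_string))
  out <- character(length(idx))
  n_a <- sum(idx == 1L); n_b <- sum(idx == 2L); n_c <- sum(idx == 3L)
  if (n_a) out[idx == 1L] <- sample(c("H", "G", "I"), n_a, replace = TRUE,
                                    prob = c(0.8, 0.15, 0.05))
  if (n_b) out[idx == 2L] <- sample(c("E", "B"), n_b, replace = TRUE,
                                    prob = c(0.9, 0.1))
  if (n_c) out[idx == 3L] <- sample(c("T", "S", " "), n_c, replace = TRUE,
                                    prob = c(0.4, 0.3, 0.3))
  paste(out, collapse = "")
}

#' Generate a synthetic protein cohort
#'
#' Draws `n_tf` TFs and `n_nontf` non-TFs with uniform background residue
#' composition and segmented background secondary structure. Every TF
#' carries the amino-acid motif rendered with the motif SSG at a uniformly
#' random offset, recorded as its DBD interval; a `confound_fraction` of
#' non-TFs carries the same amino-acid motif in coil conformation; the
#' remaining non-TFs contain no motif occurrence. GO annotations are
#' assigned consistently with the TF labeling rule (TFs via a direct TF
#' term or via regulation + DNA-binding combination; non-TFs never receive
#' a label-triggering combination).
#'
#' With `dir` set, the cohort is written out as a self-contained fixture
#' directory: `proteins.fasta`, `dssp/<id>.dssp`, `pdb/<id>.pdb`,
#' `ss_sidecar.tsv`, `annotations.tsv`, `clusters.tsv` and
#' `manifest.json`. Identical seeds give byte-identical files.
#'
#' @param cohort A [synthetic_cohort()].
#' @param motif A [motif_spec()].
#' @param dir Optional output directory.
#' @return List with `records` (one list per protein: `protein_id`,
#'   `sequence`, `ssg`, `dssp`, `confidences`, `tf_label`, `go_terms`,
#'   `dbd_intervals`), `clusters` (a `cluster_table`) and `files` (named
#'   paths, or `NULL`).
#' @export
generate_cohort <- function(cohort = synthetic_cohort(),
                            motif = motif_spec(), dir = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(motif, "motif_spec"))
  mlen <- nchar(motif$aa_motif)
  if (mlen >= cohort$min_length) {
    stop("motif longer than the minimum protein length")
  }
  standard <- setdiff(residue_alphabet(), "X")
  go <- synthetic_go_config()
  inert_terms <- c("GO:0008150", "GO:0005737", "GO:0016020", "GO:0005524")

  records <- with_seed(derive_seed(cohort$seed, "cohort"), {
    n_total <- cohort$n_tf + cohort$n_nontf
    is_tf <- rep(c(TRUE, FALSE), c(cohort$n_tf, cohort$n_nontf))
    n_conf <- round(motif$confound_fraction * cohort$n_nontf)
    confounded <- rep(FALSE, n_total)
    if (cohort$n_nontf > 0L && n_conf > 0L) {
      confounded[cohort$n_tf + sample(cohort$n_nontf, n_conf)] <- TRUE
    }
    lapply(seq_len(n_total), function(i) {
      id <- if (is_tf[i]) sprintf("TF%04d", i) else
        sprintf("NT%04d", i - cohort$n_tf)
      repeat {
        len <- sample(cohort$min_length:cohort$max_length, 1L)
        seq_chars <- sample(standard, len, replace = TRUE)
        ssg <- random_ssg_string(len, cohort$mean_segment)
        dbd <- matrix(integer(0), ncol = 2L,
                      dimnames = list(NULL, c("start", "end")))
        if (is_tf[i] || confounded[i]) {
          offset <- sample(len - mlen + 1L, 1L)
          seq_chars[offset:(offset + mlen - 1L)] <- str_chars(motif$aa_motif)
          planted_ssg <- if (is_tf[i]) motif$ssg_motif else strrep("c", mlen)
          ssg_chars <- str_chars(ssg)
          ssg_chars[offset:(offset + mlen - 1L)] <- str_chars(planted_ssg)
          ssg <- paste(ssg_chars, collapse = "")
          if (is_tf[i]) dbd <- matrix(c(offset, offset + mlen - 1L),
                                      ncol = 2L,
                                      dimnames = list(NULL,
                                                      c("start", "end")))
          seqstr <- paste(seq_chars, collapse = "")
          # reject accidental second/earlier motif occurrence
          hits <- gregexpr(motif$aa_motif, seqstr, fixed = TRUE)[[1L]]
          if (length(hits) == 1L && hits[1L] == offset) break
        } else {
          seqstr <- paste(seq_chars, collapse = "")
          if (!grepl(motif$aa_motif, seqstr, fixed = TRUE)) break
        }
      }
      go_terms <- if (is_tf[i]) {
        if (stats::runif(1L) < 0.7) {
          sample(go$tf_terms, 1L)
        } else {
          c(sample(go$regulation_terms, 1L), sample(go$dna_binding_terms, 1L))
        }
      } else {
        # never a TF term nor a regulation+DNA-binding combination
        base <- sample(inert_terms, sample(0:2, 1L))
        if (stats::runif(1L) < 0.3) {
          c(base, sample(c(go$regulation_terms, go$dna_binding_terms), 1L))
        } else base
      }
      list(protein_id = id, sequence = seqstr, ssg = ssg,
           dssp = ssg_to_dssp_string(ssg),
           confidences = generate_plddt(len, cohort$reliable),
           tf_label = is_tf[i], go_terms = go_terms, dbd_intervals = dbd)
    })
  })

  # cluster structure: singletons, plus mutated duplicates in redundant mode
  clusters <- lapply(records, function(r) r$protein_id)
  names(clusters) <- vapply(records, `[[`, "", "protein_id")
  if (cohort$redundant) {
    extra <- with_seed(derive_seed(cohort$seed, "redundant"), {
      picked <- seq_along(records)[stats::runif(length(records)) < 0.2]
      lapply(picked, function(i) {
        r <- records[[i]]
        chars <- str_chars(r$sequence)
        n_mut <- max(1L, round(0.05 * length(chars)))
        at <- sample(length(chars), n_mut)
        chars[at] <- sample(standard, n_mut, replace = TRUE)
        dup <- r
        dup$protein_id <- paste0(r$protein_id, "_d1")
        dup$sequence <- paste(chars, collapse = "")
        dup
      })
    })
    for (dup in extra) {
      parent <- sub("_d1$", "", dup$protein_id)
      clusters[[parent]] <- c(clusters[[parent]], dup$protein_id)
    }
    records <- c(records, extra)
  }
  class(clusters) <- "cluster_table"

  files <- NULL
  if (!is.null(dir)) {
    files <- write_cohort_files(records, clusters, cohort, motif, dir)
  }
  list(records = records, clusters = clusters, files = files,
       cohort = cohort, motif = motif)
}

# Write every fixture format of a generated cohort into `dir`.
write_cohort_files <- function(records, clusters, cohort, motif, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "dssp"), showWarnings = FALSE)
  dir.create(file.path(dir, "pdb"), showWarnings = FALSE)
  ids <- vapply(records, `[[`, "", "protein_id")
  seqs <- vapply(records, `[[`, "", "sequence")

  fasta <- file.path(dir, "proteins.fasta")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(seqs, ids)), filepath = fasta)

  for (r in records) {
    write_dssp_file(file.path(dir, "dssp", paste0(r$protein_id, ".dssp")),
                    r$sequence, r$dssp)
    write_alphafold_pdb(file.path(dir, "pdb", paste0(r$protein_id, ".pdb")),
                        r$sequence, r$confidences)
  }

  sidecar <- file.path(dir, "ss_sidecar.tsv")
  writeLines(paste0(ids, "\t", vapply(records, `[[`, "", "dssp")), sidecar)

  ann <- file.path(dir, "annotations.tsv")
  ann_df <- data.frame(
    protein_id = ids,
    go_terms = vapply(records, function(r)
      paste(r$go_terms, collapse = ";"), ""),
    dbd = vapply(records, function(r) {
      if (nrow(r$dbd_intervals) == 0L) "" else
        paste(sprintf("%d-%d", r$dbd_intervals[, 1L],
                      r$dbd_intervals[, 2L]), collapse = ";")
    }, ""))
  utils::write.table(ann_df, ann, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  clu <- file.path(dir, "clusters.tsv")
  lines <- unlist(lapply(names(clusters), function(rep_id)
    paste0(rep_id, "\t", clusters[[rep_id]])))
  writeLines(lines, clu)

  man <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(n_tf = cohort$n_tf, n_nontf = cohort$n_nontf,
         min_length = cohort$min_length, max_length = cohort$max_length,
         reliable = cohort$reliable, redundant = cohort$redundant,
         seed = cohort$seed, aa_motif = motif$aa_motif,
         ssg_motif = motif$ssg_motif,
         confound_fraction = motif$confound_fraction,
         protein_ids = ids),
    man, auto_unbox = TRUE, pretty = TRUE, digits = NA)

  c(fasta = fasta, sidecar = sidecar, annotations = ann, clusters = clu,
    manifest = man, dssp_dir = file.path(dir, "dssp"),
    pdb_dir = file.path(dir, "pdb"))
}

#' Encode a cohort into a model input array
#'
#' Stacks the per-protein one-hot matrices of a record list into the
#' (`pad_length`, cols, n) array consumed by [train_model()] and
#' [predict_scores()].
#'
#' @param records Record list from [generate_cohort()] (or any list with
#'   `sequence`, `ssg`, `tf_label`, `protein_id`).
#' @param mode `"structure"` (63 columns) or `"sequence"` (21 columns).
#' @param pad_length Padded length; must be at least the longest protein.
#' @return List with `X` (array), `ids`, `labels` (named logical).
#' @export
encode_records <- function(records, mode = c("structure", "sequence"),
                           pad_length = 1000L) {
  mode <- match.arg(mode)
  n <- length(records)
  cols <- if (mode == "structure") 63L else 21L
  X <- array(0, dim = c(pad_length, cols, n))
  for (i in seq_len(n)) {
    r <- records[[i]]
    X[, , i] <- if (mode == "structure") {
      encode_structure(r$sequence, r$ssg, pad_length)
    } else {
      encode_sequence(r$sequence, pad_length)
    }
  }
  ids <- vapply(records, `[[`, "", "protein_id")
  list(X = X, ids = ids,
       labels = stats::setNames(
         vapply(records, `[[`, NA, "tf_label"), ids))
}
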