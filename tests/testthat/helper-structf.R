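# Shared helpers: small model/training configurations and fixture builders
# used across the test files. Everything is generated in code; no stored
# fixtures.

# A model small enough for sub-second builds and forwards in unit tests.
tiny_model_config <- function(input_cols = 21L, pad_length = 40L,
                              channels = 4L, seed = 1L, dropout = 0.1) {
  model_config(input_cols = input_cols, pad_length = pad_length,
               channels = channels, fc_hidden = 8L, dropout = dropout,
               tail_kernel = 2L, seed = seed)
}

# Random admissible protein sequence over the 20 standard residues.
random_sequence <- function(len) {
  paste(sample(setdiff(residue_alphabet(), "X"), len, replace = TRUE),
        collapse = "")
}

# Random SSG string in a/b/c letters.
random_ssg <- function(len) {
  paste(sample(c("a", "b", "c"), len, replace = TRUE), collapse = "")
}

# A toy linearly separable encoding task: class 1 proteins are all-alanine
# alpha helices, class 0 all-glycine coils, plus a touch of noise in length.
toy_task <- function(n_per_class = 12L, pad_length = 40L, seed = 1L) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    records <- c(
      lapply(seq_len(n_per_class), function(i) {
        len <- sample(20:35, 1L)
        list(protein_id = sprintf("P%03d", i),
             sequence = strrep("A", len), ssg = strrep("a", len),
             tf_label = TRUE)
      }),
      lapply(seq_len(n_per_class), function(i) {
        len <- sample(20:35, 1L)
        list(protein_id = sprintf("N%03d", i),
             sequence = strrep("G", len), ssg = strrep("c", len),
             tf_label = FALSE)
      }))
    enc <- encode_records(records, "sequence", pad_length = pad_length)
    idx <- sample(length(records))
    list(X = enc$X, y = as.numeric(enc$labels),
         train_idx = idx[seq_len(length(idx) - 6L)],
         val_idx = idx[seq.int(length(idx) - 5L, length(idx))])
  })
}
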