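# Joint amino-acid x secondary-structure one-hot encoding.
#
# A protein of length l is represented as a zero-padded `pad_length` x 63
# binary matrix: the 21-letter residue alphabet (20 standard amino acids plus
# the wildcard X) crossed with three secondary-structure groups (SSGs) that
# collapse the eight classic DSSP categories. A 21-column sequence-only
# encoding serves the sequence-based comparator model.

#' The three secondary-structure groups
#'
#' The eight per-residue DSSP categories are collapsed into three disjoint
#' secondary-structure groups (SSGs): `alpha` (alpha-helix), `beta`
#' (beta-sheet) and `coil` (coil-turn). The ordering `alpha < beta < coil` is
#' fixed and determines column order in the joint encoding.
#'
#' @return Character vector `c("alpha", "beta", "coil")`.
#' @export
#' @examples
#' ssg_levels()
ssg_levels <- function() c("alpha", "beta", "coil")

#' The 21-letter residue alphabet
#'
#' The 20 standard one-letter amino-acid codes plus the wildcard `X` (used for
#' any non-standard residue), sorted alphabetically; `X` therefore falls
#' between `W` and `Y`. Column order of every encoded matrix derives from this
#' vector, so it is the single point of truth for residue ordering.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' residue_alphabet()
residue_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
    "N", "P", "Q", "R", "S", "T", "V", "W", "X", "Y")
}

# Short SSG letters used in per-residue SSG strings: a = alpha, b = beta,
# c = coil.
ssg_letters <- function() c("a", "b", "c")

#' Map a DSSP category to its secondary-structure group
#'
#' Total mapping from single-character DSSP categories to the three SSGs:
#' `H`, `G`, `I` (alpha-, 3-10- and pi-helix) map to `alpha`; `B`, `E`
#' (isolated beta-bridge, extended strand) map to `beta`; `T`, `S` and the
#' blank placeholder (undetermined) map to `coil`. Any other character (e.g.
#' the `P` polyproline code emitted by newer DSSP versions) also maps to
#' `coil`, mirroring the treatment of the undetermined blank.
#'
#' @param code Character vector of single characters.
#' @return Character vector of SSG names (`"alpha"`, `"beta"`, `"coil"`).
#' @export
#' @examples
#' map_dssp_to_ssg(c("H", "E", " ", "P"))
map_dssp_to_ssg <- function(code) {
  stopifnot(is.character(code))
  if (any(nchar(code) > 1L)) stop("DSSP codes must be single characters")
  out <- rep("coil", length(code))
  out[code %in% c("H", "G", "I")] <- "alpha"
  out[code %in% c("B", "E")] <- "beta"
  out
}

#' Collapse an 8-state DSSP string to a 3-letter SSG string
#'
#' @param dssp_string Per-residue DSSP category string (one character per
#'   residue; blanks allowed).
#' @return String over `a`/`b`/`c` of the same length.
#' @export
#' @examples
#' dssp_to_ssg_string("HHTE ")
dssp_to_ssg_string <- function(dssp_string) {
  stopifnot(is.character(dssp_string), length(dssp_string) == 1L)
  if (nchar(dssp_string) == 0L) return("")
  grp <- map_dssp_to_ssg(str_chars(dssp_string))
  paste(ssg_letters()[match(grp, ssg_levels())], collapse = "")
}

# Normalize an SSG spec (full names or single letters) to integer indices 1:3.
ssg_index <- function(ssg) {
  idx <- match(ssg, ssg_levels())
  idx[is.na(idx)] <- match(ssg[is.na(idx)], ssg_letters())
  if (anyNA(idx)) stop("unknown SSG value(s): ",
                       paste(unique(ssg[is.na(idx)]), collapse = ", "))
  idx
}

#' Column of an (amino acid, SSG) pair in the joint encoding
#'
#' The 63 residue-by-SSG pairs are ordered lexicographically: first by the
#' alphabetical residue alphabet, then (within a residue) alpha, beta, coil.
#' Columns are 1-based, so `("A", "alpha")` is column 1 and `("Y", "coil")` is
#' column 63.
#'
#' @param aa One-letter residue code(s); must be in [residue_alphabet()]
#'   (substitute non-standard residues with `"X"` first).
#' @param ssg SSG name(s) (`"alpha"`, `"beta"`, `"coil"`) or letter(s)
#'   (`"a"`, `"b"`, `"c"`).
#' @return Integer column index in `[1, 63]`.
#' @export
#' @examples
#' column_index("A", "alpha")  # 1
#' column_index("Y", "coil")   # 63
column_index <- function(aa, ssg) {
  ai <- match(aa, residue_alphabet())
  if (anyNA(ai)) stop("residue(s) not in the 21-letter alphabet: ",
                      paste(unique(aa[is.na(ai)]), collapse = ", "))
  3L * (ai - 1L) + ssg_index(ssg)
}

# Replace residues outside the 21-letter alphabet by the wildcard X.
# Eligibility filtering upstream should already have removed such proteins;
# this is a defensive fallback and warns when it fires.
substitute_wildcard <- function(chars) {
  bad <- !(chars %in% residue_alphabet())
  if (any(bad)) {
    warning(sum(bad), " non-standard residue(s) replaced by wildcard X")
    chars[bad] <- "X"
  }
  chars
}

#' One-hot encode a protein jointly over residues and secondary structure
#'
#' Builds the `pad_length` x 63 binary matrix in which row i carries a single
#' 1 at the column of the (residue, SSG) pair at position i; rows beyond the
#' protein length are all-zero padding (the sequence is left-aligned).
#'
#' @param sequence Residue string (one-letter codes).
#' @param ssg_string Per-residue SSG string of the same length, using letters
#'   `a`/`b`/`c` (see [dssp_to_ssg_string()]) or an 8-state DSSP string if
#'   `from_dssp = TRUE`.
#' @param pad_length Number of rows of the padded matrix (default 1000, the
#'   eligibility bound on protein length).
#' @param from_dssp If `TRUE`, `ssg_string` is an 8-state DSSP string and is
#'   collapsed first.
#' @return Binary matrix with attribute `true_length` = protein length.
#' @export
#' @examples
#' m <- encode_structure("AC", "ab")
#' which(m[1, ] == 1)  # column 1: (A, alpha)
encode_structure <- function(sequence, ssg_string, pad_length = 1000L,
                             from_dssp = FALSE) {
  stopifnot(length(sequence) == 1L, length(ssg_string) == 1L)
  if (from_dssp) ssg_string <- dssp_to_ssg_string(ssg_string)
  l <- nchar(sequence)
  if (nchar(ssg_string) != l) {
    stop("sequence and SSG string lengths differ (", l, " vs ",
         nchar(ssg_string), ")")
  }
  if (l > pad_length) stop("sequence longer than pad length (", l, " > ",
                           pad_length, ")")
  m <- matrix(0, nrow = pad_length, ncol = 63L)
  if (l > 0L) {
    chars <- substitute_wildcard(str_chars(sequence))
    cols <- column_index(chars, str_chars(ssg_string))
    m[cbind(seq_len(l), cols)] <- 1
  }
  structure(m, true_length = l)
}

#' One-hot encode a protein sequence only
#'
#' The 21-column analogue of [encode_structure()] used by the sequence-only
#' comparator model: row i carries a single 1 at the alphabet index of the
#' residue at position i.
#'
#' @inheritParams encode_structure
#' @return Binary `pad_length` x 21 matrix with attribute `true_length`.
#' @export
encode_sequence <- function(sequence, pad_length = 1000L) {
  stopifnot(length(sequence) == 1L)
  l <- nchar(sequence)
  if (l > pad_length) stop("sequence longer than pad length (", l, " > ",
                           pad_length, ")")
  m <- matrix(0, nrow = pad_length, ncol = 21L)
  if (l > 0L) {
    chars <- substitute_wildcard(str_chars(sequence))
    m[cbind(seq_len(l), match(chars, residue_alphabet()))] <- 1
  }
  structure(m, true_length = l)
}

#' Collapse a 63-column structure matrix to the 21-column sequence matrix
#'
#' Sums the three SSG columns of each residue, so
#' `marginalize(encode_structure(x, s))` equals `encode_sequence(x)` for every
#' protein. Used as a consistency bridge between the two encodings.
#'
#' @param m A 63-column encoded matrix.
#' @return The corresponding 21-column matrix (row sums preserved).
#' @export
marginalize <- function(m) {
  if (ncol(m) != 63L) stop("expected a 63-column structure matrix, got ",
                           ncol(m), " columns")
  out <- m[, seq(1L, 63L, by = 3L), drop = FALSE] +
    m[, seq(2L, 63L, by = 3L), drop = FALSE] +
    m[, seq(3L, 63L, by = 3L), drop = FALSE]
  attr(out, "true_length") <- attr(m, "true_length")
  out
}
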