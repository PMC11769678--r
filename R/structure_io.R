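# Parsing AlphaFold-style PDB files and classic DSSP output, plus the two
# dataset-entry filters: sequence eligibility and structure reliability.

# 3-letter -> 1-letter residue codes; anything else becomes the wildcard X.
aa3to1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y"
)

aa1to3 <- function(aa) {
  rev_map <- stats::setNames(names(aa3to1), unname(aa3to1))
  out <- rev_map[aa]
  out[is.na(out)] <- "UNK"
  unname(out)
}

#' Read an AlphaFold-style PDB file
#'
#' Parses a PDB file whose B-factor column stores the per-residue model
#' confidence (pLDDT in AlphaFold files, replicated across all atoms of a
#' residue). The confidence is taken from each residue's CA atom and the
#' sequence from the residue names; only the first chain is used (with a
#' warning if others are present), and only the first alternate location.
#'
#' @param path Path to a PDB file with ATOM records.
#' @return A `structure_record`: list with `protein_id` (file stem),
#'   `sequence`, `confidences` (numeric, one per residue) and `dssp_string`
#'   (empty; fill via [parse_dssp()]).
#' @export
read_alphafold_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records in ", path)
  chains <- unique(atoms$chain)
  if (length(chains) > 1L) {
    warning("multiple chains in ", basename(path), "; using first chain '",
            chains[1L], "'")
  }
  atoms <- atoms[atoms$chain == chains[1L], , drop = FALSE]
  alt <- atoms$alt
  atoms <- atoms[is.na(alt) | alt %in% c("", "A"), , drop = FALSE]
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atoms in first chain of ", path)
  n_res <- length(unique(atoms$resno))
  if (nrow(ca) < n_res) {
    stop("residue(s) without a CA atom in ", basename(path))
  }
  ca <- ca[order(ca$resno), , drop = FALSE]
  seq1 <- unname(aa3to1[ca$resid])
  seq1[is.na(seq1)] <- "X"
  list(
    protein_id = tools::file_path_sans_ext(basename(path)),
    sequence = paste(seq1, collapse = ""),
    confidences = as.numeric(ca$b),
    dssp_string = ""
  )
}

#' Parse classic DSSP text output
#'
#' Reads the fixed-column per-residue table of a classic (non-mmCIF) DSSP
#' file and returns the secondary-structure summary column as a string, one
#' character per residue. Undetermined residues keep the blank `' '` category
#' (later collapsed to coil-turn); chain-break records (`!` in the amino-acid
#' column) are skipped.
#'
#' @param path Path to a classic DSSP output file.
#' @return Single string of 8-state DSSP categories.
#' @export
parse_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) stop("DSSP residue-table header not found in ", path)
  body <- lines[seq.int(hdr[1L] + 1L, length.out = length(lines) - hdr[1L])]
  if (length(body) == 0L) return("")
  aa <- substr(body, 14L, 14L)
  keep <- aa != "!" & nzchar(trimws(substr(body, 1L, 10L)))
  body <- body[keep]
  ss <- substr(body, 17L, 17L)
  ss[ss == ""] <- " "
  paste(ss, collapse = "")
}

#' Read a per-protein secondary-structure sidecar table
#'
#' Plain-text alternative to per-protein DSSP files: a TSV with one line per
#' protein, `<protein_id>\t<8-state DSSP string>`.
#'
#' @param path Path to the sidecar TSV.
#' @return Named character vector of DSSP strings keyed by protein id.
#' @export
read_ss_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("sidecar lines must be <id>\\t<ss>")
  stats::setNames(vapply(parts, `[[`, "", 2L), vapply(parts, `[[`, "", 1L))
}

#' Sequence eligibility filter
#'
#' A protein enters the study only if it has at most 1000 residues and
#' contains exclusively the 20 standard amino acids (no wildcard, no
#' extended codes such as B, U, Z).
#'
#' @param sequence Residue string(s).
#' @param max_length Maximum admissible protein length (default 1000).
#' @return Logical vector.
#' @export
#' @examples
#' is_eligible(c("ACDEFG", "ACB"))  # TRUE, FALSE
is_eligible <- function(sequence, max_length = 1000L) {
  standard <- setdiff(residue_alphabet(), "X")
  vapply(sequence, function(s) {
    l <- nchar(s)
    if (l == 0L || l > max_length) return(FALSE)
    all(str_chars(s) %in% standard)
  }, logical(1L), USE.NAMES = FALSE)
}

#' Structure reliability filter
#'
#' A predicted structure is `reliable' when at least `min_fraction` of its
#' residues have confidence at least `min_score` (both comparisons
#' inclusive); the study default is >= 90% of residues at pLDDT >= 70.
#'
#' @param confidences Numeric vector of per-residue confidence scores
#'   (0-100).
#' @param min_fraction Minimum fraction of residues that must pass (default
#'   0.9).
#' @param min_score Minimum per-residue confidence (default 70).
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' is_reliable(c(rep(70, 90), rep(0, 10)))  # TRUE: exactly 90% at >= 70
is_reliable <- function(confidences, min_fraction = 0.9, min_score = 70) {
  if (length(confidences) == 0L) stop("empty confidence vector")
  mean(confidences >= min_score) >= min_fraction
}

#' Write an AlphaFold-style PDB file
#'
#' Emits minimal backbone (N, CA, C) ATOM records with the per-residue
#' confidence in the B-factor column of every atom, the layout used by
#' AlphaFold database files. Coordinates are placeholders on an extended
#' backbone; only sequence and confidence carry information. Used by the
#' synthetic-cohort generator and as the round-trip oracle for
#' [read_alphafold_pdb()].
#'
#' @param path Output path.
#' @param sequence Residue string.
#' @param confidences Numeric vector, one score per residue.
#' @param chain Chain identifier (default `"A"`).
#' @export
write_alphafold_pdb <- function(path, sequence, confidences, chain = "A") {
  l <- nchar(sequence)
  stopifnot(length(confidences) == l)
  res3 <- aa1to3(str_chars(sequence))
  lines <- character(3L * l + 1L)
  serial <- 0L
  for (i in seq_len(l)) {
    for (atom in c("N", "CA", "C")) {
      serial <- serial + 1L
      lines[serial] <- sprintf(
        "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, atom, " ", res3[i], chain, i,
        3.8 * i + match(atom, c("N", "CA", "C")), 0, 0,
        1.00, confidences[i], substr(atom, 1L, 1L))
    }
  }
  lines[3L * l + 1L] <- "END"
  writeLines(lines, path)
  invisible(path)
}

#' Write a classic DSSP-format file
#'
#' Produces the fixed-column residue table of classic DSSP output (header
#' plus one line per residue with the amino acid in column 14 and the
#' 8-state category in column 17). Fixture writer and round-trip oracle for
#' [parse_dssp()].
#'
#' @param path Output path.
#' @param sequence Residue string.
#' @param dssp_string 8-state category string of the same length (blanks
#'   allowed).
#' @export
write_dssp_file <- function(path, sequence, dssp_string) {
  l <- nchar(sequence)
  stopifnot(nchar(dssp_string) == l)
  aa <- str_chars(sequence)
  ss <- if (l > 0L) str_chars(dssp_string) else character(0)
  header <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "REFERENCE SYNTHETIC FIXTURE",
    sprintf("%5d  1  0  0  0 TOTAL NUMBER OF RESIDUES, ...", l),
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N"
  )
  body <- sprintf("%5d%5d A %1s  %1s  %s", seq_len(l), seq_len(l), aa, ss,
                  "0   0    0")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Shell out to a locally installed mkdssp binary
#'
#' Optional convenience for users with DSSP installed: runs
#' `mkdssp <pdb> <out>` and parses the result. Never required by the package
#' itself (tests use generated DSSP fixtures).
#'
#' @param pdb_path Input PDB file.
#' @param mkdssp Name or path of the DSSP executable.
#' @return 8-state DSSP string.
#' @export
run_mkdssp <- function(pdb_path, mkdssp = "mkdssp") {
  if (Sys.which(mkdssp) == "") stop("mkdssp executable not found on PATH")
  out <- tempfile(fileext = ".dssp")
  status <- system2(mkdssp, c(shQuote(pdb_path), shQuote(out)))
  if (status != 0L) stop("mkdssp exited with status ", status)
  parse_dssp(out)
}
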