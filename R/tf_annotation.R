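# GO-term based TF labeling and DNA-binding-domain (DBD) metadata.
#
# A protein is annotated as a TF when it carries a TF GO term, or a
# transcription-regulation GO term together with a DNA-binding GO term. The
# three term sets are supplied via configuration (the study used 21 TF, 11
# regulation and 4 DNA-binding terms); matching is exact string matching on
# GO identifiers, with no ontology-graph propagation.

#' GO rule configuration for TF annotation
#'
#' @param tf_terms Character vector of TF GO IDs.
#' @param regulation_terms Character vector of transcription-regulation GO
#'   IDs.
#' @param dna_binding_terms Character vector of DNA-binding GO IDs.
#' @return A `go_rule_config` list with the three (pairwise disjoint,
#'   non-empty) term sets.
#' @export
go_rule_config <- function(tf_terms, regulation_terms, dna_binding_terms) {
  sets <- list(tf_terms = unique(tf_terms),
               regulation_terms = unique(regulation_terms),
               dna_binding_terms = unique(dna_binding_terms))
  if (any(lengths(sets) == 0L)) stop("all three GO term sets must be non-empty")
  for (i in 1:2) for (j in (i + 1):3) {
    ov <- intersect(sets[[i]], sets[[j]])
    if (length(ov) > 0L) {
      stop("GO term sets must be pairwise disjoint; shared: ",
           paste(ov, collapse = ", "))
    }
  }
  structure(sets, class = "go_rule_config")
}

#' Default GO rule sets used by the synthetic fixtures
#'
#' Canonical representatives of the three term classes: sequence-specific
#' DNA-binding transcription factor activity, regulation of
#' DNA-templated transcription, and DNA binding. Real studies supply the
#' full term lists through [go_rule_config()].
#'
#' @return A `go_rule_config`.
#' @export
synthetic_go_config <- function() {
  go_rule_config(
    tf_terms = c("GO:0003700", "GO:0000981"),
    regulation_terms = c("GO:0006355", "GO:0045893"),
    dna_binding_terms = c("GO:0003677", "GO:0043565")
  )
}

#' Label a protein as TF or non-TF from its GO annotations
#'
#' @param go_terms Character vector of GO IDs annotated to one protein (may
#'   be empty).
#' @param cfg A [go_rule_config()].
#' @return `TRUE` iff the protein carries a TF term, or a regulation term in
#'   combination with a DNA-binding term.
#' @export
#' @examples
#' cfg <- synthetic_go_config()
#' label_tf("GO:0003700", cfg)                 # TRUE (rule 1)
#' label_tf("GO:0006355", cfg)                 # FALSE (regulation alone)
#' label_tf(c("GO:0006355", "GO:0003677"), cfg)  # TRUE (rule 2)
label_tf <- function(go_terms, cfg) {
  stopifnot(inherits(cfg, "go_rule_config"))
  any(go_terms %in% cfg$tf_terms) ||
    (any(go_terms %in% cfg$regulation_terms) &&
       any(go_terms %in% cfg$dna_binding_terms))
}

# Parse "start-end" interval specs into a 2-column matrix (1-based,
# inclusive, sorted by start). Intervals may overlap.
parse_intervals <- function(spec) {
  if (is.na(spec) || !nzchar(trimws(spec))) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(trimws(spec), ";", fixed = TRUE)[[1L]]
  m <- do.call(rbind, lapply(parts, function(p) {
    se <- suppressWarnings(as.integer(strsplit(p, "-", fixed = TRUE)[[1L]]))
    if (length(se) != 2L || anyNA(se)) stop("malformed interval: '", p, "'")
    if (se[1L] > se[2L]) stop("interval start exceeds end: '", p, "'")
    if (se[1L] < 1L) stop("intervals are 1-based: '", p, "'")
    se
  }))
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

#' Read a protein annotation table
#'
#' Parses a TSV emulating UniProt-derived record content, with columns
#' `protein_id`, `go_terms` (semicolon-separated GO IDs, possibly empty) and
#' optionally `dbd` (semicolon-separated `start-end` residue intervals,
#' 1-based inclusive). TF labels are computed from the GO rule configuration.
#'
#' @param path Path to the TSV (with header).
#' @param cfg A [go_rule_config()].
#' @return List of `annotated_protein` records: `protein_id`, `go_terms`,
#'   `tf_label`, `dbd_intervals` (2-column matrix).
#' @export
read_annotations <- function(path, cfg) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("protein_id", "go_terms") %in% names(df))) {
    stop("annotation table needs columns protein_id and go_terms")
  }
  if (anyDuplicated(df$protein_id)) {
    stop("duplicate protein_id in annotation table: ",
         df$protein_id[duplicated(df$protein_id)][1L])
  }
  lapply(seq_len(nrow(df)), function(i) {
    terms <- strsplit(df$go_terms[i], ";", fixed = TRUE)[[1L]]
    terms <- terms[nzchar(trimws(terms))]
    dbd <- if ("dbd" %in% names(df)) parse_intervals(df$dbd[i]) else
      parse_intervals(NA_character_)
    list(protein_id = df$protein_id[i],
         go_terms = terms,
         tf_label = label_tf(terms, cfg),
         dbd_intervals = dbd)
  })
}
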