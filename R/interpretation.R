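# Integrated-gradients attribution over the one-hot input matrix, and the
# DNA-binding-domain (DBD) score aggregation used to interpret what a
# trained model attends to: per-position scores are split into a DBD-related
# and a non-DBD-related sum using annotated DBD residue intervals. DBD
# information is never used in training, only here.

#' Integrated gradients of the model output
#'
#' Path-integral attribution: each input cell receives
#' `(x - baseline) * mean_s grad f(baseline + alpha_s (x - baseline))`,
#' with the gradient of the eval-mode sigmoid output taken at `steps`
#' midpoints `alpha_s = (s - 0.5)/steps` of the straight-line path
#' (Riemann midpoint rule). The attributions approximately satisfy the
#' completeness axiom: they sum to `f(x) - f(baseline)`, with the residual
#' shrinking as `steps` grows.
#'
#' @param model A trained `structf_model`.
#' @param x Encoded input matrix (`pad_length` x `input_cols`).
#' @param baseline Baseline matrix of the same shape; default the all-zero
#'   matrix, the natural "no residue" input under zero-padding.
#' @param steps Number of path points (default 64).
#' @return Attribution matrix of the same shape as `x`, with attributes
#'   `prediction` (= f(x)), `baseline_prediction` and
#'   `completeness_residual`.
#' @export
integrated_gradients <- function(model, x, baseline = NULL, steps = 64L) {
  stopifnot(inherits(model, "structf_model"), steps >= 1L)
  cfg <- model$cfg
  if (!all(dim(x) == c(cfg$pad_length, cfg$input_cols))) {
    stop("input must be ", cfg$pad_length, " x ", cfg$input_cols)
  }
  if (is.null(baseline)) {
    baseline <- matrix(0, cfg$pad_length, cfg$input_cols)
  }
  if (!all(dim(baseline) == dim(x))) stop("baseline shape mismatch")
  diff <- x - baseline
  alphas <- (seq_len(steps) - 0.5) / steps
  # evaluate the whole path as one eval-mode batch
  Xpath <- array(0, dim = c(cfg$pad_length, cfg$input_cols, steps))
  for (s in seq_len(steps)) Xpath[, , s] <- baseline + alphas[s] * diff
  grad_sum <- matrix(0, cfg$pad_length, cfg$input_cols)
  batch <- 64L
  for (start in seq(1L, steps, by = batch)) {
    take <- start:min(start + batch - 1L, steps)
    fw <- nn_forward(model, Xpath[, , take, drop = FALSE], train = FALSE,
                     keep_cache = TRUE)
    # d prob / d logit = p (1 - p) for each path point
    dz <- fw$prob * (1 - fw$prob)
    bw <- nn_backward(model, fw, dz, need_input_grad = TRUE)
    grad_sum <- grad_sum + rowSums(bw$dX, dims = 2L)
  }
  attr_mat <- diff * grad_sum / steps
  f_x <- nn_forward(model, array(x, dim = c(dim(x), 1L)))$prob
  f_b <- nn_forward(model, array(baseline, dim = c(dim(baseline), 1L)))$prob
  structure(attr_mat, prediction = f_x, baseline_prediction = f_b,
            completeness_residual = sum(attr_mat) - (f_x - f_b))
}

#' Per-position attribution scores
#'
#' Row sums of an attribution matrix over the first `l` rows (the residues
#' of the protein); zero-padding rows are excluded.
#'
#' @param attribution Attribution matrix from [integrated_gradients()].
#' @param l Protein length (number of leading rows to keep).
#' @return Numeric vector of length `l`.
#' @export
position_scores <- function(attribution, l) {
  l <- as.integer(l)
  if (l > nrow(attribution)) stop("protein length exceeds matrix rows")
  if (l == 0L) return(numeric(0))
  rowSums(attribution[seq_len(l), , drop = FALSE])
}

#' Split position scores into DBD-related and non-DBD-related sums
#'
#' Positions inside the union of the DBD intervals (overlaps counted once)
#' contribute to the DBD-related score, all remaining positions to the
#' non-DBD-related score; the two sums always add up to the total signed
#' attribution of the protein.
#'
#' @param scores Per-position score vector (length l).
#' @param dbd_intervals 2-column matrix of 1-based inclusive
#'   `start`/`end` residue intervals (possibly zero rows), as stored by
#'   [read_annotations()].
#' @return Named list `dbd_score`, `non_dbd_score`.
#' @export
dbd_partition <- function(scores, dbd_intervals) {
  l <- length(scores)
  if (is.null(dbd_intervals) || nrow(dbd_intervals) == 0L) {
    return(list(dbd_score = 0, non_dbd_score = sum(scores)))
  }
  if (any(dbd_intervals < 1L) || any(dbd_intervals > l)) {
    stop("DBD interval out of range [1, ", l, "]")
  }
  in_dbd <- logical(l)
  for (i in seq_len(nrow(dbd_intervals))) {
    in_dbd[dbd_intervals[i, 1L]:dbd_intervals[i, 2L]] <- TRUE
  }
  list(dbd_score = sum(scores[in_dbd]), non_dbd_score = sum(scores[!in_dbd]))
}

#' Attribution profile of one protein
#'
#' Convenience wrapper producing the full interpretation record: per
#' position scores and the DBD/non-DBD aggregate for one protein.
#'
#' @param model A trained `structf_model`.
#' @param x Encoded input matrix with a `true_length` attribute (as
#'   produced by [encode_structure()]).
#' @param dbd_intervals Optional interval matrix (see [dbd_partition()]).
#' @param steps Integration steps (default 64).
#' @param protein_id Optional id carried through to the result.
#' @return An `attribution_profile` list.
#' @export
attribution_profile <- function(model, x, dbd_intervals = NULL,
                                steps = 64L, protein_id = NA_character_) {
  l <- attr(x, "true_length") %||% nrow(x)
  am <- integrated_gradients(model, x, steps = steps)
  ps <- position_scores(am, l)
  part <- dbd_partition(ps, dbd_intervals %||%
                          matrix(integer(0), ncol = 2L))
  structure(list(protein_id = protein_id, per_position_scores = ps,
                 dbd_score = part$dbd_score,
                 non_dbd_score = part$non_dbd_score,
                 prediction = attr(am, "prediction"),
                 completeness_residual = attr(am, "completeness_residual")),
            class = "attribution_profile")
}
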