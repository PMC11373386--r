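# Latent-neuron attribution: integrated gradients from an all-zero reference
# encoding to the observed dinucleotide one-hot, collapsed to positions and
# projected onto bases (score assigned to the first nucleotide of each
# pair), with baseline-sequence correction.

#' Integrated-gradients attribution of a latent neuron
#'
#' Computes the integrated-gradients attribution of one latent node's
#' activation with respect to the encoded input, along the straight path
#' from an all-zero reference encoding, using a midpoint Riemann
#' approximation with `steps` points. Channel scores are summed per
#' dinucleotide position and projected to bases via
#' [project_scores_to_bases()]. The completeness axiom holds up to Riemann
#' error: the attributions sum to the node's activation at the sequence
#' minus its activation at the zero reference.
#'
#' @param object A fitted `mfd` model (or encoder).
#' @param seq Character window sequence (model window size).
#' @param node Latent node index in `1..C` (`1..C/2` biological,
#'   the rest technical).
#' @param steps Number of Riemann points.
#' @param weight Optional scalar multiplier (e.g. a class's output-layer
#'   weight for this node, to attribute the node's contribution to a class
#'   logit, as for direct-forwarded metadata features).
#' @return Object of class `attribution_map`: list with `base_scores`
#'   (length = window size), `position_scores` (per dinucleotide position),
#'   `node`, `activation`, `reference_activation` and `completeness_error`.
#' @export
latent_attribution <- function(object, seq, node, steps = 64L, weight = 1) {
  enc <- if (inherits(object, "mfd")) object$encoder else object
  stopifnot(inherits(enc, "mfd_encoder"))
  C <- enc$cfg$n_features
  if (node < 1L || node > C) stop("node index must be in 1..", C)
  L <- enc$cfg$window_size
  X <- encode_batch(features_input_codes(seq, L))   # (1, L-1, 16)
  P <- dim(X)[2]
  alphas <- (seq_len(steps) - 0.5) / steps
  # evaluate the whole alpha grid as one batch
  Xa <- array(0, c(steps, P, 16L))
  for (i in seq_len(steps)) Xa[i, , ] <- alphas[i] * X[1, , ]
  fwd <- encoder_forward(enc, Xa, cache = TRUE)
  ds <- matrix(0, steps, C)
  ds[, node] <- 1
  g <- encoder_backward(enc, fwd$cache, ds, input_grad = TRUE)$dX
  avg_grad <- apply(g, c(2L, 3L), mean)             # (L-1) x 16
  contrib <- X[1, , ] * avg_grad * weight
  position_scores <- rowSums(contrib)
  s_x <- encoder_forward(enc, X)[1, node] * weight
  s_0 <- encoder_forward(enc, array(0, dim(X)))[1, node] * weight
  structure(list(base_scores = project_scores_to_bases(position_scores, L),
                 position_scores = position_scores,
                 node = node, activation = s_x, reference_activation = s_0,
                 completeness_error = abs(sum(position_scores) - (s_x - s_0)),
                 steps = steps),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("Attribution map for latent node %d (%d bases)\n",
              x$node, length(x$base_scores)))
  cat(sprintf("  activation %.4f  (reference %.4f), completeness error %.2e\n",
              x$activation, x$reference_activation, x$completeness_error))
  invisible(x)
}

#' Select baseline sequences
#'
#' Windows exhibiting fewer than two signal peaks across all classes
#' (label row sum of at most 1) serve as baseline sequences for
#' attribution correction.
#'
#' @param label_matrix Binary matrix `windows x classes`.
#' @return Integer indices of the baseline windows.
#' @export
select_baseline_sequences <- function(label_matrix) {
  which(rowSums(as.matrix(label_matrix)) < 2)
}

#' Baseline-corrected average attribution profile
#'
#' Subtracts the positionwise mean baseline attribution from the
#' positionwise mean target attribution; also reports the same correction
#' applied to absolute scores.
#'
#' @param maps Numeric matrix of target attribution profiles
#'   (`sequences x positions`), e.g. rows of `base_scores`.
#' @param baseline_maps Matrix of baseline profiles with the same number of
#'   positions.
#' @return List with `mean` (corrected average profile) and `abs_mean`
#'   (corrected average of absolute scores).
#' @export
baseline_subtract <- function(maps, baseline_maps) {
  maps <- as.matrix(maps)
  baseline_maps <- as.matrix(baseline_maps)
  if (nrow(maps) == 0L || nrow(baseline_maps) == 0L) {
    stop("empty attribution set")
  }
  if (ncol(maps) != ncol(baseline_maps)) stop("profile lengths differ")
  list(mean = colMeans(maps) - colMeans(baseline_maps),
       abs_mean = colMeans(abs(maps)) - colMeans(abs(baseline_maps)))
}

# attribution profiles for a set of window indices of a dataset (rows =
# windows); used by the attribute CLI subcommand and tests
attribution_profiles <- function(object, dataset, idx, node, steps = 32L) {
  t(vapply(idx, function(w) {
    seq <- substring(dataset$genome[[dataset$windows$chrom[w]]],
                     dataset$windows$start[w] + 1L,
                     dataset$windows$end[w])
    latent_attribution(object, seq, node, steps)$base_scores
  }, numeric(dataset$window_size)))
}
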