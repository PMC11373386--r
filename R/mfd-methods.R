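# S3 methods for fitted models.

#' @export
print.mfd <- function(x, ...) {
  cat("Metadata-guided feature disentanglement model\n")
  cat(sprintf("  classes: %d   latent width C: %d (two halves of %d)\n",
              length(x$class_ids), x$encoder$cfg$n_features,
              x$encoder$cfg$n_features %/% 2L))
  cat(sprintf("  window: %d bp   lambda_indep: %g   seed: %d\n",
              x$encoder$cfg$window_size, x$lambda, x$seed))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final training bce: %.4f   sum rho^2: %.3f\n",
              last$bce, last$sum_rho2))
  nrep <- sum(lengths(x$replicates) > 1L)
  if (nrep) cat(sprintf("  replicate groups sharing weights: %d\n", nrep))
  invisible(x)
}

#' @export
summary.mfd <- function(object, ...) {
  out <- list(
    classes = object$class_ids,
    lambda = object$lambda,
    C = object$encoder$cfg$n_features,
    window = object$encoder$cfg$window_size,
    steps = nrow(object$history),
    final = object$history[nrow(object$history), ],
    epoch_log = object$epoch_log,
    replicates = object$replicates,
    bias = object$bias
  )
  class(out) <- "summary.mfd"
  out
}

#' @export
print.summary.mfd <- function(x, ...) {
  cat("MFD fit over", length(x$classes), "classes,", x$steps, "steps\n")
  cat("lambda_indep:", x$lambda, "  C:", x$C, "  window:", x$window, "bp\n\n")
  cat("Per-epoch log:\n")
  print(x$epoch_log, row.names = FALSE)
  cat("\nClass biases:\n")
  print(round(x$bias, 3))
  invisible(x)
}

#' @export
coef.mfd <- function(object, ...) {
  list(W1 = object$weights$W1, W2 = object$weights$W2,
       W = object$weights$W, bias = object$bias)
}

#' Predict peak probabilities for new sequences
#'
#' @param object A fitted `mfd` model.
#' @param newdata Sequences accepted by [extract_features()], or an
#'   `mfd_dataset`; defaults to the training dataset.
#' @param type `"response"` for probabilities, `"link"` for logits,
#'   `"features"` for the latent matrix.
#' @param ... Unused.
#' @return An `n x O` matrix (or the latent `n x C` matrix).
#' @export
predict.mfd <- function(object, newdata = NULL,
                        type = c("response", "link", "features"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$dataset
  seqs <- if (inherits(newdata, "mfd_dataset")) newdata$seq_codes else newdata
  s <- extract_features(object, seqs)
  if (type == "features") return(s)
  eta <- add_bias(s %*% t(object$weights$W), object$bias)
  colnames(eta) <- object$class_ids
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
fitted.mfd <- function(object, ...) {
  predict(object, object$dataset)
}

#' Residuals of a fitted model
#'
#' @param object A fitted `mfd` model.
#' @param type `"response"` (`y - p`) or `"deviance"`.
#' @param ... Unused.
#' @return Matrix of residuals over the training windows and classes.
#' @export
residuals.mfd <- function(object, type = c("response", "deviance"), ...) {
  type <- match.arg(type)
  p <- fitted(object)
  y <- object$dataset$labels
  if (type == "response") return(y - p)
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Plot training curves
#'
#' Binary cross-entropy and the summed squared cross-subspace correlations
#' per optimisation step.
#'
#' @param x A fitted `mfd` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mfd <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$step, h$bce, type = "l", xlab = "step", ylab = "bce",
                 main = "classification loss", ...)
  graphics::abline(h = log(2), lty = 3)
  graphics::plot(h$step, h$sum_rho2, type = "l", xlab = "step",
                 ylab = expression(sum(rho^2)),
                 main = "cross-subspace dependence", ...)
  invisible(x)
}

#' Simulate label draws from fitted probabilities
#'
#' Bernoulli draws per (window, class) from the model's predicted peak
#' probabilities.
#'
#' @param object A fitted `mfd` model.
#' @param nsim Number of simulated label matrices.
#' @param seed Optional seed.
#' @param newdata Optional sequences / dataset (defaults to training data).
#' @param ... Unused.
#' @return List of `n x O` binary matrices.
#' @export
simulate.mfd <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  p <- predict(object, newdata)
  draw <- function() {
    matrix(stats::rbinom(length(p), 1L, as.vector(p)), nrow(p), ncol(p),
           dimnames = dimnames(p))
  }
  if (!is.null(seed)) {
    with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  } else {
    replicate(nsim, draw(), simplify = FALSE)
  }
}
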