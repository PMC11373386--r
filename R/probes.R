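# Post-hoc disentanglement probes: a freshly trained network probe measuring
# how well one latent half predicts the other (held-out R^2 per dimension),
# and factor probes measuring how well a metadata factor can be decoded from
# a feature set. These quantify what the adversarial penalty removed.

#' Cross-subspace predictability probe
#'
#' Trains a fresh perceptron (same architecture family as the adversaries)
#' to predict one latent half from the other on a training split and
#' reports the per-dimension held-out R^2. High values mean the subspaces
#' share information; an effective independence penalty drives them down.
#'
#' @param s1,s2 Latent half matrices (`n x C/2`): the probe predicts `s2`
#'   from `s1`.
#' @param hidden Hidden width of the probe (default: `2 * ncol(s1)`).
#' @param iters Full-batch Adam iterations.
#' @param lr Learning rate.
#' @param holdout Fraction of rows held out for the R^2 estimate.
#' @param seed Integer seed (initialisation and split).
#' @return Numeric vector of held-out R^2 per predicted dimension (clamped
#'   below at 0).
#' @export
probe_r2 <- function(s1, s2, hidden = NULL, iters = 300L, lr = 1e-2,
                     holdout = 0.3, seed = 1L) {
  s1 <- as.matrix(s1); s2 <- as.matrix(s2)
  stopifnot(nrow(s1) == nrow(s2), nrow(s1) >= 10L)
  d_in <- ncol(s1); d_out <- ncol(s2)
  if (is.null(hidden)) hidden <- 2L * d_in
  with_seed(seed, {
    n <- nrow(s1)
    test <- sort(sample.int(n, max(2L, round(n * holdout))))
    train <- setdiff(seq_len(n), test)
    # standardise inputs and targets on the training split (R^2 is invariant
    # to affine target rescaling, and the probe should be scale-free too)
    std <- function(m) {
      mu <- colMeans(m[train, , drop = FALSE])
      sd <- apply(m[train, , drop = FALSE], 2L, stats::sd)
      sd[sd < 1e-8] <- 1
      sweep(sweep(m, 2L, mu), 2L, sd, "/")
    }
    x <- std(s1)
    s2 <- std(s2)
    probe <- mlp_init(c(d_in, hidden, d_out))
    state <- adam_init(probe$params)
    for (it in seq_len(iters)) {
      cache <- mlp_forward(probe, x[train, , drop = FALSE], cache = TRUE)
      resid <- cache$out - s2[train, , drop = FALSE]
      bw <- mlp_backward(probe, cache, 2 * resid / length(resid))
      up <- adam_update(probe$params, bw$grads, state, lr)
      probe$params <- up$params
      state <- up$state
    }
    pred <- mlp_forward(probe, x[test, , drop = FALSE])
    truth <- s2[test, , drop = FALSE]
    r2 <- vapply(seq_len(d_out), function(j) {
      ss_tot <- sum((truth[, j] - mean(truth[, j]))^2)
      if (ss_tot < 1e-12) return(0)
      1 - sum((truth[, j] - pred[, j])^2) / ss_tot
    }, numeric(1))
    pmax(r2, 0)
  })
}

#' Factor decodability probe
#'
#' Ridge-logistic probe predicting a per-window factor label from a feature
#' matrix; reports held-out classification accuracy. Used to ask, e.g.,
#' whether the technical factor is still decodable from the biological
#' subspace after training with the independence penalty.
#'
#' @param features Numeric matrix `n x d`.
#' @param factor_labels Factor (or coercible) of length `n`.
#' @param holdout Held-out fraction.
#' @param seed Integer seed.
#' @return List with `accuracy` (held-out), `chance` (majority-class rate)
#'   and `n_test`.
#' @export
factor_probe <- function(features, factor_labels, holdout = 0.3, seed = 1L) {
  features <- as.matrix(features)
  y <- factor(factor_labels)
  stopifnot(nrow(features) == length(y), nlevels(y) >= 2L)
  if (ncol(features) == 1L) features <- cbind(features, 0)
  with_seed(seed, {
    n <- length(y)
    test <- sort(unlist(lapply(split(seq_len(n), y), function(idx) {
      sample_vec(idx, max(1L, round(length(idx) * holdout)))
    })))
    train <- setdiff(seq_len(n), test)
    fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
    cv <- glmnet::cv.glmnet(features[train, , drop = FALSE], y[train],
                            family = fam, alpha = 0, nfolds = 5L)
    pred <- stats::predict(cv, features[test, , drop = FALSE],
                           s = "lambda.min", type = "class")
    list(accuracy = mean(pred == as.character(y[test])),
         chance = max(table(y[test])) / length(test),
         n_test = length(test))
  })
}
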