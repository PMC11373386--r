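# Model fitting: alternating optimisation of the full objective
# L_MFD = bce - lambda * L_indep  (equivalently bce + lambda * sum(rho^2))
# over mini-batches, with `adversary_steps` adversary updates per model
# update. Fully seeded: two runs with the same seed produce identical logs.

#' Binary cross-entropy over a probability matrix
#'
#' Mean negative log-likelihood over all `N x O` entries, with probabilities
#' clamped to `(1e-7, 1 - 1e-7)` for numerical safety.
#'
#' @param p Numeric matrix (or vector) of probabilities in (0, 1).
#' @param y Binary labels of the same shape.
#' @return Non-negative scalar; `log(2)` for `p = 0.5` everywhere.
#' @export
bce_loss <- function(p, y) {
  if (any(p <= 0 - 1e-12) || any(p >= 1 + 1e-12)) {
    stop("probabilities outside (0, 1)")
  }
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Full objective on a batch
#'
#' Evaluates `L_MFD = bce - lambda * L_indep` for a batch of sequences and
#' labels under a fitted model's current parameters and adversaries. With
#' `lambda = 0` the value equals the binary cross-entropy exactly.
#'
#' @param object A fitted `mfd` model.
#' @param seqs Sequences accepted by [extract_features()].
#' @param labels Binary label matrix aligned to the model's classes.
#' @param lambda Penalty weight; defaults to the model's own.
#' @return Scalar objective with attributes `bce` and `indep`.
#' @export
mfd_objective <- function(object, seqs, labels, lambda = object$lambda) {
  stopifnot(inherits(object, "mfd"), lambda >= 0)
  s <- extract_features(object, seqs)
  p <- predict_probs(s, object$weights$W, object$bias)
  half <- ncol(s) %/% 2L
  bce <- bce_loss(p, as.matrix(labels))
  indep <- independence_loss(s[, seq_len(half), drop = FALSE],
                             s[, half + seq_len(half), drop = FALSE],
                             object$adversaries)
  structure(bce - lambda * indep, bce = bce, indep = indep)
}

#' Fit a metadata-guided feature disentanglement model
#'
#' Trains the multi-task peak predictor: a convolutional encoder produces a
#' latent vector per window, split into a biological half `s1` and a
#' technical half `s2`; two metadata hypernetworks generate each class's
#' output weight halves from its biological and technical metadata sub-rows;
#' per-class free biases complete the output layer. Training alternates
#' adversary updates (which learn to predict one half from the other) with
#' model updates on `bce + lambda * sum(rho^2)`, so the encoder is pushed to
#' make the two halves unpredictable from each other while fitting the peak
#' labels.
#'
#' @param dataset An `mfd_dataset` (see [generate_dataset()] /
#'   [read_dataset()]): windows, dinucleotide-coded sequences, a binary label
#'   matrix, and a metadata table plus schema.
#' @param lambda Non-negative weight of the independence penalty; 0 disables
#'   it exactly.
#' @param encoder An [encoder_config()]; default adapts the window size to
#'   the dataset.
#' @param epochs,batch_size,lr Optimisation settings (Adam).
#' @param adversary_steps Adversary updates per model update.
#' @param adversary_lr,adversary_hidden Adversary optimiser / architecture
#'   settings (hidden width defaults to `C`).
#' @param embed_hidden Hidden width of the hypernetwork interaction trunks.
#' @param test_chroms Chromosomes held out entirely (default: the last
#'   chromosome present). No held-out window enters training.
#' @param val_chroms Chromosomes used for per-epoch validation loss
#'   (default: the test chromosomes).
#' @param seed Integer seed controlling initialisation, batch order and all
#'   other randomness.
#' @param verbose Print per-epoch progress.
#' @return An object of class `mfd` with components including `encoder`,
#'   `emb1`, `emb2`, `bias`, `adversaries`, `weights` (generated class
#'   weights), `history` (per-step metric log), `epoch_log` (per-epoch
#'   training/validation summary), `replicates`, and the held-out split.
#' @seealso [predict.mfd()], [extract_features()], [variant_effect()],
#'   [latent_attribution()]
#' @export
mfd <- function(dataset, lambda = 0.001, encoder = NULL,
                epochs = 5L, batch_size = 64L, lr = 1e-3,
                adversary_steps = 1L, adversary_lr = 1e-3,
                adversary_hidden = NULL, embed_hidden = 16L,
                test_chroms = NULL, val_chroms = NULL,
                seed = 1L, verbose = FALSE) {
  stopifnot(inherits(dataset, "mfd_dataset"), lambda >= 0, epochs >= 1L)
  labels <- dataset$labels
  if (nrow(labels) == 0L) stop("empty dataset")
  meta <- build_metadata_matrix(dataset$metadata_table, dataset$schema)
  ord <- match(colnames(labels), meta$class_ids)
  if (anyNA(ord)) {
    stop("label columns without metadata rows: ",
         paste(colnames(labels)[is.na(ord)], collapse = ", "))
  }
  meta$rows <- meta$rows[ord, , drop = FALSE]
  meta$blocks <- lapply(meta$blocks, function(b) b[ord, , drop = FALSE])
  meta$class_ids <- meta$class_ids[ord]

  cfg <- if (is.null(encoder)) {
    encoder_config(window_size = dataset$window_size, seed = seed)
  } else {
    encoder
  }
  if (cfg$window_size != dataset$window_size) {
    stop("encoder window (", cfg$window_size, ") does not match dataset (",
         dataset$window_size, ")")
  }
  C <- cfg$n_features
  half <- C %/% 2L
  O <- ncol(labels)

  chroms <- unique(dataset$windows$chrom)
  if (is.null(test_chroms)) test_chroms <- chroms[length(chroms)]
  if (is.null(val_chroms)) val_chroms <- test_chroms
  train_idx <- which(!(dataset$windows$chrom %in% c(test_chroms, val_chroms)))
  val_idx <- which(dataset$windows$chrom %in% val_chroms)
  if (length(train_idx) < batch_size) {
    stop("fewer training windows (", length(train_idx),
         ") than one batch (", batch_size, ")")
  }

  enc <- init_encoder(cfg)
  emb1 <- init_embedding(meta, 1L, half, hidden = embed_hidden, seed = seed + 1L)
  emb2 <- init_embedding(meta, 2L, half, hidden = embed_hidden, seed = seed + 2L)
  adv <- init_adversaries(C, hidden = if (is.null(adversary_hidden)) C else
                            adversary_hidden, seed = seed + 3L)
  # bias initialised at the per-class base-rate logit of the training labels
  base <- pmin(pmax(colMeans(labels[train_idx, , drop = FALSE]), 1e-3), 1 - 1e-3)
  bias <- stats::qlogis(base)

  params <- c(prefix_names(enc$params, "enc"),
              prefix_names(emb1$params, "emb1"),
              prefix_names(emb2$params, "emb2"),
              list(bias = bias))
  opt <- adam_init(params)
  adv_state <- NULL

  log_rows <- list()
  epoch_rows <- list()
  step <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      order_ep <- sample(train_idx)
      n_batches <- length(order_ep) %/% batch_size
      for (bi in seq_len(n_batches)) {
        idx <- order_ep[((bi - 1L) * batch_size + 1L):(bi * batch_size)]
        X <- encode_batch(dataset$seq_codes[idx, , drop = FALSE])
        y <- labels[idx, , drop = FALSE]

        enc$params <- strip_prefix(params, "enc")
        emb1$params <- strip_prefix(params, "emb1")
        emb2$params <- strip_prefix(params, "emb2")
        bias <- params$bias

        fwd <- encoder_forward(enc, X, cache = TRUE)
        s <- fwd$s
        s1 <- s[, seq_len(half), drop = FALSE]
        s2 <- s[, half + seq_len(half), drop = FALSE]

        if (lambda > 0) {
          for (k in seq_len(adversary_steps)) {
            st <- adversary_step(s1, s2, adv, adv_state, adversary_lr)
            adv <- st$adv
            adv_state <- st$state
          }
        }

        c1 <- embedding_forward(emb1, meta$blocks, cache = TRUE)
        c2 <- embedding_forward(emb2, meta$blocks, cache = TRUE)
        W <- cbind(c1$W, c2$W)
        p <- predict_probs(s, W, bias)
        bce <- bce_loss(p, y)

        n <- nrow(y)
        dlogit <- (p - y) / (n * O)
        ds <- dlogit %*% W
        dW <- crossprod(dlogit, s)
        dbias <- colSums(dlogit)

        if (lambda > 0) {
          terms <- indep_sum_rho2(s1, s2, adv)
          pg <- indep_model_grads(s1, s2, adv, terms)
          sum_rho2 <- pg$sum_rho2
          ds <- ds + lambda * cbind(pg$ds1, pg$ds2)
        } else {
          sum_rho2 <- indep_sum_rho2(s1, s2, adv)$total
        }

        eb <- encoder_backward(enc, fwd$cache, ds)
        g1 <- embedding_backward(emb1, c1$cache, dW[, seq_len(half), drop = FALSE])
        g2 <- embedding_backward(emb2, c2$cache,
                                 dW[, half + seq_len(half), drop = FALSE])
        grads <- c(prefix_names(eb$grads, "enc"),
                   prefix_names(g1, "emb1"),
                   prefix_names(g2, "emb2"),
                   list(bias = dbias))
        up <- adam_update(params, grads, opt, lr)
        params <- up$params
        opt <- up$state

        step <- step + 1L
        log_rows[[step]] <- c(step = step, epoch = ep, bce = bce,
                              sum_rho2 = sum_rho2, indep = -sum_rho2,
                              objective = bce + lambda * sum_rho2)
      }
      # per-epoch validation loss on held-out chromosomes
      enc$params <- strip_prefix(params, "enc")
      emb1$params <- strip_prefix(params, "emb1")
      emb2$params <- strip_prefix(params, "emb2")
      val_bce <- NA_real_
      if (length(val_idx)) {
        Wv <- cbind(embedding_forward(emb1, meta$blocks),
                    embedding_forward(emb2, meta$blocks))
        sv <- extract_features(enc, dataset$seq_codes[val_idx, , drop = FALSE])
        val_bce <- bce_loss(predict_probs(sv, Wv, params$bias),
                            labels[val_idx, , drop = FALSE])
      }
      last <- log_rows[[step]]
      epoch_rows[[ep]] <- c(epoch = ep, bce = unname(last["bce"]),
                            sum_rho2 = unname(last["sum_rho2"]),
                            val_bce = val_bce)
      if (verbose) {
        message(sprintf("epoch %d/%d  bce %.4f  sum_rho2 %.3f  val_bce %.4f",
                        ep, epochs, last["bce"], last["sum_rho2"], val_bce))
      }
    }
  })

  enc$params <- strip_prefix(params, "enc")
  emb1$params <- strip_prefix(params, "emb1")
  emb2$params <- strip_prefix(params, "emb2")
  weights <- compute_class_weights(meta, emb1, emb2)

  structure(list(
    encoder = enc, emb1 = emb1, emb2 = emb2,
    bias = stats::setNames(params$bias, meta$class_ids),
    adversaries = adv, weights = weights, metadata = meta,
    replicates = resolve_replicates(meta),
    lambda = lambda, seed = seed,
    history = as.data.frame(do.call(rbind, log_rows)),
    epoch_log = as.data.frame(do.call(rbind, epoch_rows)),
    split = list(train = train_idx, val = val_idx,
                 test_chroms = test_chroms, val_chroms = val_chroms),
    class_ids = meta$class_ids,
    dataset = dataset,
    control = list(epochs = epochs, batch_size = batch_size, lr = lr,
                   adversary_steps = adversary_steps,
                   adversary_lr = adversary_lr, embed_hidden = embed_hidden),
    call = match.call()
  ), class = "mfd")
}

#' Class heads of a fitted model
#'
#' @param object A fitted `mfd` model.
#' @return List of per-class heads (`w1`, `w2`, `b`) for [predict_all()].
#' @export
model_heads <- function(object) {
  stopifnot(inherits(object, "mfd"))
  class_heads(object$weights$W1, object$weights$W2, object$bias)
}
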