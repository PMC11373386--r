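# The package's self-contained disentanglement study: generates a synthetic
# peak dataset per seed, trains one model without and one with the
# independence penalty, and measures every downstream quantity of interest
# (cross-subspace probe R^2, factor decodability, enhancer AUROC, variant
# effect separation, tagging enrichment, attribution contrast). Both the
# test suite and the acceptance script drive this function.

#' Run the desk-scale disentanglement study
#'
#' For each seed: simulates a dataset with known biological and technical
#' generative factors, fits the model at `lambda = 0` and at
#' `lambda = lambda_pen` with identical settings, and evaluates on the
#' held-out chromosome:
#' \itemize{
#'   \item cross-subspace predictability: median held-out R^2 of a fresh
#'     probe predicting the technical half from the biological half;
#'   \item factor probes from the biological half: biological-combination
#'     decoding on truly active windows, and GC-level decoding on motif-free
#'     windows (a clean per-window readout of the technical bias driver);
#'   \item enhancer-style classification (active vs inactive windows) from
#'     bidirectional biological features;
#'   \item variant effect scores for planted causal vs neutral variants
#'     (penalised model), plus quantile tagging and enrichment odds ratio;
#'   \item baseline-corrected attribution contrast at planted motif
#'     positions for the biological latent node most used by a matching
#'     class.
#' }
#'
#' @param seeds Integer vector of study seeds (one dataset + model pair per
#'   seed).
#' @param lambda_pen Penalty weight of the penalised arm.
#' @param n_windows,window_size,n_chroms Synthetic dataset size.
#' @param n_features,filters,kernels,pools Encoder settings.
#' @param epochs,batch_size,lr,adversary_steps,adversary_lr Training
#'   settings (shared by both arms).
#' @param n_causal,n_neutral Planted variant counts per seed.
#' @param keep_fits Keep the fitted models in the result (memory-heavy).
#' @param verbose Print progress.
#' @return Object of class `mfd_study`: list with one entry per seed
#'   (measured quantities, see above) plus the call settings.
#' @export
disentanglement_study <- function(seeds = 1:3, lambda_pen = 0.01,
                                  n_windows = 1800L, window_size = 256L,
                                  n_chroms = 4L, n_features = 16L,
                                  filters = c(32L, 24L), kernels = c(8L, 6L),
                                  pools = c(8L, 8L), epochs = 24L,
                                  batch_size = 64L, lr = 3e-3,
                                  adversary_steps = 3L, adversary_lr = 5e-3,
                                  n_causal = 40L, n_neutral = 40L,
                                  keep_fits = FALSE, verbose = FALSE) {
  per_seed <- lapply(seeds, function(seed) {
    ds <- generate_dataset(synthetic_config(
      n_windows = n_windows, window_size = window_size,
      n_chroms = n_chroms, seed = seed))
    enc <- function() encoder_config(window_size = window_size,
                                     n_features = n_features,
                                     filters = filters, kernels = kernels,
                                     pools = pools, seed = seed)
    fits <- lapply(c(0, lambda_pen), function(lam) {
      mfd(ds, lambda = lam, encoder = enc(), epochs = epochs,
          batch_size = batch_size, lr = lr,
          adversary_steps = adversary_steps, adversary_lr = adversary_lr,
          seed = seed)
    })
    names(fits) <- c("lambda0", "penalised")

    test_idx <- which(ds$windows$chrom %in% fits$penalised$split$test_chroms)
    led <- ds$ledger[test_idx]
    combo <- vapply(led, function(e) ifelse(is.na(e$combo), "none", e$combo),
                    character(1))
    gc <- vapply(led, function(e) e$gc, numeric(1))
    active <- combo != "none"
    gcf <- factor(gc[!active] > stats::median(gc[!active]))
    half <- n_features %/% 2L

    eval_arm <- function(fit) {
      s <- extract_features(fit, ds$seq_codes[test_idx, , drop = FALSE])
      s1 <- s[, seq_len(half), drop = FALSE]
      s2 <- s[, half + seq_len(half), drop = FALSE]
      list(probe_r2 = stats::median(probe_r2(s1, s2, seed = seed)),
           bio_acc = factor_probe(s1[active, , drop = FALSE], combo[active],
                                  seed = seed)$accuracy,
           tech_acc = factor_probe(s1[!active, , drop = FALSE], gcf,
                                   seed = seed)$accuracy)
    }
    arms <- lapply(fits, eval_arm)

    # enhancer-style task: active vs inactive test windows, biological
    # bidirectional features of the penalised model
    win_seqs <- substring(ds$genome[ds$windows$chrom[test_idx]],
                          ds$windows$start[test_idx] + 1L,
                          ds$windows$end[test_idx])
    feats <- featurize_bidirectional(fits$penalised, unname(win_seqs))
    enhancer_auroc <- enhancer_classify(feats$s_bio, as.integer(active),
                                        seed = seed)$auroc

    # variant effects under the penalised model
    variants <- make_variants(ds, n_causal = n_causal, n_neutral = n_neutral,
                              seed = seed)
    scores <- variant_effect(fits$penalised, variants)
    comb <- scores[, , "combined", drop = TRUE]
    ct <- ds$config$class_table
    class_combo <- paste(ct$tissue, ct$target, sep = ".")
    causal_score <- vapply(which(variants$causal), function(v) {
      mean(abs(comb[v, class_combo == variants$combo[v]]))
    }, numeric(1))
    neutral_score <- rowMeans(abs(comb[!variants$causal, , drop = FALSE]))
    tags <- tag_by_quantile(comb, upper = 0.9)
    enrich <- enrichment_odds_ratio(tags, variants$causal)

    # logit-level mode identity (exact by linearity of the output layer)
    eta <- function(s) add_bias(s %*% t(fits$penalised$weights$W),
                                fits$penalised$bias)
    # attribution contrast for the most-used biological node of a
    # matching class (heart.accessible)
    cls <- which(class_combo == "heart.accessible")[1]
    node <- which.max(abs(fits$penalised$weights$W1[cls, ]))
    wgt <- fits$penalised$weights$W1[cls, node]
    targets <- test_idx[combo == "heart.accessible"]
    targets <- targets[seq_len(min(20L, length(targets)))]
    base_idx <- test_idx[select_baseline_sequences(
      ds$labels[test_idx, , drop = FALSE])]
    base_idx <- base_idx[seq_len(min(20L, length(base_idx)))]
    tmaps <- attribution_profiles(fits$penalised, ds, targets, node,
                                  steps = 32L)
    bmaps <- attribution_profiles(fits$penalised, ds, base_idx, node,
                                  steps = 32L)
    tmaps <- tmaps * wgt
    bmaps <- bmaps * wgt
    base_profile <- colMeans(bmaps)
    motif_len <- nchar(ds$config$motifs[["heart.accessible"]])
    motif_vals <- c(); bg_vals <- c()
    for (i in seq_along(targets)) {
      e <- ds$ledger[[targets[i]]]
      mpos <- unlist(lapply(e$motif_positions,
                            function(p) p:(p + motif_len - 1L)))
      corrected <- tmaps[i, ] - base_profile
      motif_vals <- c(motif_vals, corrected[mpos])
      bg_vals <- c(bg_vals, corrected[-mpos])
    }

    res <- list(
      seed = seed,
      probe_r2_lambda0 = arms$lambda0$probe_r2,
      probe_r2_penalised = arms$penalised$probe_r2,
      bio_acc_lambda0 = arms$lambda0$bio_acc,
      bio_acc_penalised = arms$penalised$bio_acc,
      tech_acc_lambda0 = arms$lambda0$tech_acc,
      tech_acc_penalised = arms$penalised$tech_acc,
      enhancer_auroc = enhancer_auroc,
      vep_causal_median = stats::median(causal_score),
      vep_neutral_median = stats::median(neutral_score),
      enrichment_or = enrich$odds_ratio,
      attribution_motif_mean = mean(motif_vals),
      attribution_background_mean = mean(bg_vals),
      final_bce_lambda0 = utils::tail(fits$lambda0$history$bce, 1),
      final_bce_penalised = utils::tail(fits$penalised$history$bce, 1),
      final_sum_rho2_penalised = utils::tail(fits$penalised$history$sum_rho2, 1)
    )
    if (keep_fits) res$fits <- fits
    if (verbose) {
      message(sprintf(
        "seed %d: probe R2 %.3f -> %.3f, bio %.2f -> %.2f, VEP %.4f vs %.4f",
        seed, res$probe_r2_lambda0, res$probe_r2_penalised,
        res$bio_acc_lambda0, res$bio_acc_penalised,
        res$vep_causal_median, res$vep_neutral_median))
    }
    res
  })
  structure(list(seeds = per_seed, lambda_pen = lambda_pen,
                 settings = list(n_windows = n_windows,
                                 window_size = window_size,
                                 n_features = n_features, epochs = epochs)),
            class = "mfd_study")
}

#' Summarise a study as medians across seeds
#'
#' @param object An `mfd_study`.
#' @param ... Unused.
#' @return Named list of across-seed medians of every measured quantity.
#' @export
summary.mfd_study <- function(object, ...) {
  fields <- setdiff(names(object$seeds[[1]]), c("seed", "fits"))
  out <- lapply(fields, function(f) {
    stats::median(vapply(object$seeds, `[[`, numeric(1), f))
  })
  names(out) <- fields
  out
}

#' @export
print.mfd_study <- function(x, ...) {
  s <- summary(x)
  cat("Disentanglement study over", length(x$seeds), "seed(s)\n")
  cat(sprintf("  probe R2 (s1 -> s2): %.3f without penalty, %.3f with lambda = %g\n",
              s$probe_r2_lambda0, s$probe_r2_penalised, x$lambda_pen))
  cat(sprintf("  factor probes from s_bio: bio %.3f -> %.3f, technical %.3f -> %.3f\n",
              s$bio_acc_lambda0, s$bio_acc_penalised,
              s$tech_acc_lambda0, s$tech_acc_penalised))
  cat(sprintf("  enhancer AUROC (bio features): %.3f\n", s$enhancer_auroc))
  cat(sprintf("  VEP |combined| medians: causal %.4f vs neutral %.4f; enrichment OR %.2f\n",
              s$vep_causal_median, s$vep_neutral_median, s$enrichment_or))
  cat(sprintf("  attribution: motif %.4g vs background %.4g\n",
              s$attribution_motif_mean, s$attribution_background_mean))
  invisible(x)
}
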