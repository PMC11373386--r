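# Downstream procedures over the disentangled features: bidirectional
# featurization, ridge-logistic enhancer classification, subspace-swapped
# zero-shot variant effect prediction, quantile tagging, and enrichment odds
# ratios.

#' Bidirectional feature sets
#'
#' Encodes each sequence in the forward and the reverse-complement direction
#' and concatenates the corresponding latent halves, yielding `C` features
#' per subspace (forward `C/2` + reverse `C/2`) and `2C` combined features
#' `s_full = [s_bio, s_tech]`.
#'
#' @param object A fitted `mfd` model (or encoder).
#' @param seqs Character vector of window-sized sequences.
#' @return List of matrices `s_bio` (`n x C`), `s_tech` (`n x C`) and
#'   `s_full` (`n x 2C`).
#' @export
featurize_bidirectional <- function(object, seqs) {
  stopifnot(is.character(seqs))
  fwd <- extract_features(object, seqs)
  rev <- extract_features(object, vapply(seqs, reverse_complement,
                                         character(1), USE.NAMES = FALSE))
  half <- attr(fwd, "half")
  s_bio <- cbind(fwd[, seq_len(half), drop = FALSE],
                 rev[, seq_len(half), drop = FALSE])
  s_tech <- cbind(fwd[, half + seq_len(half), drop = FALSE],
                  rev[, half + seq_len(half), drop = FALSE])
  list(s_bio = s_bio, s_tech = s_tech, s_full = cbind(s_bio, s_tech))
}

#' Ridge-logistic enhancer classification
#'
#' Fits an L2-regularised logistic regression on a feature matrix with the
#' regularisation strength chosen by internal cross-validation, and reports
#' AUROC on a held-out split.
#'
#' @param features Numeric feature matrix (`n x d`).
#' @param labels Binary vector of length `n` (both classes must occur).
#' @param holdout Fraction of observations held out for evaluation.
#' @param nfolds Folds of the internal cross-validation over the ridge grid.
#' @param seed Integer seed for the split and fold assignment.
#' @return List of class `enhancer_fit` with `auroc`, the fitted `model`
#'   (a `cv.glmnet` object), `test_idx` and held-out `scores`.
#' @export
enhancer_classify <- function(features, labels, holdout = 0.25,
                              nfolds = 5L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  stopifnot(nrow(features) == length(labels))
  if (ncol(features) == 1L) {
    # glmnet needs >= 2 columns; a zero column changes nothing
    features <- cbind(features, 0)
  }
  with_seed(seed, {
    n <- length(labels)
    test_idx <- sort(unlist(lapply(split(seq_len(n), labels), function(idx) {
      sample_vec(idx, max(1L, round(length(idx) * holdout)))
    })))
    train_idx <- setdiff(seq_len(n), test_idx)
    cv <- glmnet::cv.glmnet(features[train_idx, , drop = FALSE],
                            labels[train_idx], family = "binomial",
                            alpha = 0, nfolds = nfolds,
                            standardize = TRUE)
    scores <- as.vector(stats::predict(cv, features[test_idx, , drop = FALSE],
                                       s = "lambda.min", type = "link"))
    auroc <- as.numeric(pROC::auc(pROC::roc(labels[test_idx], scores,
                                            quiet = TRUE, direction = "<")))
    structure(list(auroc = auroc, model = cv, test_idx = test_idx,
                   scores = scores, labels = labels[test_idx]),
              class = "enhancer_fit")
  })
}

#' @export
print.enhancer_fit <- function(x, ...) {
  cat(sprintf("Ridge-logistic enhancer classifier: held-out AUROC %.3f (n = %d)\n",
              x$auroc, length(x$labels)))
  invisible(x)
}

# extract ref/alt window pair strings for one variant at one shift
variant_windows <- function(genome, chrom, pos, ref, alt, L, shift) {
  cs <- genome[[chrom]]
  lo <- pos - L %/% 2L + shift         # 1-based window start
  if (lo < 1L || lo + L - 1L > nchar(cs)) {
    stop("variant window out of chromosome bounds at ", chrom, ":", pos)
  }
  win <- substring(cs, lo, lo + L - 1L)
  at <- pos - lo + 1L
  have <- substring(win, at, at)
  if (!identical(have, ref)) {
    stop("REF mismatch at ", chrom, ":", pos, " (genome has ", have,
         ", VCF says ", ref, ")")
  }
  alt_win <- paste0(substring(win, 1L, at - 1L), alt,
                    substring(win, at + 1L, L))
  c(ref = win, alt = alt_win)
}

#' Zero-shot variant effect prediction with subspace swapping
#'
#' Scores each variant against every output class as the difference in
#' model predictions between the reference and alternative allele windows,
#' `Phi(s_ref) - Phi(s_alt)` with `Phi_i(x) = sigmoid(x w_i + b_i)`. Three
#' modes are computed: `combined` substitutes the full alternative latent
#' vector; `biological` uses biological features from the alternative allele
#' but technical features from the reference; `technical` the reverse.
#' Predictions are averaged over small window shifts around the variant and
#' over both strands.
#'
#' @param object A fitted `mfd` model.
#' @param variants Data frame with `chrom`, `pos` (1-based), `ref`, `alt`
#'   (SNVs), e.g. from [make_variants()] or [read_variants()].
#' @param genome Named character vector of chromosome sequences; defaults to
#'   the model's training genome.
#' @param shifts Integer window offsets averaged over.
#' @return Array of class `variant_scores` with dimensions
#'   `(variant, class, mode)`, modes `combined`, `biological`, `technical`.
#' @export
variant_effect <- function(object, variants, genome = NULL, shifts = -2:2) {
  stopifnot(inherits(object, "mfd"))
  if (is.null(genome)) genome <- object$dataset$genome
  L <- object$encoder$cfg$window_size
  nv <- nrow(variants)
  bad <- nchar(variants$ref) != 1L | nchar(variants$alt) != 1L
  if (any(bad)) stop("only single-nucleotide variants are supported")

  # gather all (variant, shift) ref/alt windows, then batch-encode both
  # strands in one pass per allele
  refs <- character(nv * length(shifts))
  alts <- character(nv * length(shifts))
  k <- 0L
  for (v in seq_len(nv)) {
    for (sh in shifts) {
      k <- k + 1L
      w <- variant_windows(genome, variants$chrom[v], variants$pos[v],
                           variants$ref[v], variants$alt[v], L, sh)
      refs[k] <- w["ref"]
      alts[k] <- w["alt"]
    }
  }
  W <- object$weights$W
  b <- object$bias
  half <- ncol(W) %/% 2L
  O <- nrow(W)
  score_block <- function(seqs) extract_features(object, seqs)
  modes <- c("combined", "biological", "technical")
  acc <- array(0, c(nv, O, 3L), dimnames = list(variants$id, rownames(W), modes))
  strands <- list(identity,
                  function(s) vapply(s, reverse_complement, character(1),
                                     USE.NAMES = FALSE))
  for (st in strands) {
    s_ref <- score_block(st(refs))
    s_alt <- score_block(st(alts))
    p_ref <- predict_probs(s_ref, W, b)
    p_alt_full <- predict_probs(s_alt, W, b)
    s_bio_alt <- cbind(s_alt[, seq_len(half), drop = FALSE],
                       s_ref[, half + seq_len(half), drop = FALSE])
    s_tech_alt <- cbind(s_ref[, seq_len(half), drop = FALSE],
                        s_alt[, half + seq_len(half), drop = FALSE])
    p_alt_bio <- predict_probs(s_bio_alt, W, b)
    p_alt_tech <- predict_probs(s_tech_alt, W, b)
    for (m in seq_along(modes)) {
      p_alt <- switch(modes[m], combined = p_alt_full,
                      biological = p_alt_bio, technical = p_alt_tech)
      d <- p_ref - p_alt                       # (nv * shifts) x O
      dim(d) <- c(length(shifts), nv, O)       # shift index varies fastest
      acc[, , m] <- acc[, , m] + apply(d, c(2L, 3L), mean)
    }
  }
  structure(acc / 2, class = "variant_scores", shifts = shifts)
}

#' Quantile-based variant tagging
#'
#' Tags variants whose per-class scores fall beyond empirical quantile
#' cutoffs computed per class over the variant set: one-sided (`upper`
#' only), variants with score strictly above the upper quantile; two-sided
#' (`lower` also given), additionally those strictly below the lower
#' quantile. Ties at the cutoff are never tagged.
#'
#' @param scores Numeric matrix `variants x classes` (one mode slice of a
#'   `variant_scores` array) or a vector.
#' @param upper Upper quantile level in (0, 1).
#' @param lower Optional lower quantile level for two-sided tagging.
#' @return Logical matrix of the same shape as `scores`.
#' @export
tag_by_quantile <- function(scores, upper = 0.95, lower = NULL) {
  vec <- is.null(dim(scores))
  scores <- as.matrix(scores)
  if (nrow(scores) == 0L) stop("empty score matrix")
  if (any(!is.finite(scores))) stop("scores must be finite")
  tags <- matrix(FALSE, nrow(scores), ncol(scores),
                 dimnames = dimnames(scores))
  for (j in seq_len(ncol(scores))) {
    hi <- stats::quantile(scores[, j], upper, names = FALSE, type = 7)
    tags[, j] <- scores[, j] > hi
    if (!is.null(lower)) {
      lo <- stats::quantile(scores[, j], lower, names = FALSE, type = 7)
      tags[, j] <- tags[, j] | (scores[, j] < lo)
    }
  }
  if (vec) tags[, 1L] else tags
}

#' Enrichment odds ratio of tagged variants
#'
#' Overall mode: a variant counts as tagged if it is tagged in any class
#' (unique-variant aggregation); the odds ratio is the cross-product ratio
#' of the 2x2 table of tagged status against truth status. A zero cell
#' triggers a 0.5 continuity correction (flagged in the result). Stratified
#' mode (when `strata` gives a per-class grouping) reports the mean of
#' per-class odds ratios within each stratum.
#'
#' @param tags Logical matrix `variants x classes` (or vector).
#' @param truth Logical/binary vector over variants (true positives).
#' @param strata Optional character vector over classes (e.g. assay or
#'   target) selecting the stratified view.
#' @return An object of class `enrichment` (overall mode): list with
#'   `table`, `odds_ratio`, `continuity`; or a data frame of mean per-class
#'   odds ratios per stratum.
#' @export
enrichment_odds_ratio <- function(tags, truth, strata = NULL) {
  tags <- as.matrix(tags)
  truth <- as.logical(truth)
  stopifnot(nrow(tags) == length(truth))
  if (all(truth) || !any(truth)) {
    stop("odds ratio undefined: truth labels are all ",
         if (all(truth)) "positive" else "negative")
  }
  or_from <- function(tagged) {
    a <- sum(tagged & truth); b <- sum(tagged & !truth)
    cc <- sum(!tagged & truth); d <- sum(!tagged & !truth)
    tab <- matrix(c(a, cc, b, d), 2L, 2L,
                  dimnames = list(tagged = c("yes", "no"),
                                  truth = c("yes", "no")))
    cont <- any(tab == 0)
    if (cont) tab <- tab + 0.5
    list(or = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
         table = tab, continuity = cont)
  }
  if (is.null(strata)) {
    res <- or_from(rowSums(tags) > 0L)
    return(structure(list(table = res$table, odds_ratio = res$or,
                          continuity = res$continuity),
                     class = "enrichment"))
  }
  stopifnot(length(strata) == ncol(tags))
  per_class <- vapply(seq_len(ncol(tags)),
                      function(j) or_from(tags[, j])$or, numeric(1))
  out <- stats::aggregate(list(mean_or = per_class),
                          by = list(stratum = strata), FUN = mean)
  out$n_classes <- as.vector(table(strata)[out$stratum])
  out
}

#' @export
print.enrichment <- function(x, ...) {
  cat("Enrichment 2x2 (unique variants, any-class tagging):\n")
  print(x$table)
  cat(sprintf("odds ratio: %.4f%s\n", x$odds_ratio,
              if (x$continuity) "  (0.5 continuity correction applied)" else ""))
  invisible(x)
}
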