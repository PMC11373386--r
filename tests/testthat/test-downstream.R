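test_that("bidirectional featurization has the documented geometry", {
  fit <- tiny_fit()
  ds <- tiny_dataset()
  seqs <- substring(ds$genome[ds$windows$chrom[1:6]],
                    ds$windows$start[1:6] + 1L, ds$windows$end[1:6])
  fs <- featurize_bidirectional(fit, unname(seqs))
  C <- fit$encoder$cfg$n_features
  expect_equal(ncol(fs$s_bio), C)
  expect_equal(ncol(fs$s_tech), C)
  expect_equal(ncol(fs$s_full), 2 * C)
  expect_identical(fs$s_full[, 1:C], fs$s_bio)
  # reverse-complemented inputs swap the forward/reverse halves
  fs_rc <- featurize_bidirectional(
    fit, vapply(unname(seqs), reverse_complement, character(1),
                USE.NAMES = FALSE))
  half <- C / 2
  expect_equal(fs_rc$s_bio[, 1:half], fs$s_bio[, half + 1:half],
               tolerance = 1e-12)
  expect_equal(fs_rc$s_tech[, half + 1:half], fs$s_tech[, 1:half],
               tolerance = 1e-12)
})

test_that("enhancer classification reaches the analytic extremes", {
  set.seed(71)
  y <- rep(c(0, 1), each = 40)
  x <- matrix(y + rnorm(80, sd = 1e-3), ncol = 1)   # separable 1-D feature
  res <- enhancer_classify(x, y, seed = 1)
  expect_equal(res$auroc, 1)
  # shuffled labels: AUROC within the permutation interval around 0.5
  xs <- matrix(rnorm(160), ncol = 2)
  ys <- sample(y)
  res2 <- enhancer_classify(xs, ys, seed = 2)
  perm <- replicate(300, oracle_auroc(sample(res2$labels), res2$scores))
  expect_gte(res2$auroc, quantile(perm, 0.005))
  expect_lte(res2$auroc, quantile(perm, 0.995))
  expect_error(enhancer_classify(xs, rep(1, 80)), "single class")
})

test_that("reported AUROC equals the concordant-pair oracle", {
  set.seed(72)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- rbinom(60, 1, plogis(x[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  res <- enhancer_classify(x, y, seed = 3)
  expect_equal(res$auroc, oracle_auroc(res$labels, res$scores),
               tolerance = 1e-9)
})

test_that("identity variants score zero in every mode", {
  fit <- tiny_fit()
  ds <- tiny_dataset()
  vars <- make_variants(ds, n_causal = 3, n_neutral = 3, seed = 5)
  idv <- vars
  idv$alt <- idv$ref
  vs <- variant_effect(fit, idv, shifts = -1:1)
  expect_true(all(vs == 0))
})

test_that("biological and technical logit differences sum to the combined one", {
  fit <- tiny_fit()
  ds <- tiny_dataset()
  vars <- make_variants(ds, n_causal = 4, n_neutral = 2, seed = 6)
  L <- fit$encoder$cfg$window_size
  W <- fit$weights$W
  half <- ncol(W) / 2
  for (i in 1:3) {
    wins <- mfd:::variant_windows(ds$genome, vars$chrom[i], vars$pos[i],
                                  vars$ref[i], vars$alt[i], L, 0)
    s <- extract_features(fit, wins)
    eta <- function(x) as.vector(x %*% t(W)) + fit$bias
    d_comb <- eta(s[1, , drop = FALSE]) - eta(s[2, , drop = FALSE])
    s_bio_alt <- c(s[2, 1:half], s[1, half + 1:half])
    s_tech_alt <- c(s[1, 1:half], s[2, half + 1:half])
    d_bio <- eta(s[1, , drop = FALSE]) - eta(matrix(s_bio_alt, 1))
    d_tech <- eta(s[1, , drop = FALSE]) - eta(matrix(s_tech_alt, 1))
    expect_equal(d_bio + d_tech, d_comb, tolerance = 1e-9)
  }
})

test_that("variant scores equal the strand-and-shift averaging oracle", {
  fit <- tiny_fit()
  ds <- tiny_dataset()
  vars <- make_variants(ds, n_causal = 2, n_neutral = 1, seed = 7)
  v <- vars[1, ]
  shifts <- -1:1
  W <- fit$weights$W
  acc <- 0
  for (sh in shifts) {
    wins <- mfd:::variant_windows(ds$genome, v$chrom, v$pos, v$ref, v$alt,
                                  fit$encoder$cfg$window_size, sh)
    for (strand in 1:2) {
      seqs <- if (strand == 1) wins else
        vapply(wins, reverse_complement, character(1), USE.NAMES = FALSE)
      s <- extract_features(fit, seqs)
      p <- mfd:::predict_probs(s, W, fit$bias)
      acc <- acc + (p[1, ] - p[2, ])
    }
  }
  oracle <- acc / (2 * length(shifts))
  vs <- variant_effect(fit, v, shifts = shifts)
  expect_equal(as.vector(vs[1, , "combined"]), unname(oracle),
               tolerance = 1e-10)
  # REF mismatch is a hard error
  bad <- v
  bad$ref <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  expect_error(variant_effect(fit, bad, shifts = 0), "REF mismatch")
})

test_that("quantile tagging matches sort-and-count and is monotone", {
  sc <- 1:100
  expect_equal(sum(tag_by_quantile(sc, upper = 0.95)), 5)
  expect_equal(which(tag_by_quantile(sc, upper = 0.95)), 96:100)
  expect_equal(sum(tag_by_quantile(sc, upper = 0.9, lower = 0.1)), 20)
  expect_equal(sum(tag_by_quantile(rep(3, 50), upper = 0.9)), 0)
  set.seed(73)
  x <- rnorm(200)
  counts <- vapply(c(0.5, 0.7, 0.9, 0.95, 0.99),
                   function(q) sum(tag_by_quantile(x, upper = q)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(tag_by_quantile(numeric(0)), "empty")
  expect_error(tag_by_quantile(c(1, NA)), "finite")
})

test_that("enrichment odds ratios match the cross-product oracle", {
  # 2x2 table [[30,70],[10,90]]
  truth <- c(rep(TRUE, 40), rep(FALSE, 160))
  tags <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 70), rep(FALSE, 90))
  enr <- enrichment_odds_ratio(matrix(tags, ncol = 1), truth)
  expect_equal(enr$odds_ratio, 27 / 7, tolerance = 1e-12)
  expect_false(enr$continuity)
  # zero cell -> continuity correction, flagged
  enr0 <- enrichment_odds_ratio(matrix(c(rep(TRUE, 40), rep(FALSE, 160)),
                                       ncol = 1), truth)
  expect_true(enr0$continuity)
  expect_error(enrichment_odds_ratio(matrix(tags, ncol = 1),
                                     rep(TRUE, 200)), "undefined")
})

test_that("independent tags give an odds ratio consistent with permutation", {
  set.seed(74)
  truth <- rbinom(400, 1, 0.3) == 1
  tags <- matrix(rbinom(400, 1, 0.2) == 1, ncol = 1)
  obs <- enrichment_odds_ratio(tags, truth)$odds_ratio
  perm <- replicate(400, {
    enrichment_odds_ratio(tags, sample(truth))$odds_ratio
  })
  expect_gte(obs, quantile(perm, 0.025))
  expect_lte(obs, quantile(perm, 0.975))
})

test_that("stratified enrichment averages per-class odds ratios", {
  set.seed(75)
  truth <- c(rep(TRUE, 30), rep(FALSE, 70))
  tags <- cbind(a = truth, b = sample(truth), c = rep(c(TRUE, FALSE), 50))
  strata <- c("x", "x", "y")
  out <- enrichment_odds_ratio(tags, truth, strata = strata)
  per_class <- vapply(1:3, function(j) {
    enrichment_odds_ratio(tags[, j, drop = FALSE], truth)$odds_ratio
  }, numeric(1))
  expect_equal(out$mean_or[out$stratum == "x"], mean(per_class[1:2]))
  expect_equal(out$mean_or[out$stratum == "y"], per_class[3])
})
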