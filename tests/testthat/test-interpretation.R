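test_that("integrated gradients satisfy completeness within Riemann error", {
  fit <- tiny_fit()
  ds <- tiny_dataset()
  seq1 <- substring(ds$genome[[ds$windows$chrom[2]]],
                    ds$windows$start[2] + 1L, ds$windows$end[2])
  am64 <- latent_attribution(fit, seq1, node = 3, steps = 64)
  am256 <- latent_attribution(fit, seq1, node = 3, steps = 256)
  delta <- am64$activation - am64$reference_activation
  # midpoint-Riemann error bound shrinks like 1/steps
  tol <- 0.05 * max(1, abs(delta))
  expect_lt(am64$completeness_error, tol)
  expect_lt(am256$completeness_error, tol / 4)
  expect_equal(sum(am64$base_scores), sum(am64$position_scores))
  expect_error(latent_attribution(fit, seq1, node = 99), "node index")
})

test_that("a sequence-blind node yields an all-zero map", {
  enc <- mfd:::init_encoder(tiny_encoder(seed = 6))
  enc$params$dense_W[, 5] <- 0          # node 5 ignores the sequence
  ds <- tiny_dataset()
  seq1 <- substring(ds$genome[[ds$windows$chrom[4]]],
                    ds$windows$start[4] + 1L, ds$windows$end[4])
  am <- latent_attribution(enc, seq1, node = 5, steps = 16)
  expect_true(all(abs(am$base_scores) < 1e-12))
})

test_that("a linear single-filter model attributes its own weights", {
  # width-1 convolution, no pooling, bias far inside the linear ReLU region:
  # the model is linear in the encoding, so integrated gradients equal the
  # closed-form gradient x input
  cfg <- encoder_config(window_size = 12, n_features = 2, filters = 1L,
                        kernels = 2L, pools = 1L, seed = 8)
  enc <- mfd:::init_encoder(cfg)
  enc$params$conv_b1 <- 100               # keep every ReLU active
  enc$params$dense_W <- matrix(c(1, 0), 1, 2)
  enc$params$dense_b <- c(0, 0)
  s <- "ACGTACGTACGT"
  am <- latent_attribution(enc, s, node = 1, steps = 64)
  e <- encode_sequence(s)
  P <- nrow(e$onehot)                     # conv width 2 -> P - 1 positions
  Lout <- P - 1L
  # closed form: position p contributes mean over the conv offsets that see
  # it of W[j, channel(p)] / Lout
  Wc <- enc$params$conv_W1
  expected <- numeric(P)
  for (p in seq_len(P)) {
    ch <- e$codes[p]
    for (j in 1:2) {
      pos <- p - j + 1L
      if (pos >= 1L && pos <= Lout) {
        expected[p] <- expected[p] + Wc[j, ch, 1] / Lout
      }
    }
  }
  expect_equal(am$position_scores, expected, tolerance = 1e-8)
})

test_that("baseline selection implements the fewer-than-two-peaks rule", {
  lm <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  expect_equal(select_baseline_sequences(lm), c(1, 2))
  # loop oracle on a random matrix
  set.seed(81)
  m <- matrix(rbinom(200, 1, 0.2), 40, 5)
  oracle <- integer(0)
  for (i in 1:40) {
    total <- 0
    for (j in 1:5) total <- total + m[i, j]
    if (total < 2) oracle <- c(oracle, i)
  }
  expect_equal(select_baseline_sequences(m), oracle)
})

test_that("baseline subtraction is exact positionwise algebra", {
  set.seed(82)
  t_maps <- matrix(rnorm(5 * 20), 5, 20)
  b_maps <- matrix(rnorm(4 * 20), 4, 20)
  out <- baseline_subtract(t_maps, b_maps)
  expect_equal(out$mean, colMeans(t_maps) - colMeans(b_maps))
  expect_equal(out$abs_mean, colMeans(abs(t_maps)) - colMeans(abs(b_maps)))
  same <- baseline_subtract(t_maps, t_maps)
  expect_equal(same$mean, numeric(20), ignore_attr = TRUE)
  zero <- baseline_subtract(t_maps, matrix(0, 2, 20))
  expect_equal(zero$mean, colMeans(t_maps))
  expect_error(baseline_subtract(t_maps, b_maps[, 1:10]), "lengths")
  expect_error(baseline_subtract(t_maps[0, , drop = FALSE], b_maps), "empty")
})
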