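# identity-map adversary pair built by hand (x -> (x+, x-) -> x through the
# two ReLU hidden layers), used to realise the extreme of the penalty
make_identity_adversaries <- function(C) {
  half <- C %/% 2L
  adv <- init_adversaries(C, hidden = 2L * half, seed = 1)
  ident <- function() {
    I <- diag(half)
    list(W1 = cbind(I, -I), b1 = numeric(2 * half),
         W2 = diag(2 * half), b2 = numeric(2 * half),
         W3 = rbind(I, -I), b3 = numeric(half))
  }
  adv$rho12$params <- ident()
  adv$rho21$params <- ident()
  adv
}

test_that("batch Pearson matches stats::cor and handles degeneracies", {
  x <- c(1, 2, 3, 4)
  expect_equal(batch_pearson(x, x), 1)
  expect_equal(batch_pearson(x, -x), -1)
  y <- c(1, 2, 3, 5)
  expect_equal(batch_pearson(x, y), cor(x, y), tolerance = 1e-9)
  expect_equal(batch_pearson(x, y), oracle_pearson(x, y), tolerance = 1e-9)
  expect_equal(batch_pearson(x, rep(2, 4)), 0)
  expect_error(batch_pearson(1, 1), "length")
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(batch_pearson(a, b), cor(a, b), tolerance = 1e-9)
  }
})

test_that("independence loss attains its bounds at the constructed extremes", {
  set.seed(42)
  C <- 8L
  s1 <- matrix(rnorm(16 * 4), 16, 4)
  # constant adversaries: zero-variance convention gives exactly 0
  adv0 <- init_adversaries(C, seed = 2)
  for (nm in names(adv0$rho12$params)) {
    adv0$rho12$params[[nm]] <- adv0$rho12$params[[nm]] * 0
    adv0$rho21$params[[nm]] <- adv0$rho21$params[[nm]] * 0
  }
  expect_equal(independence_loss(s1, s1 + matrix(rnorm(64), 16, 4), adv0), 0)
  # identity adversaries with s2 = s1: every correlation is 1 -> -C
  advI <- make_identity_adversaries(C)
  expect_equal(independence_loss(s1, s1, advI), -C, tolerance = 1e-9)
})

test_that("independence loss matches the per-dimension loop oracle and bounds", {
  set.seed(43)
  for (i in 1:10) {
    C <- 2L * sample(2:4, 1)
    n <- sample(8:32, 1)
    s1 <- matrix(rnorm(n * C / 2), n, C / 2)
    s2 <- matrix(rnorm(n * C / 2), n, C / 2)
    adv <- init_adversaries(C, hidden = 6, seed = i)
    u <- mfd:::mlp_forward(adv$rho12, s1)
    v <- mfd:::mlp_forward(adv$rho21, s2)
    oracle <- 0
    for (d in seq_len(C / 2)) {
      oracle <- oracle - oracle_pearson(s2[, d], u[, d])^2 -
        oracle_pearson(s1[, d], v[, d])^2
    }
    val <- independence_loss(s1, s2, adv)
    expect_equal(val, oracle, tolerance = 1e-7)
    expect_gte(val, -C)
    expect_lte(val, 0)
  }
})

test_that("pearson and affine invariance carry over to the loss", {
  set.seed(44)
  C <- 6L
  s1 <- matrix(rnorm(20 * 3), 20, 3)
  s2 <- matrix(rnorm(20 * 3), 20, 3)
  adv <- init_adversaries(C, hidden = 5, seed = 3)
  base <- -mfd:::indep_sum_rho2(s1, s2, adv)$total
  # positive-slope affine rescaling of the *target* halves leaves each
  # correlation term unchanged
  s1r <- sweep(sweep(s1, 2, c(2, 0.5, 3), "*"), 2, c(1, -2, 0.3), "+")
  terms <- mfd:::indep_sum_rho2(s1, s2, adv)
  terms_r <- lapply(seq_len(3), function(d) {
    oracle_pearson(s1r[, d], mfd:::mlp_forward(adv$rho21, s2)[, d])^2
  })
  terms_o <- lapply(seq_len(3), function(d) {
    oracle_pearson(s1[, d], mfd:::mlp_forward(adv$rho21, s2)[, d])^2
  })
  expect_equal(unlist(terms_r), unlist(terms_o), tolerance = 1e-9)
  expect_lte(base, 0)
})

test_that("a zero learning rate leaves the adversaries bit-identical", {
  set.seed(45)
  s1 <- matrix(rnorm(12 * 3), 12, 3)
  s2 <- matrix(rnorm(12 * 3), 12, 3)
  adv <- init_adversaries(6L, hidden = 5, seed = 4)
  st <- adversary_step(s1, s2, adv, lr = 0)
  expect_identical(st$adv$rho12$params, adv$rho12$params)
  expect_identical(st$adv$rho21$params, adv$rho21$params)
})

test_that("adversaries learn a planted linear dependence to near-saturation", {
  set.seed(46)
  C <- 8L
  n <- 64
  s1 <- matrix(rnorm(n * 4), n, 4)
  A <- matrix(rnorm(16), 4, 4)
  s2 <- s1 %*% A                                 # perfectly predictable
  adv <- init_adversaries(C, hidden = 8, seed = 5)
  state <- NULL
  for (i in 1:400) {
    st <- adversary_step(s1, s2, adv, state, lr = 5e-3)
    adv <- st$adv; state <- st$state
  }
  terms <- mfd:::indep_sum_rho2(s1, s2, adv)
  sum12 <- sum(vapply(terms$r12, function(t) t$r^2, numeric(1)))
  expect_gt(sum12, 0.8 * (C / 2))                # analytic optimum is C/2
})

test_that("on independent subspaces trained predictability stays at chance level", {
  set.seed(47)
  n <- 64
  train_adv <- function(s1, s2, seed) {
    adv <- init_adversaries(8L, hidden = 8, seed = seed)
    state <- NULL
    for (i in 1:150) {
      st <- adversary_step(s1, s2, adv, state, lr = 5e-3)
      adv <- st$adv; state <- st$state
    }
    sum(vapply(mfd:::indep_sum_rho2(s1, s2, adv)$r12,
               function(t) t$r^2, numeric(1)))
  }
  s1 <- matrix(rnorm(n * 4), n, 4)
  s2 <- matrix(rnorm(n * 4), n, 4)                # independent by draw
  observed <- train_adv(s1, s2, seed = 6)
  # permutation-null oracle: same training on row-permuted targets
  null <- vapply(1:8, function(b) {
    train_adv(s1, s2[sample(n), , drop = FALSE], seed = 6 + b)
  }, numeric(1))
  expect_lte(observed, max(null) + 0.5)
})

test_that("model and adversary push the squared correlations in opposite directions", {
  set.seed(48)
  s1 <- matrix(rnorm(24 * 4), 24, 4)
  s2 <- s1 + matrix(rnorm(24 * 4, sd = 0.5), 24, 4)
  adv <- init_adversaries(8L, hidden = 8, seed = 7)
  state <- NULL
  for (i in 1:100) {
    st <- adversary_step(s1, s2, adv, state, lr = 5e-3)
    adv <- st$adv; state <- st$state
  }
  total <- function(a, b) mfd:::indep_sum_rho2(a, b, adv)$total
  before <- total(s1, s2)
  # model step direction: descend the penalty through the latent batches
  pg <- mfd:::indep_model_grads(s1, s2, adv)
  eps <- 1e-3
  after_model <- total(s1 - eps * pg$ds1, s2 - eps * pg$ds2)
  expect_lt(after_model, before)
  # adversary step: ascend
  st <- adversary_step(s1, s2, adv, state, lr = 1e-3)
  expect_gt(mfd:::indep_sum_rho2(s1, s2, st$adv)$total, before - 1e-6)
})
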