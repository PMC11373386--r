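# Adversarial subspace-independence penalty: two perceptrons predict one
# latent half from the other; the penalty is the (negated) sum of squared
# per-dimension mini-batch Pearson correlations between predictions and
# targets. The adversaries maximise these correlations; the sequence model is
# penalised for them.

#' Empirical Pearson correlation over a mini-batch
#'
#' Standard empirical Pearson correlation with the convention that a
#' zero-variance vector yields correlation 0 (no evidence of dependence);
#' a small epsilon stabilises the denominator.
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @param eps Stabilising constant added under the square root.
#' @return Correlation in `[-1, 1]`.
#' @export
batch_pearson <- function(x, y, eps = 1e-12) {
  n <- length(x)
  if (n < 2L || length(y) != n) stop("need two vectors of equal length >= 2")
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sum(xc * xc)
  sy <- sum(yc * yc)
  if (sx < 1e-12 || sy < 1e-12) return(0)
  sum(xc * yc) / sqrt(sx * sy + eps)
}

# correlation with gradients w.r.t. both vectors (zero-variance -> all zero)
pearson_with_grad <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sum(xc * xc)
  sy <- sum(yc * yc)
  if (sx < 1e-12 || sy < 1e-12) {
    return(list(r = 0, dx = numeric(n), dy = numeric(n)))
  }
  denom <- sqrt(sx * sy + 1e-12)
  r <- sum(xc * yc) / denom
  list(r = r,
       dx = yc / denom - r * xc / sx,
       dy = xc / denom - r * yc / sy)
}

#' Initialise the adversary pair
#'
#' Two multilayer perceptrons mapping one latent half to a prediction of the
#' other (`rho12`: biological to technical, `rho21`: the reverse).
#'
#' @param C Full latent width (each adversary maps `C/2` to `C/2`).
#' @param hidden Hidden width (two hidden layers); defaults to `C`.
#' @param seed Integer seed for initialisation.
#' @return An object of class `mfd_adversaries`.
#' @export
init_adversaries <- function(C, hidden = C, seed = 1L) {
  stopifnot(C %% 2L == 0L)
  half <- C %/% 2L
  with_seed(seed, {
    structure(list(rho12 = mlp_init(c(half, hidden, hidden, half)),
                   rho21 = mlp_init(c(half, hidden, hidden, half)),
                   C = as.integer(C)),
              class = "mfd_adversaries")
  })
}

#' Subspace-independence loss
#'
#' The adversarial penalty
#' `L_indep = -sum_i r_i(s2, rho12(s1))^2 - sum_i r_i(s1, rho21(s2))^2`,
#' where `r_i` is the per-dimension mini-batch Pearson correlation. The value
#' always lies in `[-C, 0]`; adversaries minimise it (drive correlations to
#' 1), while the sequence model is trained with `-lambda * L_indep` added to
#' its loss, pushing the squared correlations down.
#'
#' @param s1_batch,s2_batch Numeric matrices `n x C/2` of the two latent
#'   halves over a mini-batch (`n >= 2`).
#' @param adv An `mfd_adversaries` pair.
#' @return Scalar loss in `[-C, 0]`.
#' @export
independence_loss <- function(s1_batch, s2_batch, adv) {
  -indep_sum_rho2(s1_batch, s2_batch, adv)$total
}

# sum of squared correlations (both directions) plus caches for gradients
indep_sum_rho2 <- function(s1, s2, adv) {
  stopifnot(nrow(s1) >= 2L, all(dim(s1) == dim(s2)))
  u_cache <- mlp_forward(adv$rho12, s1, cache = TRUE)
  v_cache <- mlp_forward(adv$rho21, s2, cache = TRUE)
  u <- u_cache$out
  v <- v_cache$out
  half <- ncol(s1)
  r12 <- vector("list", half)
  r21 <- vector("list", half)
  total <- 0
  for (i in seq_len(half)) {
    r12[[i]] <- pearson_with_grad(s2[, i], u[, i])
    r21[[i]] <- pearson_with_grad(s1[, i], v[, i])
    total <- total + r12[[i]]$r^2 + r21[[i]]$r^2
  }
  list(total = total, u_cache = u_cache, v_cache = v_cache,
       r12 = r12, r21 = r21)
}

# gradients of sum(rho^2) for the model step: w.r.t. s1 and s2, with
# adversary parameters frozen (gradient flows through the adversary inputs)
indep_model_grads <- function(s1, s2, adv, terms = NULL) {
  if (is.null(terms)) terms <- indep_sum_rho2(s1, s2, adv)
  half <- ncol(s1)
  n <- nrow(s1)
  ds1 <- matrix(0, n, half)
  ds2 <- matrix(0, n, half)
  du <- matrix(0, n, half)
  dv <- matrix(0, n, half)
  for (i in seq_len(half)) {
    t12 <- terms$r12[[i]]
    t21 <- terms$r21[[i]]
    ds2[, i] <- ds2[, i] + 2 * t12$r * t12$dx
    du[, i] <- 2 * t12$r * t12$dy
    ds1[, i] <- ds1[, i] + 2 * t21$r * t21$dx
    dv[, i] <- 2 * t21$r * t21$dy
  }
  ds1 <- ds1 + mlp_backward(adv$rho12, terms$u_cache, du)$dinput
  ds2 <- ds2 + mlp_backward(adv$rho21, terms$v_cache, dv)$dinput
  list(ds1 = ds1, ds2 = ds2, sum_rho2 = terms$total)
}

# gradients of sum(rho^2) w.r.t. adversary parameters (inputs detached)
indep_adversary_grads <- function(s1, s2, adv, terms = NULL) {
  if (is.null(terms)) terms <- indep_sum_rho2(s1, s2, adv)
  half <- ncol(s1)
  n <- nrow(s1)
  du <- matrix(0, n, half)
  dv <- matrix(0, n, half)
  for (i in seq_len(half)) {
    du[, i] <- 2 * terms$r12[[i]]$r * terms$r12[[i]]$dy
    dv[, i] <- 2 * terms$r21[[i]]$r * terms$r21[[i]]$dy
  }
  list(g12 = mlp_backward(adv$rho12, terms$u_cache, du)$grads,
       g21 = mlp_backward(adv$rho21, terms$v_cache, dv)$grads,
       sum_rho2 = terms$total)
}

#' One adversary update step
#'
#' Performs one Adam ascent step on the adversary parameters, maximising the
#' sum of squared cross-subspace correlations (equivalently minimising
#' [independence_loss()]). The latent batches are treated as constants: no
#' gradient reaches the sequence model.
#'
#' @param s1_batch,s2_batch Latent halves over a mini-batch (`n x C/2`).
#' @param adv An `mfd_adversaries` pair.
#' @param state Optimiser state from a previous call, or `NULL` to start.
#' @param lr Learning rate (0 leaves parameters bit-identical).
#' @return List with updated `adv`, `state` and the step's `loss`
#'   (the [independence_loss()] value before the update).
#' @export
adversary_step <- function(s1_batch, s2_batch, adv, state = NULL, lr = 1e-3) {
  g <- indep_adversary_grads(s1_batch, s2_batch, adv)
  if (is.null(state)) {
    state <- list(a12 = adam_init(adv$rho12$params),
                  a21 = adam_init(adv$rho21$params))
  }
  # ascent on sum(rho^2) == descent on L_indep
  up12 <- adam_update(adv$rho12$params, lapply(g$g12, function(x) -x),
                      state$a12, lr)
  up21 <- adam_update(adv$rho21$params, lapply(g$g21, function(x) -x),
                      state$a21, lr)
  adv$rho12$params <- up12$params
  adv$rho21$params <- up21$params
  list(adv = adv, state = list(a12 = up12$state, a21 = up21$state),
       loss = -g$sum_rho2)
}
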