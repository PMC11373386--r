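# Internal neural-network primitives shared by the encoder, the metadata
# embedding hypernetworks and the adversaries: dense stacks with hand-coded
# reverse-mode gradients, and an Adam optimiser over flat named parameter
# lists. Kept deliberately free of external dependencies so every gradient
# path (including input gradients for attribution) is explicit.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_grad <- function(z) (z > 0) * 1

# add a bias vector to every row of a matrix (column-major fill trick)
add_bias <- function(z, b) z + rep(b, each = nrow(z))

# He-scaled Gaussian init; callers are responsible for seeding the RNG
init_matrix <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / max(nin, 1L))), nin, nout)
}

# Evaluate a thunk under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level reproducibility.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

## ---- multilayer perceptron -------------------------------------------------

# sizes: c(n_in, hidden..., n_out); hidden layers use `activation`, the output
# layer is linear. Parameters live in a flat named list (W1, b1, W2, ...).
mlp_init <- function(sizes, activation = "relu") {
  stopifnot(length(sizes) >= 2L, all(sizes >= 1L))
  params <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    params[[paste0("W", l)]] <- init_matrix(sizes[l], sizes[l + 1L])
    params[[paste0("b", l)]] <- numeric(sizes[l + 1L])
  }
  structure(list(params = params, sizes = sizes, activation = activation),
            class = "mfd_mlp")
}

mlp_act <- function(name) {
  switch(name,
         relu = list(f = relu, g = relu_grad),
         tanh = list(f = tanh, g = function(z) 1 - tanh(z)^2),
         stop("unknown activation: ", name))
}

# Forward pass; with cache = TRUE returns pre-activations needed for backprop.
mlp_forward <- function(mlp, x, cache = FALSE) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  nl <- length(mlp$sizes) - 1L
  act <- mlp_act(mlp$activation)
  hs <- vector("list", nl + 1L)
  zs <- vector("list", nl)
  hs[[1L]] <- x
  for (l in seq_len(nl)) {
    z <- add_bias(hs[[l]] %*% mlp$params[[paste0("W", l)]],
                  mlp$params[[paste0("b", l)]])
    zs[[l]] <- z
    hs[[l + 1L]] <- if (l < nl) act$f(z) else z
  }
  if (cache) list(out = hs[[nl + 1L]], hs = hs, zs = zs) else hs[[nl + 1L]]
}

# Reverse pass: returns parameter gradients (same names as params) and the
# gradient with respect to the input rows.
mlp_backward <- function(mlp, cache, dout) {
  nl <- length(mlp$sizes) - 1L
  act <- mlp_act(mlp$activation)
  grads <- list()
  dz <- dout
  for (l in rev(seq_len(nl))) {
    grads[[paste0("W", l)]] <- crossprod(cache$hs[[l]], dz)
    grads[[paste0("b", l)]] <- colSums(dz)
    dh <- dz %*% t(mlp$params[[paste0("W", l)]])
    if (l > 1L) dz <- dh * act$g(cache$zs[[l - 1L]])
  }
  list(grads = grads, dinput = dh)
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# prefix every name in a flat list (used to pool parameter groups for Adam)
prefix_names <- function(x, prefix) {
  names(x) <- paste0(prefix, ".", names(x))
  x
}

strip_prefix <- function(x, prefix) {
  keep <- startsWith(names(x), paste0(prefix, "."))
  out <- x[keep]
  names(out) <- substring(names(out), nchar(prefix) + 2L)
  out
}
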