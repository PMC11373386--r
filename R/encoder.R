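# Convolutional sequence encoder: a scaled-down configurable tower of
# valid-mode 1D convolutions with ReLU and max pooling (motif presence
# detection), global average pooling, and a linear map to the C latent
# features. The latent vector is
# split positionally: the first C/2 entries form the biological subspace
# s^(1), the last C/2 the technical subspace s^(2). Forward and reverse
# passes are hand-coded so gradients w.r.t. both parameters and the input
# encoding (needed for integrated gradients) are available.

#' Encoder configuration
#'
#' Describes the convolutional tower mapping a one-hot dinucleotide window to
#' a `C`-dimensional latent vector. Each block is a valid-mode convolution
#' followed by ReLU and max pooling; a global average pool and a linear
#' layer produce the latent features.
#'
#' @param window_size Input window width in bp (the encoded axis has
#'   `window_size - 1` dinucleotide positions).
#' @param n_features Latent width `C`; must be even (split into a biological
#'   and a technical half of `C/2` each).
#' @param filters Integer vector: number of filters per block.
#' @param kernels Integer vector: kernel width per block.
#' @param pools Integer vector: max-pooling factor per block.
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(window_size = 1152L, n_features = 64L,
                           filters = c(48L, 64L), kernels = c(10L, 6L),
                           pools = c(8L, 8L), seed = 1L) {
  window_size <- as.integer(window_size)
  n_features <- as.integer(n_features)
  stopifnot(window_size >= 4L,
            n_features >= 2L,
            length(filters) == length(kernels),
            length(filters) == length(pools),
            all(filters >= 1L), all(kernels >= 2L), all(pools >= 1L))
  if (n_features %% 2L != 0L) stop("n_features (C) must be even")
  # check the tower leaves at least one position (receptive field fits)
  P <- window_size - 1L
  for (b in seq_along(filters)) {
    P <- P - kernels[b] + 1L
    if (P < 1L) stop("receptive field exceeds window size at block ", b)
    P <- P %/% pools[b]
    if (P < 1L) stop("pooling collapses block ", b, " below one position")
  }
  structure(list(window_size = window_size, n_features = n_features,
                 filters = as.integer(filters), kernels = as.integer(kernels),
                 pools = as.integer(pools), seed = as.integer(seed)),
            class = "encoder_config")
}

# seed-fixed parameter initialisation; returns list(cfg, params)
init_encoder <- function(cfg) {
  stopifnot(inherits(cfg, "encoder_config"))
  params <- with_seed(cfg$seed, {
    p <- list()
    cin <- 16L
    for (b in seq_along(cfg$filters)) {
      k <- cfg$kernels[b]
      f <- cfg$filters[b]
      p[[paste0("conv_W", b)]] <-
        array(stats::rnorm(k * cin * f, sd = sqrt(2 / (k * cin))), c(k, cin, f))
      p[[paste0("conv_b", b)]] <- numeric(f)
      cin <- f
    }
    p$dense_W <- init_matrix(cin, cfg$n_features)
    p$dense_b <- numeric(cfg$n_features)
    p
  })
  structure(list(cfg = cfg, params = params), class = "mfd_encoder")
}

# valid-mode convolution over an (N, L, Cin) array with an (k, Cin, F) kernel
conv_forward <- function(X, W, b) {
  d <- dim(X)
  N <- d[1]; L <- d[2]; cin <- d[3]
  k <- dim(W)[1]; f <- dim(W)[3]
  Lout <- L - k + 1L
  out <- matrix(rep(b, each = N * Lout), N * Lout, f)
  for (j in seq_len(k)) {
    Xs <- X[, j:(j + Lout - 1L), , drop = FALSE]
    dim(Xs) <- c(N * Lout, cin)
    out <- out + Xs %*% matrix(W[j, , ], cin, f)
  }
  dim(out) <- c(N, Lout, f)
  out
}

# backward through conv_forward; returns dW, db and (optionally) dX
conv_backward <- function(X, W, dOut, input_grad = TRUE) {
  d <- dim(X)
  N <- d[1]; L <- d[2]; cin <- d[3]
  k <- dim(W)[1]; f <- dim(W)[3]
  Lout <- L - k + 1L
  dO <- dOut
  dim(dO) <- c(N * Lout, f)
  dW <- array(0, dim(W))
  dX <- if (input_grad) array(0, d) else NULL
  for (j in seq_len(k)) {
    Xs <- X[, j:(j + Lout - 1L), , drop = FALSE]
    dim(Xs) <- c(N * Lout, cin)
    dW[j, , ] <- crossprod(Xs, dO)
    if (input_grad) {
      dXs <- dO %*% t(matrix(W[j, , ], cin, f))
      dim(dXs) <- c(N, Lout, cin)
      dX[, j:(j + Lout - 1L), ] <- dX[, j:(j + Lout - 1L), , drop = FALSE] + dXs
    }
  }
  db <- colSums(dO)
  list(dW = dW, db = db, dX = dX)
}

# non-overlapping max pooling along the position axis (tail trimmed);
# returns the pooled values and the winning slice index for backprop
pool_forward <- function(X, p) {
  if (p == 1L) return(list(out = X, idx = NULL))
  d <- dim(X)
  L2 <- d[2] %/% p
  cur <- X[, seq(1L, by = p, length.out = L2), , drop = FALSE]
  idx <- array(1L, dim(cur))
  for (r in 2:p) {
    cand <- X[, seq(r, by = p, length.out = L2), , drop = FALSE]
    better <- cand > cur
    cur[better] <- cand[better]
    idx[better] <- r
  }
  list(out = cur, idx = idx)
}

pool_backward <- function(dP, idx, p, L) {
  if (p == 1L) return(dP)
  d <- dim(dP)
  dX <- array(0, c(d[1], L, d[3]))
  for (r in seq_len(p)) {
    dX[, seq(r, by = p, length.out = d[2]), ] <- dP * (idx == r)
  }
  dX
}

# full tower forward; X is (N, window-1, 16)
encoder_forward <- function(enc, X, cache = FALSE) {
  cfg <- enc$cfg
  p <- enc$params
  caches <- list()
  A <- X
  for (b in seq_along(cfg$filters)) {
    Z <- conv_forward(A, p[[paste0("conv_W", b)]], p[[paste0("conv_b", b)]])
    R <- relu(Z)
    pl <- pool_forward(R, cfg$pools[b])
    if (cache) {
      caches[[b]] <- list(Xin = A, Z = Z, Lrelu = dim(R)[2], pool_idx = pl$idx)
    }
    A <- pl$out
  }
  N <- dim(A)[1]; Lg <- dim(A)[2]; f <- dim(A)[3]
  h <- apply(A, 3L, rowMeans)
  if (N == 1L) h <- matrix(h, 1L, f)
  s <- add_bias(h %*% p$dense_W, p$dense_b)
  if (cache) list(s = s, cache = list(blocks = caches, h = h, Lg = Lg, f = f)) else s
}

# reverse pass from ds (N x C); returns flat grads and optionally dX
encoder_backward <- function(enc, cache, ds, input_grad = FALSE) {
  cfg <- enc$cfg
  p <- enc$params
  grads <- list()
  grads$dense_W <- crossprod(cache$h, ds)
  grads$dense_b <- colSums(ds)
  dh <- ds %*% t(p$dense_W)
  N <- nrow(dh); Lg <- cache$Lg; f <- cache$f
  # global average pool backward: spread dh/Lg over positions
  dA <- array(apply(dh / Lg, 2L, function(col) rep(col, Lg)), c(N, Lg, f))
  for (b in rev(seq_along(cfg$filters))) {
    bc <- cache$blocks[[b]]
    dR <- pool_backward(dA, bc$pool_idx, cfg$pools[b], bc$Lrelu)
    dZ <- dR * relu_grad(bc$Z)
    need_dx <- b > 1L || input_grad
    cb <- conv_backward(bc$Xin, p[[paste0("conv_W", b)]], dZ, input_grad = need_dx)
    grads[[paste0("conv_W", b)]] <- cb$dW
    grads[[paste0("conv_b", b)]] <- cb$db
    dA <- cb$dX
  }
  list(grads = grads, dX = if (input_grad) dA else NULL)
}

#' Extract latent sequence features
#'
#' Runs sequences through the trained (or freshly initialised) encoder and
#' returns the `C`-dimensional latent representation per sequence. The first
#' `C/2` columns are the biological subspace, the last `C/2` the technical
#' subspace.
#'
#' @param object A fitted `mfd` model or an encoder created by the package.
#' @param seqs Character vector of window sequences, an integer dinucleotide
#'   code matrix, or a single `encoded_sequence`.
#' @param chunk Batch size used internally to bound memory.
#' @return Numeric matrix `n x C` with an attribute `half = C/2`.
#' @export
extract_features <- function(object, seqs, chunk = 256L) {
  enc <- if (inherits(object, "mfd")) object$encoder else object
  stopifnot(inherits(enc, "mfd_encoder"))
  codes <- features_input_codes(seqs, enc$cfg$window_size)
  n <- nrow(codes)
  C <- enc$cfg$n_features
  out <- matrix(0, n, C)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    out[i:j, ] <- encoder_forward(enc, encode_batch(codes[i:j, , drop = FALSE]))
    i <- j + 1L
  }
  attr(out, "half") <- C %/% 2L
  out
}

features_input_codes <- function(seqs, window_size) {
  if (inherits(seqs, "encoded_sequence")) {
    codes <- matrix(seqs$codes, nrow = 1L)
  } else if (is.character(seqs)) {
    codes <- seqs_to_dinuc_matrix(seqs)
  } else if (is.matrix(seqs)) {
    codes <- seqs
  } else {
    stop("unsupported sequence input")
  }
  if (ncol(codes) != window_size - 1L) {
    stop("sequences have ", ncol(codes) + 1L,
         " bp but the encoder window is ", window_size, " bp")
  }
  codes
}

#' Per-class peak probability from latent features
#'
#' The prediction rule of the model's output layer: the latent halves are
#' dotted with the class's generated weight halves, the free class bias is
#' added, and a sigmoid is applied:
#' `p = sigmoid(s1 . w1 + s2 . w2 + b)`.
#'
#' @param f Latent features: a numeric vector of length `C`, or a list with
#'   elements `s1` and `s2`.
#' @param head A class head: list with `w1`, `w2` (each length `C/2`) and
#'   scalar `b`.
#' @return Probability strictly inside (0, 1).
#' @export
predict_class <- function(f, head) {
  if (is.list(f)) {
    s1 <- f$s1; s2 <- f$s2
  } else {
    half <- length(f) %/% 2L
    s1 <- f[seq_len(half)]
    s2 <- f[half + seq_len(half)]
  }
  if (length(s1) != length(head$w1) || length(s2) != length(head$w2)) {
    stop("feature / head dimension mismatch")
  }
  stats::plogis(sum(s1 * head$w1) + sum(s2 * head$w2) + head$b)
}

#' Per-class probabilities for all classes
#'
#' Applies [predict_class()] across a list of class heads.
#'
#' @param f Latent features (vector of length `C` or list with `s1`, `s2`).
#' @param heads List of class heads.
#' @return Numeric probability vector, one entry per head.
#' @export
predict_all <- function(f, heads) {
  stopifnot(length(heads) >= 1L)
  vapply(heads, function(h) predict_class(f, h), numeric(1))
}

# vectorised head application: s (n x C), W (O x C), bias (O) -> n x O probs
predict_probs <- function(s, W, bias) {
  stats::plogis(add_bias(s %*% t(W), bias))
}

# build a list of class heads from weight halves and biases
class_heads <- function(W1, W2, bias) {
  lapply(seq_len(nrow(W1)), function(i) {
    list(w1 = W1[i, ], w2 = W2[i, ], b = bias[i], class_id = rownames(W1)[i])
  })
}
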