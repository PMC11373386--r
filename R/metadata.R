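# Metadata embedding: per-experiment metadata rows are partitioned into a
# biological group (1) and a technical group (2); a separate hypernetwork per
# group maps its sub-row to the corresponding half of the class's output
# weights. Classes with identical metadata rows are replicates and receive
# bit-identical generated weights; only their free biases differ.

#' Declare a metadata schema
#'
#' One row per metadata variable, assigning each to the biological (1) or
#' technical (2) group, its encoding kind, and whether its transformed value
#' bypasses the interaction trunk and is concatenated directly into the
#' generated weights.
#'
#' @param name Character vector of column names in the metadata table.
#' @param kind One of `"categorical"`, `"scalar"`, `"vector"` per variable.
#'   Vector variables hold comma-separated numeric values in the table cell.
#' @param group Integer 1 (biological) or 2 (technical) per variable.
#' @param direct Logical per variable: direct-forward flag (default none).
#' @param direct_dim Intermediate dimension of direct-forward variables.
#' @return A `metadata_schema` data frame.
#' @export
metadata_schema <- function(name, kind, group, direct = FALSE, direct_dim = 1L) {
  n <- length(name)
  sch <- data.frame(name = as.character(name),
                    kind = as.character(kind),
                    group = as.integer(group),
                    direct = rep_len(as.logical(direct), n),
                    direct_dim = rep_len(as.integer(direct_dim), n),
                    stringsAsFactors = FALSE)
  stopifnot(all(sch$kind %in% c("categorical", "scalar", "vector")),
            all(sch$group %in% c(1L, 2L)),
            !anyDuplicated(sch$name))
  for (g in 1:2) {
    if (!any(sch$group == g)) stop("schema must assign variables to group ", g)
  }
  class(sch) <- c("metadata_schema", "data.frame")
  sch
}

#' Read / write a metadata schema sidecar TSV
#'
#' @param path File path of a tab-separated sidecar with columns
#'   `name`, `kind`, `group`, `direct`, `direct_dim`.
#' @return [read_metadata_schema()] returns a `metadata_schema`.
#' @export
read_metadata_schema <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  metadata_schema(df$name, df$kind, df$group, df$direct, df$direct_dim)
}

#' @rdname read_metadata_schema
#' @param schema A `metadata_schema`.
#' @export
write_metadata_schema <- function(schema, path) {
  utils::write.table(as.data.frame(schema), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

encode_variable <- function(x, spec, encoder = NULL) {
  if (anyNA(x)) stop("missing metadata values in variable '", spec$name,
                     "' (imputation is not supported)")
  if (spec$kind == "categorical") {
    x <- as.character(x)
    levels <- if (is.null(encoder)) sort(unique(x)) else encoder$levels
    mat <- matrix(0, length(x), length(levels),
                  dimnames = list(NULL, paste0(spec$name, "=", levels)))
    hit <- match(x, levels)            # unseen level -> all-zero block
    ok <- which(!is.na(hit))
    mat[cbind(ok, hit[ok])] <- 1
    list(mat = mat, encoder = list(levels = levels))
  } else {
    vals <- if (spec$kind == "vector") {
      do.call(rbind, lapply(strsplit(as.character(x), ","), as.numeric))
    } else {
      matrix(as.numeric(x), ncol = 1L)
    }
    if (anyNA(vals)) stop("non-numeric value in scalar/vector variable '",
                          spec$name, "'")
    if (is.null(encoder)) {
      mu <- colMeans(vals)
      sd <- apply(vals, 2L, stats::sd)
      sd[!is.finite(sd) | sd < 1e-12] <- 1
      encoder <- list(mean = mu, sd = sd)
    }
    mat <- sweep(sweep(vals, 2L, encoder$mean), 2L, encoder$sd, "/")
    colnames(mat) <- if (ncol(mat) == 1L) spec$name else
      paste0(spec$name, ".", seq_len(ncol(mat)))
    list(mat = mat, encoder = encoder)
  }
}

#' Build the encoded metadata matrix
#'
#' Encodes a per-class metadata table against a schema: categoricals are
#' one-hot expanded with a stored level dictionary, scalars standardised with
#' stored mean/sd, and columns laid out in the deterministic schema order.
#' Missing values are a hard error.
#'
#' @param table Data frame with one row per output class; must contain every
#'   schema variable and a `class_id` column (or row names) identifying
#'   classes.
#' @param schema A [metadata_schema()].
#' @return An object of class `mfd_metadata` with elements `rows` (the full
#'   `O x M` encoded matrix), `blocks` (per-variable encoded blocks),
#'   `schema`, `class_ids` and `encoders` (level dictionaries / moments for
#'   re-encoding new metadata).
#' @export
build_metadata_matrix <- function(table, schema) {
  stopifnot(inherits(schema, "metadata_schema"))
  missing_cols <- setdiff(schema$name, colnames(table))
  if (length(missing_cols)) {
    stop("metadata table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  class_ids <- if ("class_id" %in% colnames(table)) {
    as.character(table$class_id)
  } else if (!is.null(rownames(table))) {
    rownames(table)
  } else {
    as.character(seq_len(nrow(table)))
  }
  if (anyDuplicated(class_ids)) stop("duplicate class ids in metadata table")
  blocks <- list()
  encoders <- list()
  for (k in seq_len(nrow(schema))) {
    spec <- schema[k, ]
    ev <- encode_variable(table[[spec$name]], spec)
    blocks[[spec$name]] <- ev$mat
    encoders[[spec$name]] <- ev$encoder
  }
  rows <- do.call(cbind, blocks)
  rownames(rows) <- class_ids
  structure(list(rows = rows, blocks = blocks, schema = schema,
                 class_ids = class_ids, encoders = encoders),
            class = "mfd_metadata")
}

# re-encode a new metadata table with stored encoders (zero-shot inference);
# unseen categorical levels map to all-zero one-hot blocks
encode_metadata <- function(meta, table) {
  schema <- meta$schema
  blocks <- list()
  for (k in seq_len(nrow(schema))) {
    spec <- schema[k, ]
    blocks[[spec$name]] <-
      encode_variable(table[[spec$name]], spec, meta$encoders[[spec$name]])$mat
  }
  out <- meta
  out$blocks <- blocks
  out$rows <- do.call(cbind, blocks)
  out$class_ids <- if ("class_id" %in% colnames(table)) {
    as.character(table$class_id)
  } else {
    as.character(seq_len(nrow(table)))
  }
  rownames(out$rows) <- out$class_ids
  out
}

#' Partition classes into replicate groups
#'
#' Classes whose encoded metadata rows are exactly equal are replicates: they
#' share generated output weights and differ only through their free class
#' biases.
#'
#' @param M An `mfd_metadata` object.
#' @return Named list of integer vectors partitioning class indices.
#' @export
resolve_replicates <- function(M) {
  stopifnot(inherits(M, "mfd_metadata"))
  key <- apply(M$rows, 1L, paste, collapse = "\r")
  groups <- split(seq_along(key), match(key, unique(key)))
  names(groups) <- vapply(groups, function(g) M$class_ids[g[1]], character(1))
  groups
}

## ---- embedding hypernetwork ------------------------------------------------

# One module per group: per-variable transforms f_k (identity for
# scalar/vector, learned linear for one-hot blocks; direct-forward variables
# map to their direct_dim), an interaction trunk (one hidden layer) over the
# concatenated non-direct intermediates, and a linear map to C/2 - x
# dimensions; direct intermediates are concatenated to give C/2 weights.
init_embedding <- function(meta, group, half_C, hidden = 16L, seed = 1L,
                           activation = "relu") {
  schema <- meta$schema
  vars <- schema[schema$group == group, , drop = FALSE]
  if (nrow(vars) == 0L) stop("no metadata variables in group ", group)
  with_seed(seed, {
    params <- list()
    info <- list()
    x_tot <- 0L
    trunk_in <- 0L
    for (k in seq_len(nrow(vars))) {
      spec <- vars[k, ]
      d <- ncol(meta$blocks[[spec$name]])
      hdim <- if (spec$direct) spec$direct_dim else d
      learned <- spec$kind == "categorical" || (spec$direct && hdim != d)
      if (learned) {
        params[[paste0("f_W_", spec$name)]] <- init_matrix(d, hdim)
        params[[paste0("f_b_", spec$name)]] <- numeric(hdim)
      }
      info[[spec$name]] <- list(d = d, hdim = hdim, learned = learned,
                                direct = spec$direct)
      if (spec$direct) x_tot <- x_tot + hdim else trunk_in <- trunk_in + hdim
    }
    if (x_tot > half_C) stop("direct-forward dimensions exceed C/2")
    trunk_out <- half_C - x_tot
    if (trunk_out > 0L) {
      if (trunk_in == 0L) stop("group ", group, " has no trunk inputs but ",
                               trunk_out, " trunk output dimensions")
      params$trunk_W1 <- init_matrix(trunk_in, hidden)
      params$trunk_b1 <- numeric(hidden)
      params$trunk_W2 <- init_matrix(hidden, trunk_out)
      params$trunk_b2 <- numeric(trunk_out)
    }
    structure(list(params = params, info = info, vars = vars$name,
                   group = group, half_C = half_C, hidden = hidden,
                   trunk_out = trunk_out, activation = activation),
              class = "mfd_embedding")
  })
}

# forward: encoded blocks (named list of O x d matrices) -> W_g (O x C/2)
embedding_forward <- function(emb, blocks, cache = FALSE) {
  act <- mlp_act(emb$activation)
  hs <- list()
  for (v in emb$vars) {
    X <- blocks[[v]]
    inf <- emb$info[[v]]
    hs[[v]] <- if (inf$learned) {
      add_bias(X %*% emb$params[[paste0("f_W_", v)]],
               emb$params[[paste0("f_b_", v)]])
    } else {
      X
    }
  }
  direct_vars <- emb$vars[vapply(emb$info[emb$vars], `[[`, TRUE, "direct")]
  trunk_vars <- setdiff(emb$vars, direct_vars)
  pieces <- list()
  G <- NULL; Z1 <- NULL; H1 <- NULL
  if (emb$trunk_out > 0L) {
    G <- do.call(cbind, hs[trunk_vars])
    Z1 <- add_bias(G %*% emb$params$trunk_W1, emb$params$trunk_b1)
    H1 <- act$f(Z1)
    pieces$trunk <- add_bias(H1 %*% emb$params$trunk_W2, emb$params$trunk_b2)
  }
  for (v in direct_vars) pieces[[v]] <- hs[[v]]
  W <- do.call(cbind, pieces)
  if (cache) {
    list(W = W, cache = list(hs = hs, G = G, Z1 = Z1, H1 = H1,
                             blocks = blocks, trunk_vars = trunk_vars,
                             direct_vars = direct_vars))
  } else {
    W
  }
}

# backward from dW (O x C/2) -> parameter gradients
embedding_backward <- function(emb, cache, dW) {
  act <- mlp_act(emb$activation)
  grads <- list()
  dh <- list()
  col <- 0L
  if (emb$trunk_out > 0L) {
    dT <- dW[, seq_len(emb$trunk_out), drop = FALSE]
    col <- emb$trunk_out
    grads$trunk_W2 <- crossprod(cache$H1, dT)
    grads$trunk_b2 <- colSums(dT)
    dH1 <- dT %*% t(emb$params$trunk_W2)
    dZ1 <- dH1 * act$g(cache$Z1)
    grads$trunk_W1 <- crossprod(cache$G, dZ1)
    grads$trunk_b1 <- colSums(dZ1)
    dG <- dZ1 %*% t(emb$params$trunk_W1)
    gcol <- 0L
    for (v in cache$trunk_vars) {
      hdim <- emb$info[[v]]$hdim
      dh[[v]] <- dG[, gcol + seq_len(hdim), drop = FALSE]
      gcol <- gcol + hdim
    }
  }
  for (v in cache$direct_vars) {
    hdim <- emb$info[[v]]$hdim
    dh[[v]] <- dW[, col + seq_len(hdim), drop = FALSE]
    col <- col + hdim
  }
  for (v in emb$vars) {
    if (emb$info[[v]]$learned && !is.null(dh[[v]])) {
      grads[[paste0("f_W_", v)]] <- crossprod(cache$blocks[[v]], dh[[v]])
      grads[[paste0("f_b_", v)]] <- colSums(dh[[v]])
    }
  }
  grads
}

#' Generate per-class output weights from metadata
#'
#' Applies the group-1 hypernetwork to each class's biological metadata
#' sub-row and the group-2 hypernetwork to its technical sub-row, yielding
#' the two generated weight halves of the output layer. Group-1 variables
#' cannot influence the technical half and vice versa, by construction.
#'
#' @param M An `mfd_metadata` object.
#' @param emb1,emb2 Embedding modules for groups 1 and 2.
#' @return List with `W1`, `W2` (each `O x C/2`, row names = class ids) and
#'   `W` (their column binding).
#' @export
compute_class_weights <- function(M, emb1, emb2) {
  stopifnot(inherits(M, "mfd_metadata"),
            inherits(emb1, "mfd_embedding"), inherits(emb2, "mfd_embedding"),
            emb1$group == 1L, emb2$group == 2L)
  W1 <- embedding_forward(emb1, M$blocks)
  W2 <- embedding_forward(emb2, M$blocks)
  rownames(W1) <- rownames(W2) <- M$class_ids
  list(W1 = W1, W2 = W2, W = cbind(W1, W2))
}
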