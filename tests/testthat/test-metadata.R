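test_that("metadata encoding does the dimension bookkeeping", {
  tab <- data.frame(class_id = c("a", "b", "c"),
                    tissue = c("x", "y", "x"),
                    assay = c(1.5, 2.5, 3.5))
  sch <- metadata_schema(c("tissue", "assay"), c("categorical", "scalar"),
                         c(1L, 2L))
  meta <- build_metadata_matrix(tab, sch)
  expect_equal(dim(meta$rows), c(3, 3))     # 2 one-hot + 1 scalar
  expect_equal(meta$class_ids, c("a", "b", "c"))
  # scalars standardised
  expect_equal(mean(meta$rows[, "assay"]), 0)
  expect_equal(sd(meta$rows[, "assay"]), 1)
})

test_that("identical raw rows encode identically and row order is equivariant", {
  fx <- toy_metadata()
  meta <- fx$meta
  expect_identical(meta$rows["c1", ], meta$rows["c2", ])
  perm <- c(3, 1, 5, 2, 4)
  meta_p <- build_metadata_matrix(fx$table[perm, ], fx$schema)
  expect_equal(meta_p$rows, meta$rows[perm, ], ignore_attr = TRUE)
})

test_that("missing values and unknown columns are hard errors", {
  tab <- data.frame(class_id = c("a", "b"), tissue = c("x", NA),
                    assay = c(1, 2))
  sch <- metadata_schema(c("tissue", "assay"), c("categorical", "scalar"),
                         c(1L, 2L))
  expect_error(build_metadata_matrix(tab, sch), "missing")
  sch2 <- metadata_schema(c("tissue", "depth"), c("categorical", "scalar"),
                          c(1L, 2L))
  expect_error(build_metadata_matrix(data.frame(tissue = "x"), sch2),
               "lacks columns")
})

test_that("unseen categorical level maps to an all-zero block", {
  fx <- toy_metadata()
  new_tab <- fx$table[1, ]
  new_tab$tissue <- "kidney"
  enc <- mfd:::encode_metadata(fx$meta, new_tab)
  expect_true(all(enc$blocks$tissue == 0))
  expect_equal(ncol(enc$blocks$tissue), 3)  # heart / liver / brain
})

test_that("replicate classes receive bit-identical generated weights", {
  fx <- toy_metadata()
  emb1 <- mfd:::init_embedding(fx$meta, 1L, 6L, hidden = 8, seed = 31)
  emb2 <- mfd:::init_embedding(fx$meta, 2L, 6L, hidden = 8, seed = 32)
  cw <- compute_class_weights(fx$meta, emb1, emb2)
  expect_identical(cw$W1["c1", ], cw$W1["c2", ])
  expect_identical(cw$W2["c1", ], cw$W2["c2", ])
  # pure function: repeated calls bit-identical
  expect_identical(cw, compute_class_weights(fx$meta, emb1, emb2))
})

test_that("group-2 perturbations cannot touch group-1 weights (and vice versa)", {
  fx <- toy_metadata()
  emb1 <- mfd:::init_embedding(fx$meta, 1L, 6L, hidden = 8, seed = 31)
  emb2 <- mfd:::init_embedding(fx$meta, 2L, 6L, hidden = 8, seed = 32)
  cw <- compute_class_weights(fx$meta, emb1, emb2)
  tab2 <- fx$table
  tab2$depth[3] <- tab2$depth[3] + 5        # group-2 scalar
  meta2 <- mfd:::encode_metadata(fx$meta, tab2)
  cw2 <- compute_class_weights(meta2, emb1, emb2)
  expect_identical(cw$W1, cw2$W1)           # sensitivity exactly 0
  expect_false(identical(cw$W2[3, ], cw2$W2[3, ]))
  tab3 <- fx$table
  tab3$tissue[5] <- "liver"                 # group-1 categorical
  meta3 <- mfd:::encode_metadata(fx$meta, tab3)
  cw3 <- compute_class_weights(meta3, emb1, emb2)
  expect_identical(cw$W2, cw3$W2)
  expect_false(identical(cw$W1[5, ], cw3$W1[5, ]))
})

test_that("direct-forward scalar appears verbatim in the generated weights", {
  fx <- toy_metadata()
  sch <- metadata_schema(
    name = c("tissue", "target", "assay", "depth"),
    kind = c("categorical", "categorical", "categorical", "scalar"),
    group = c(1L, 1L, 2L, 2L),
    direct = c(FALSE, FALSE, FALSE, TRUE)
  )
  meta <- build_metadata_matrix(fx$table, sch)
  emb2 <- mfd:::init_embedding(meta, 2L, 4L, hidden = 8, seed = 33)
  W2 <- mfd:::embedding_forward(emb2, meta$blocks)
  expect_equal(W2[, 4], unname(meta$blocks$depth[, 1]))
})

test_that("replicate resolution groups by exact row equality", {
  fx <- toy_metadata()
  groups <- resolve_replicates(fx$meta)
  expect_equal(sort(lengths(groups), decreasing = TRUE), c(2, 1, 1, 1),
               ignore_attr = TRUE)
  expect_true(any(vapply(groups, function(g) identical(g, c(1L, 2L)),
                         logical(1))))
  # all-distinct rows -> singletons
  tab <- fx$table[3:5, ]
  meta <- build_metadata_matrix(tab, fx$schema)
  expect_equal(lengths(resolve_replicates(meta)), rep(1L, 3),
               ignore_attr = TRUE)
  # grouping invariant to uniform row scaling (brute-force pairwise oracle)
  scaled <- fx$meta
  scaled$rows <- scaled$rows * 3.7
  oracle <- outer(seq_len(5), seq_len(5), Vectorize(function(i, j) {
    all(fx$meta$rows[i, ] == fx$meta$rows[j, ])
  }))
  groups_s <- resolve_replicates(scaled)
  member <- integer(5)
  for (g in seq_along(groups_s)) member[groups_s[[g]]] <- g
  expect_equal(outer(member, member, "=="), oracle)
})

test_that("replicate predictions differ only through their biases", {
  fit <- tiny_fit()
  reps <- fit$replicates[lengths(fit$replicates) > 1]
  expect_gte(length(reps), 1)
  pair <- reps[[1]][1:2]
  set.seed(34)
  s <- matrix(rnorm(6 * 8, sd = 0.5), 6, 8)
  eta <- mfd:::add_bias(s %*% t(fit$weights$W), fit$bias)
  # same logit core z: eta_i - b_i identical across the replicate pair
  expect_equal(eta[, pair[1]] - fit$bias[pair[1]],
               eta[, pair[2]] - fit$bias[pair[2]],
               tolerance = 1e-12, ignore_attr = TRUE)
})
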