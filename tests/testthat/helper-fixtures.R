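# Shared fixtures, memoised per test run. Heavy objects (the full study, the
# tiny trained model) are built once and reused across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures, inherits = FALSE)) {
    assign(key, builder(), envir = .fixtures)
  }
  get(key, envir = .fixtures, inherits = FALSE)
}

tiny_config <- function(seed = 7) {
  synthetic_config(n_windows = 240, window_size = 96, n_chroms = 3,
                   seed = seed)
}

tiny_dataset <- function() memo("tiny_dataset", function() {
  generate_dataset(tiny_config())
})

tiny_encoder <- function(seed = 1) {
  encoder_config(window_size = 96, n_features = 8, filters = c(8, 8),
                 kernels = c(6, 4), pools = c(4, 4), seed = seed)
}

# a small trained model shared by VEP / attribution / objective tests
tiny_fit <- function() memo("tiny_fit", function() {
  mfd(tiny_dataset(), lambda = 0.01, encoder = tiny_encoder(), epochs = 2,
      batch_size = 32, seed = 3)
})

# the full desk-scale study backing the disentanglement, VEP-separation and
# attribution-contrast checks (one dataset + two fits per seed)
study_result <- function() memo("study", function() {
  disentanglement_study(seeds = 1:3)
})

study_medians <- function() summary(study_result())

# small metadata table exercising both groups, a replicate pair, and a
# scalar variable
toy_metadata <- function() {
  table <- data.frame(
    class_id = paste0("c", 1:5),
    tissue = c("heart", "heart", "liver", "liver", "brain"),
    target = c("acc", "acc", "acc", "mark", "mark"),
    assay = c("a1", "a1", "a2", "a2", "a1"),
    depth = c(10, 10, 20, 30, 25),
    stringsAsFactors = FALSE
  )
  schema <- metadata_schema(
    name = c("tissue", "target", "assay", "depth"),
    kind = c("categorical", "categorical", "categorical", "scalar"),
    group = c(1L, 1L, 2L, 2L)
  )
  list(table = table, schema = schema,
       meta = build_metadata_matrix(table, schema))
}

# independent scalar-loop Pearson correlation (oracle; no shared code with
# batch_pearson)
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  if (sxx == 0 || syy == 0) return(0)
  sxy / sqrt(sxx * syy)
}

# O(n^2) concordant-pair AUROC oracle
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  num <- 0
  for (p in pos) for (q in neg) {
    num <- num + (p > q) + 0.5 * (p == q)
  }
  num / (length(pos) * length(neg))
}
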