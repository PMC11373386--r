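test_that("generation is a deterministic function of the configuration", {
  ds1 <- generate_dataset(tiny_config(seed = 5))
  ds2 <- generate_dataset(tiny_config(seed = 5))
  expect_identical(ds1$genome, ds2$genome)
  expect_identical(ds1$labels, ds2$labels)
  expect_identical(ds1$ledger, ds2$ledger)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(ds1, d1)
  write_dataset(ds2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  ds3 <- generate_dataset(tiny_config(seed = 6))
  expect_false(identical(ds1$genome, ds3$genome))
})

test_that("motif planting is local and respects the mutation rate limits", {
  host <- strrep("A", 30)
  out <- plant_motif(host, "CGCG", 11, mutation_rate = 0)
  expect_identical(substring(out, 11, 14), "CGCG")
  expect_identical(substring(out, 1, 10), strrep("A", 10))
  expect_identical(substring(out, 15, 30), strrep("A", 16))
  set.seed(61)
  full <- plant_motif(host, "CGCGCGCG", 5, mutation_rate = 1)
  planted <- strsplit(substring(full, 5, 12), "")[[1]]
  expect_true(all(planted != strsplit("CGCGCGCG", "")[[1]]))
  expect_error(plant_motif(host, "CGCG", 29), "fit")
})

test_that("planted activity matches configured density and copy number", {
  ds <- tiny_dataset()
  cfg <- ds$config
  active <- vapply(ds$ledger, function(e) !is.na(e$combo), logical(1))
  n <- length(active)
  # binomial oracle: observed count within the central 99.9% of the
  # configured planting distribution
  ci <- qbinom(c(5e-4, 1 - 5e-4), n, cfg$peak_density)
  expect_gte(sum(active), ci[1])
  expect_lte(sum(active), ci[2])
  copies <- vapply(ds$ledger[active], function(e) length(e$motif_positions),
                   integer(1))
  expect_true(all(copies == cfg$motif_copies))
})

test_that("labels are recomputable from the ledger alone", {
  ds <- tiny_dataset()
  expect_identical(mfd:::recompute_labels(ds), ds$labels)
})

test_that("replicate classes share their label rule up to the noise draw", {
  ds <- tiny_dataset()
  ct <- ds$config$class_table
  # exp1/exp2 have identical metadata rows
  expect_identical(ct[1, -1], ct[2, -1], ignore_attr = TRUE)
  # observed labels differ only where a recorded noise flip hit one of them
  diff <- which(ds$labels[, 1] != ds$labels[, 2])
  flips <- vapply(ds$ledger[diff], function(e) {
    any(c(e$fn_classes, e$fp_classes) %in% c(1L, 2L))
  }, logical(1))
  expect_true(all(flips))
})

test_that("planted variants are VCF-valid and causally placed", {
  ds <- tiny_dataset()
  vars <- make_variants(ds, n_causal = 15, n_neutral = 10, seed = 3)
  expect_true(all(vars$ref != vars$alt))
  # REF always matches the genome
  for (i in seq_len(nrow(vars))) {
    expect_identical(substring(ds$genome[[vars$chrom[i]]], vars$pos[i],
                               vars$pos[i]), vars$ref[i])
  }
  # causal variants sit inside a ledger motif interval
  k <- nchar(ds$config$motifs[[1]])
  for (i in which(vars$causal)) {
    w <- which(ds$windows$chrom == vars$chrom[i] &
                 ds$windows$start < vars$pos[i] &
                 ds$windows$end >= vars$pos[i])
    e <- ds$ledger[[w]]
    rel <- vars$pos[i] - e$start
    inside <- any(rel >= e$motif_positions &
                    rel <= e$motif_positions + k - 1L)
    expect_true(inside)
  }
  # no causal requested -> all neutral
  vars0 <- make_variants(ds, n_causal = 0, n_neutral = 5, seed = 4)
  expect_false(any(vars0$causal))
})

test_that("the biological factor is decodable from raw 4-mer counts", {
  ds <- tiny_dataset()
  active <- which(vapply(ds$ledger, function(e) !is.na(e$combo), logical(1)))
  seqs <- substring(ds$genome[ds$windows$chrom[active]],
                    ds$windows$start[active] + 1L, ds$windows$end[active])
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(unname(seqs)), width = 4)
  combo <- vapply(ds$ledger[active], function(e) e$combo, character(1))
  acc <- factor_probe(counts, combo, seed = 8)
  expect_gt(acc$accuracy, acc$chance + 0.1)
})

test_that("datasets round-trip through the plain-text directory format", {
  ds <- tiny_dataset()
  dir <- tempfile()
  vars <- make_variants(ds, n_causal = 5, n_neutral = 5, seed = 9)
  write_dataset(ds, dir, variants = vars)
  back <- read_dataset(dir)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$genome, ds$genome, ignore_attr = TRUE)
  expect_identical(back$seq_codes, ds$seq_codes)
  expect_equal(back$window_size, ds$window_size)
  expect_equal(length(back$ledger), length(ds$ledger))
  expect_identical(back$ledger[[3]]$motif_positions,
                   ds$ledger[[3]]$motif_positions)
})
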