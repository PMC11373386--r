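# Synthetic study generator: multi-class peak labels over pseudo-chromosomes
# where the biological generative factors (tissue x target, each combination
# tied to a planted sequence motif) and the technical factors (assay and lab,
# acting as GC-linked label noise) are known exactly, so disentanglement is
# directly testable. The per-window ledger suffices to recompute every label.

#' Synthetic study configuration
#'
#' Defines the generative factors of the synthetic peak dataset. Each
#' biological factor combination (tissue, target) is tied to a consensus
#' motif planted in windows that are truly active for that combination.
#' Technical factors act as sequence-correlated label noise: the
#' false-positive rate of a class depends on window GC content with a sign
#' set by its assay level and a scale set by its lab level, so technical
#' structure is learnable from sequence, as real composition biases are.
#'
#' @param n_windows Total number of fixed-width windows.
#' @param window_size Window width in bp.
#' @param n_chroms Number of pseudo-chromosomes (`chrS1..chrSn`); the last is
#'   conventionally held out for testing.
#' @param class_table Data frame with columns `class_id`, `tissue`, `target`,
#'   `assay`, `lab` (one row per output class). The default defines 8
#'   classes, including one replicate pair with identical metadata.
#' @param motifs Named list mapping `"tissue.target"` combinations to
#'   consensus motif strings.
#' @param peak_density Probability that a window is truly active for some
#'   biological combination.
#' @param motif_copies Motif copies planted per active window.
#' @param mutation_rate Per-base mutation probability when planting.
#' @param gc_range Range of per-window target GC content.
#' @param tech_noise Base false-positive label noise rate (scaled by GC and
#'   the technical factor levels).
#' @param fn_rate False-negative rate applied to truly active labels.
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the configuration.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_windows = 20000L, window_size = 1152L,
                             n_chroms = 4L,
                             class_table = default_class_table(),
                             motifs = default_motifs(),
                             peak_density = 0.3, motif_copies = 2L,
                             mutation_rate = 0.05,
                             gc_range = c(0.25, 0.75),
                             tech_noise = 0.15, fn_rate = 0.05,
                             seed = 1L) {
  stopifnot(n_windows >= n_chroms, window_size >= 32L,
            peak_density >= 0, peak_density <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            tech_noise >= 0, fn_rate >= 0,
            all(c("class_id", "tissue", "target", "assay", "lab") %in%
                  colnames(class_table)))
  combos <- unique(paste(class_table$tissue, class_table$target, sep = "."))
  missing <- setdiff(combos, names(motifs))
  if (length(missing)) {
    stop("no motif defined for biological combination(s): ",
         paste(missing, collapse = ", "))
  }
  structure(list(n_windows = as.integer(n_windows),
                 window_size = as.integer(window_size),
                 n_chroms = as.integer(n_chroms),
                 class_table = class_table, motifs = motifs,
                 peak_density = peak_density,
                 motif_copies = as.integer(motif_copies),
                 mutation_rate = mutation_rate, gc_range = gc_range,
                 tech_noise = tech_noise, fn_rate = fn_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_class_table <- function() {
  data.frame(
    class_id = paste0("exp", 1:8),
    tissue = c("heart", "heart", "heart", "liver", "liver", "liver", "heart", "liver"),
    target = c("accessible", "accessible", "mark", "accessible", "accessible",
               "mark", "mark", "mark"),
    assay = c("assayA", "assayA", "assayB", "assayA", "assayB", "assayA",
              "assayA", "assayB"),
    lab = c("lab1", "lab1", "lab1", "lab2", "lab2", "lab1", "lab2", "lab2"),
    stringsAsFactors = FALSE
  )
}

#' @rdname synthetic_config
#' @export
default_motifs <- function() {
  list(heart.accessible = "TGATAAGG",
       heart.mark = "CACGTGAC",
       liver.accessible = "TTAATCCG",
       liver.mark = "GGACGTCA")
}

default_schema <- function() {
  metadata_schema(name = c("tissue", "target", "assay", "lab"),
                  kind = "categorical",
                  group = c(1L, 1L, 2L, 2L))
}

# sample() without the scalar-x pitfall
sample_vec <- function(x, size) x[sample.int(length(x), size)]

# mutate planted bases in code space: each base independently replaced by a
# uniformly chosen *different* base with probability `rate`
mutate_codes <- function(codes, rate) {
  if (rate <= 0) return(codes)
  hit <- which(stats::runif(length(codes)) < rate)
  for (i in hit) {
    codes[i] <- sample(setdiff(1:4, codes[i]), 1L)
  }
  codes
}

#' Plant a motif into a sequence
#'
#' Replaces the substring starting at `position` by the motif consensus,
#' mutating each planted base to a different base with probability
#' `mutation_rate`. Flanking sequence is untouched.
#'
#' @param seq Character scalar (the host sequence).
#' @param motif Character scalar (the consensus).
#' @param position 1-based start position; `position + nchar(motif) - 1`
#'   must not exceed `nchar(seq)`.
#' @param mutation_rate Per-base mutation probability in `[0, 1]`.
#' @return The modified sequence string.
#' @export
plant_motif <- function(seq, motif, position, mutation_rate = 0) {
  L <- nchar(seq)
  k <- nchar(motif)
  if (position < 1L || position + k - 1L > L) {
    stop("motif does not fit at position ", position)
  }
  codes <- seq_to_base_codes(seq)
  codes[position:(position + k - 1L)] <-
    mutate_codes(seq_to_base_codes(motif), mutation_rate)
  base_codes_to_seq(codes)
}

#' Generate a synthetic peak dataset
#'
#' Emits a fully seeded dataset: pseudo-chromosome sequences, fixed-width
#' windows, a binary label matrix (windows x classes), the per-class
#' metadata table with its schema, and a ground-truth ledger from which
#' every label can be recomputed.
#'
#' Windows draw a target GC content; truly active windows carry planted
#' copies of the motif of their biological combination. A class labels a
#' window 1 when the window is active for the class's (tissue, target)
#' combination, subject to false negatives at `fn_rate` and GC-dependent
#' false positives whose rate is `tech_noise * g` for assay level B and
#' `tech_noise * (1 - g)` for assay level A (with `g` the realised window
#' GC), scaled by 1.5 for lab2 and 0.5 for lab1.
#'
#' @param cfg A [synthetic_config()].
#' @return An object of class `mfd_dataset`: `windows` (BED-like data
#'   frame), `seq_codes` (dinucleotide code matrix for the model),
#'   `labels` (binary matrix), `genome` (named character vector),
#'   `metadata_table`, `schema`, `ledger` and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  L <- cfg$window_size
  n <- cfg$n_windows
  ct <- cfg$class_table
  O <- nrow(ct)
  combo_of_class <- paste(ct$tissue, ct$target, sep = ".")
  combos <- names(cfg$motifs)
  motif_codes <- lapply(cfg$motifs, function(m) seq_to_base_codes(m))

  with_seed(cfg$seed, {
    per_chrom <- rep(n %/% cfg$n_chroms, cfg$n_chroms)
    per_chrom[cfg$n_chroms] <- per_chrom[cfg$n_chroms] + n %% cfg$n_chroms
    chrom <- rep(paste0("chrS", seq_len(cfg$n_chroms)), per_chrom)
    within <- unlist(lapply(per_chrom, seq_len))
    start <- (within - 1L) * L

    base_codes <- matrix(0L, n, L)
    labels <- matrix(0L, n, O, dimnames = list(NULL, ct$class_id))
    ledger <- vector("list", n)
    margin <- 4L

    for (w in seq_len(n)) {
      g_target <- stats::runif(1, cfg$gc_range[1], cfg$gc_range[2])
      bc <- sample.int(4L, L, replace = TRUE,
                       prob = c((1 - g_target) / 2, g_target / 2,
                                g_target / 2, (1 - g_target) / 2))
      active <- stats::runif(1) < cfg$peak_density
      combo <- NA_character_
      motif_pos <- integer(0)
      if (active) {
        combo <- sample(combos, 1L)
        mc <- motif_codes[[combo]]
        k <- length(mc)
        slots <- seq(margin + 1L, L - k - margin, by = k + 2L)
        motif_pos <- sort(sample_vec(slots, min(cfg$motif_copies, length(slots))))
        for (pos in motif_pos) {
          bc[pos:(pos + k - 1L)] <- mutate_codes(mc, cfg$mutation_rate)
        }
      }
      gc <- mean(bc == 2L | bc == 3L)
      base <- active & (combo_of_class == combo)
      fn <- base & (stats::runif(O) < cfg$fn_rate)
      p_fp <- cfg$tech_noise *
        ifelse(ct$assay == "assayB", gc, 1 - gc) *
        ifelse(ct$lab == "lab2", 1.5, 0.5)
      fp <- !base & (stats::runif(O) < p_fp)
      labels[w, ] <- as.integer((base & !fn) | fp)
      base_codes[w, ] <- bc
      ledger[[w]] <- list(window = w, chrom = chrom[w], start = start[w],
                          gc = gc, combo = combo,
                          motif_positions = motif_pos,
                          fn_classes = which(fn), fp_classes = which(fp))
    }

    genome <- vapply(split(seq_len(n), factor(chrom, unique(chrom))),
                     function(idx) {
                       intToUtf8(c(78L, 65L, 67L, 71L, 84L)[
                         t(base_codes[idx, , drop = FALSE]) + 1L])
                     }, character(1))

    seq_codes <- matrix(0L, n, L - 1L)
    for (w in seq_len(n)) {
      seq_codes[w, ] <- base_to_dinuc_codes(base_codes[w, ])
    }

    meta <- ct[, c("class_id", "tissue", "target", "assay", "lab")]
    structure(list(
      windows = data.frame(chrom = chrom, start = start, end = start + L,
                           id = paste0("w", seq_len(n)),
                           stringsAsFactors = FALSE),
      seq_codes = seq_codes, labels = labels, genome = genome,
      window_size = L, metadata_table = meta, schema = default_schema(),
      ledger = ledger, config = cfg
    ), class = "mfd_dataset")
  })
}

#' @export
print.mfd_dataset <- function(x, ...) {
  cat("Synthetic/loaded peak dataset\n")
  cat(sprintf("  %d windows of %d bp over %d chromosome(s); %d classes\n",
              nrow(x$windows), x$window_size, length(unique(x$windows$chrom)),
              ncol(x$labels)))
  cat(sprintf("  positive label rate: %.3f\n", mean(x$labels)))
  invisible(x)
}

# recompute the label matrix purely from the ledger and class table
# (invariant: must equal dataset$labels exactly)
recompute_labels <- function(ds) {
  ct <- ds$config$class_table
  combo_of_class <- paste(ct$tissue, ct$target, sep = ".")
  out <- matrix(0L, nrow(ds$labels), ncol(ds$labels),
                dimnames = dimnames(ds$labels))
  for (w in seq_along(ds$ledger)) {
    e <- ds$ledger[[w]]
    base <- !is.na(e$combo) & (combo_of_class == e$combo)
    lab <- base
    lab[e$fn_classes] <- FALSE
    lab[e$fp_classes] <- TRUE
    out[w, ] <- as.integer(lab)
  }
  out
}

#' Plant causal and neutral variants
#'
#' Causal variants substitute a consensus-matching base inside a planted
#' motif instance; neutral variants substitute a base in motif-free
#' background windows. Both are placed so that a model window centred on the
#' variant (plus small shifts) fits inside the chromosome, and the REF
#' allele always matches the genome.
#'
#' @param dataset An `mfd_dataset` with a ground-truth ledger.
#' @param n_causal,n_neutral Number of variants of each kind.
#' @param seed Integer seed.
#' @param max_shift Largest window shift the variants must accommodate.
#' @return Data frame with columns `chrom`, `pos` (1-based), `id`, `ref`,
#'   `alt`, `causal`, `combo` (biological combination of the disrupted
#'   motif, `NA` for neutral).
#' @export
make_variants <- function(dataset, n_causal = 100L, n_neutral = 100L,
                          seed = 1L, max_shift = 2L) {
  stopifnot(inherits(dataset, "mfd_dataset"), !is.null(dataset$ledger))
  L <- dataset$window_size
  cfg <- dataset$config
  chrom_len <- nchar(dataset$genome)
  ok_window <- function(ch, pos) {
    lo <- pos - L %/% 2L - max_shift
    hi <- pos + L %/% 2L + max_shift
    lo >= 1L && hi <= chrom_len[[ch]]
  }
  with_seed(seed, {
    has_motif <- which(vapply(dataset$ledger,
                              function(e) length(e$motif_positions) > 0,
                              logical(1)))
    no_motif <- which(vapply(dataset$ledger,
                             function(e) length(e$motif_positions) == 0,
                             logical(1)))
    if (n_causal > 0L && length(has_motif) == 0L) {
      stop("no planted motif instances available for causal variants")
    }
    rows <- list()
    take_causal <- sample_vec(has_motif, min(n_causal, length(has_motif)))
    for (w in take_causal) {
      e <- dataset$ledger[[w]]
      mc <- seq_to_base_codes(cfg$motifs[[e$combo]])
      pos_in_win <- sample_vec(e$motif_positions, 1L)
      win_seq <- substring(dataset$genome[[e$chrom]],
                           e$start + pos_in_win,
                           e$start + pos_in_win + length(mc) - 1L)
      planted <- seq_to_base_codes(win_seq)
      informative <- which(planted == mc & planted > 0L)
      if (!length(informative)) next
      off <- sample_vec(informative, 1L)
      pos <- e$start + pos_in_win + off - 1L   # 1-based genome position
      if (!ok_window(e$chrom, pos)) next
      ref <- .BASES[planted[off]]
      alt <- sample(setdiff(.BASES, ref), 1L)
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = e$chrom, pos = pos, ref = ref, alt = alt,
                   causal = TRUE, combo = e$combo, stringsAsFactors = FALSE)
    }
    take_neutral <- sample_vec(no_motif, min(n_neutral, length(no_motif)))
    for (w in take_neutral) {
      e <- dataset$ledger[[w]]
      off <- sample.int(L - 8L, 1L) + 4L
      pos <- e$start + off
      if (!ok_window(e$chrom, pos)) next
      base <- substring(dataset$genome[[e$chrom]], pos, pos)
      if (base == "N") next
      alt <- sample(setdiff(.BASES, base), 1L)
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = e$chrom, pos = pos, ref = base, alt = alt,
                   causal = FALSE, combo = NA_character_,
                   stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$id <- paste0("var", seq_len(nrow(out)))
    out[, c("chrom", "pos", "id", "ref", "alt", "causal", "combo")]
  })
}

#' Write a dataset to a directory of plain-text files
#'
#' Emits `genome.fa`, `windows.bed`, `labels.tsv` (BED-like columns followed
#' by one 0/1 column per class), `metadata.tsv`, `metadata.schema.tsv`,
#' `ledger.jsonl`, and `variants.vcf` plus `variants.truth.tsv` when a
#' variant table is supplied.
#'
#' @param dataset An `mfd_dataset`.
#' @param dir Output directory (created if needed).
#' @param variants Optional variant table from [make_variants()].
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir, variants = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(dataset$genome)
  Biostrings::writeXStringSet(dna, file.path(dir, "genome.fa"))
  utils::write.table(dataset$windows, file.path(dir, "windows.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_label_matrix(dataset$windows, dataset$labels,
                     file.path(dir, "labels.tsv"))
  utils::write.table(dataset$metadata_table, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_metadata_schema(dataset$schema, file.path(dir, "metadata.schema.tsv"))
  if (!is.null(dataset$ledger)) {
    con <- file(file.path(dir, "ledger.jsonl"), "w")
    for (e in dataset$ledger) {
      writeLines(jsonlite::toJSON(e, auto_unbox = TRUE, null = "null"), con)
    }
    close(con)
  }
  if (!is.null(variants)) {
    write_variants_vcf(variants, file.path(dir, "variants.vcf"))
    utils::write.table(variants, file.path(dir, "variants.truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' Reconstructs the in-memory dataset (including model-ready dinucleotide
#' codes) from the plain-text files.
#'
#' @param dir Directory containing `genome.fa`, `labels.tsv`,
#'   `metadata.tsv` and `metadata.schema.tsv`.
#' @return An `mfd_dataset` (without ledger/config unless present on disk).
#' @export
read_dataset <- function(dir) {
  dna <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  genome <- stats::setNames(as.character(dna), names(dna))
  lm <- read_label_matrix(file.path(dir, "labels.tsv"))
  windows <- lm$windows
  L <- unique(windows$end - windows$start)
  if (length(L) != 1L) stop("windows are not fixed-width")
  seqs <- substring(genome[windows$chrom], windows$start + 1L, windows$end)
  seq_codes <- seqs_to_dinuc_matrix(unname(seqs))
  meta <- utils::read.table(file.path(dir, "metadata.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  schema <- read_metadata_schema(file.path(dir, "metadata.schema.tsv"))
  ledger <- NULL
  lp <- file.path(dir, "ledger.jsonl")
  if (file.exists(lp)) {
    ledger <- lapply(readLines(lp), function(l) {
      e <- jsonlite::fromJSON(l)
      e$motif_positions <- as.integer(e$motif_positions)
      e$fn_classes <- as.integer(e$fn_classes)
      e$fp_classes <- as.integer(e$fp_classes)
      if (is.null(e$combo)) e$combo <- NA_character_
      e
    })
  }
  structure(list(windows = windows, seq_codes = seq_codes,
                 labels = lm$labels, genome = genome, window_size = L,
                 metadata_table = meta, schema = schema, ledger = ledger,
                 config = NULL),
            class = "mfd_dataset")
}

# minimal VCF 4.2 writer for the synthetic SNVs (reading goes through vcfR)
write_variants_vcf <- function(variants, path) {
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=CAUSAL,Number=0,Type=Flag,Description=\"Disrupts a planted motif\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  info <- ifelse(variants$causal, "CAUSAL", ".")
  writeLines(paste(variants$chrom, variants$pos, variants$id, variants$ref,
                   variants$alt, ".", "PASS", info, sep = "\t"), con)
  close(con)
  invisible(path)
}
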