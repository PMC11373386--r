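# Readers and writers for the plain-text interchange formats: BED-like
# binary label matrices, VCF variants (REF-verified against the genome),
# and model checkpoints.

#' Read a binary label matrix
#'
#' Expects a TSV with header whose first columns are BED-like
#' (`chrom`, `start`, `end`, optionally `id`) followed by one strictly 0/1
#' column per class.
#'
#' @param path File path.
#' @return List with `windows` (data frame) and `labels` (integer matrix
#'   with class-named columns).
#' @export
read_label_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- intersect(c("chrom", "start", "end", "id"), colnames(df))
  if (!all(c("chrom", "start", "end") %in% fixed)) {
    stop("label matrix must start with chrom/start/end columns")
  }
  class_cols <- setdiff(colnames(df), fixed)
  if (!length(class_cols)) stop("no class columns in label matrix")
  if (anyDuplicated(class_cols)) stop("duplicate class names in label matrix")
  labels <- as.matrix(df[, class_cols, drop = FALSE])
  if (!all(labels %in% c(0, 1))) stop("label matrix entries must be 0 or 1")
  storage.mode(labels) <- "integer"
  windows <- df[, fixed, drop = FALSE]
  if (!"id" %in% fixed) windows$id <- paste0("w", seq_len(nrow(windows)))
  list(windows = windows, labels = labels)
}

#' @rdname read_label_matrix
#' @param windows BED-like data frame (`chrom`, `start`, `end`, `id`).
#' @param labels Binary matrix with one named column per class.
#' @export
write_label_matrix <- function(windows, labels, path) {
  stopifnot(nrow(windows) == nrow(labels))
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  out <- cbind(windows[, c("chrom", "start", "end", "id")],
               as.data.frame(labels, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SNVs from a VCF, verifying REF alleles
#'
#' Retains single-nucleotide records only; each record's REF allele is
#' checked against the genome, and mismatching or out-of-range records are
#' dropped with a per-record note. Positions stay 1-based in the returned
#' table (the package converts to window coordinates internally).
#'
#' @param path VCF 4.x file path.
#' @param genome Named character vector of chromosome sequences (or a
#'   `DNAStringSet`).
#' @return Data frame with `chrom`, `pos`, `id`, `ref`, `alt` and `causal`
#'   (from a `CAUSAL` INFO flag when present); dropped-record counts in
#'   attribute `dropped`.
#' @export
read_variants <- function(path, genome) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                      stringsAsFactors = FALSE)
  causal <- grepl("(^|;)CAUSAL(;|=|$)", fx$INFO %||% "")
  out <- data.frame(chrom = fx$CHROM, pos = as.integer(fx$POS),
                    id = fx$ID, ref = fx$REF, alt = fx$ALT,
                    causal = causal, stringsAsFactors = FALSE)
  dropped <- c(non_snv = 0L, ref_mismatch = 0L, out_of_range = 0L)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (nchar(out$ref[i]) != 1L || nchar(out$alt[i]) != 1L ||
        grepl(",", out$alt[i], fixed = TRUE)) {
      keep[i] <- FALSE
      dropped["non_snv"] <- dropped["non_snv"] + 1L
      next
    }
    cs <- genome[[out$chrom[i]]]
    if (is.null(cs) || out$pos[i] < 1L || out$pos[i] > nchar(cs)) {
      keep[i] <- FALSE
      dropped["out_of_range"] <- dropped["out_of_range"] + 1L
      message("dropping ", out$id[i], ": position off chromosome")
      next
    }
    if (substring(cs, out$pos[i], out$pos[i]) != out$ref[i]) {
      keep[i] <- FALSE
      dropped["ref_mismatch"] <- dropped["ref_mismatch"] + 1L
      message("dropping ", out$id[i], ": REF does not match genome")
    }
  }
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint with the configuration embedded and a format
#' version tag.
#'
#' @param object A fitted `mfd` model.
#' @param path Checkpoint file path.
#' @param keep_dataset Whether to embed the training dataset (larger file,
#'   but enables [residuals.mfd()] and default genomes after reload).
#' @return [read_mfd()] returns the restored `mfd` object.
#' @export
write_mfd <- function(object, path, keep_dataset = TRUE) {
  stopifnot(inherits(object, "mfd"))
  if (!keep_dataset) object$dataset <- NULL
  saveRDS(list(format = "mfd-checkpoint", version = 1L, model = object), path)
  invisible(path)
}

#' @rdname write_mfd
#' @export
read_mfd <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "mfd-checkpoint")) stop("not an mfd checkpoint")
  x$model
}
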