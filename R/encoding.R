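# Sequence encoding: overlapping dinucleotide one-hot representation with
# single-base attribution projection. Channel order is alphabetical over
# ordered pairs (AA, AC, ..., TT); any pair containing N is all-zero and
# masked.

.BASES <- c("A", "C", "G", "T")

#' Ordered dinucleotide alphabet
#'
#' The 16 ordered dinucleotides in alphabetical order (`AA`, `AC`, ...,
#' `TT`). This fixed ordering defines the channel axis of
#' [encode_sequence()].
#'
#' @return Character vector of length 16.
#' @export
dinucleotides <- function() {
  paste0(rep(.BASES, each = 4L), rep(.BASES, 4L))
}

# byte lookup: A/C/G/T -> 1..4, N -> 0, anything else NA (case-folded)
.base_lookup <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("a")] <- 1L
  v[utf8ToInt("C")] <- 2L; v[utf8ToInt("c")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("g")] <- 3L
  v[utf8ToInt("T")] <- 4L; v[utf8ToInt("t")] <- 4L
  v[utf8ToInt("N")] <- 0L; v[utf8ToInt("n")] <- 0L
  v
})

# character string -> integer base codes (1..4, 0 for N); errors on anything
# outside the {A,C,G,T,N} alphabet
seq_to_base_codes <- function(bases) {
  stopifnot(is.character(bases), length(bases) == 1L)
  codes <- .base_lookup[utf8ToInt(bases)]
  if (anyNA(codes)) {
    bad <- unique(strsplit(bases, "")[[1]][is.na(codes)])
    stop("invalid sequence characters: ", paste(bad, collapse = ", "))
  }
  codes
}

base_codes_to_seq <- function(codes) {
  chars <- c("N", .BASES)[codes + 1L]
  paste(chars, collapse = "")
}

# base codes (length L) -> dinucleotide codes (length L-1); 0 where either
# base is N
base_to_dinuc_codes <- function(bc) {
  L <- length(bc)
  stopifnot(L >= 2L)
  b1 <- bc[-L]
  b2 <- bc[-1L]
  ifelse(b1 > 0L & b2 > 0L, (b1 - 1L) * 4L + b2, 0L)
}

#' Encode a DNA sequence as overlapping dinucleotide one-hots
#'
#' Position `k` of the encoding corresponds to the ordered base pair at
#' sequence positions `(k, k+1)`. Positions where either base is `N` are
#' all-zero across channels and flagged in the mask.
#'
#' @param seq Character scalar over the alphabet `A,C,G,T,N`
#'   (case-insensitive), length at least 2.
#' @return An object of class `encoded_sequence`: a list with `onehot`
#'   (an `(L-1) x 16` matrix with columns named by [dinucleotides()]),
#'   `mask` (logical, `FALSE` where a pair contains `N`) and `codes`
#'   (integer dinucleotide codes, 0 for masked positions).
#' @examples
#' enc <- encode_sequence("ACGT")
#' colnames(enc$onehot)[apply(enc$onehot, 1, which.max)]
#' @export
encode_sequence <- function(seq) {
  bc <- seq_to_base_codes(seq)
  if (length(bc) < 2L) stop("sequence must have length >= 2")
  dc <- base_to_dinuc_codes(bc)
  P <- length(dc)
  onehot <- matrix(0, P, 16L, dimnames = list(NULL, dinucleotides()))
  keep <- which(dc > 0L)
  onehot[cbind(keep, dc[keep])] <- 1
  structure(list(onehot = onehot, mask = dc > 0L, codes = dc),
            class = "encoded_sequence")
}

#' Decode dinucleotide codes back to a string
#'
#' Inverse of the encoding for N-free input: recovers the base string from
#' the argmax channel per position.
#'
#' @param codes Integer dinucleotide codes (1..16), no masked positions.
#' @return Character scalar of length `length(codes) + 1`.
#' @export
decode_dinucleotides <- function(codes) {
  stopifnot(all(codes >= 1L), all(codes <= 16L))
  b1 <- (codes - 1L) %/% 4L + 1L
  b2 <- (codes - 1L) %% 4L + 1L
  paste(c(.BASES[b1], .BASES[b2[length(b2)]]), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Applying it twice
#' returns the input.
#'
#' @param seq Character scalar over `A,C,G,T,N` (case-insensitive).
#' @return Character scalar.
#' @examples
#' reverse_complement("AAAC") # "GTTT"
#' @export
reverse_complement <- function(seq) {
  seq_to_base_codes(seq) # alphabet validation
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", seq)
  intToUtf8(rev(utf8ToInt(comp)))
}

#' Project per-dinucleotide scores onto bases
#'
#' Each dinucleotide position's score is assigned to its first nucleotide;
#' the final base receives 0. Total score is conserved.
#'
#' @param position_scores Numeric vector of length `L - 1`.
#' @param L Integer sequence length.
#' @return Numeric vector of length `L`.
#' @export
project_scores_to_bases <- function(position_scores, L) {
  if (length(position_scores) != L - 1L) {
    stop("expected ", L - 1L, " position scores, got ", length(position_scores))
  }
  c(position_scores, 0)
}

# batch one-hot: integer dinucleotide code matrix (N x P) -> array (N, P, 16)
encode_batch <- function(codes) {
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = 1L)
  N <- nrow(codes)
  P <- ncol(codes)
  X <- array(0, c(N, P, 16L))
  keep <- which(codes > 0L)
  if (length(keep)) {
    rows <- ((keep - 1L) %% N) + 1L
    cols <- ((keep - 1L) %/% N) + 1L
    X[cbind(rows, cols, codes[keep])] <- 1
  }
  X
}

# character vector of window sequences -> dinucleotide code matrix (N x L-1)
seqs_to_dinuc_matrix <- function(seqs) {
  t(vapply(seqs,
           function(s) base_to_dinuc_codes(seq_to_base_codes(s)),
           integer(nchar(seqs[[1]]) - 1L), USE.NAMES = FALSE))
}
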