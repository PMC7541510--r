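# Column order A,C,G,U is fixed package-wide and recorded in every model
# checkpoint; changing it breaks checkpoint portability.

seq_to_ints <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], RNA_ALPHABET)
}

#' One-hot encode a sequence
#'
#' @param seq Character scalar over A/C/G/U (T normalized to U).
#' @return length x 4 indicator matrix with columns A,C,G,U.
#' @examples
#' one_hot("ACGU")
#' @export
one_hot <- function(seq) {
  seq <- normalize_seq(seq)
  idx <- seq_to_ints(seq)
  m <- matrix(0, nrow = length(idx), ncol = 4L,
              dimnames = list(NULL, RNA_ALPHABET))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Decode a one-hot (or relaxed probability) matrix back to letters
#'
#' Takes the per-row argmax, so it also discretizes a relaxed position
#' weight matrix.
#'
#' @param m length x 4 numeric matrix, columns A,C,G,U.
#' @return Character scalar.
#' @export
one_hot_decode <- function(m) {
  paste(RNA_ALPHABET[max.col(m, ties.method = "first")], collapse = "")
}

# flat batch encoding used by the CNN: row = sequence, column (p-1)*4+b
encode_batch <- function(seqs, len = 59L) {
  n <- length(seqs)
  out <- matrix(0, nrow = n, ncol = len * 4L)
  for (i in seq_len(n)) {
    idx <- seq_to_ints(seqs[i])
    if (length(idx) != len) stop("sequence ", i, " has length ", length(idx),
                                 ", expected ", len, call. = FALSE)
    out[i, (seq_len(len) - 1L) * 4L + idx] <- 1
  }
  out
}

#' Fixed k-mer vocabulary
#'
#' All 4^k k-mers in lexicographic A<C<G<U order, with dense integer ids
#' starting at 1. Stored alongside language-model checkpoints.
#'
#' @param k Token width.
#' @return Named integer vector mapping k-mer to id.
#' @export
kmer_vocabulary <- function(k = 3L) {
  grids <- rev(expand.grid(rep(list(RNA_ALPHABET), k),
                           stringsAsFactors = FALSE))
  kmers <- do.call(paste0, grids)
  kmers <- sort(kmers)
  setNames(seq_along(kmers), kmers)
}

#' Tokenize a sequence into k-mers
#'
#' Non-overlapping by default (stride = k), the "words" of the toehold
#' language model: a 59-mer yields 19 tokens and the trailing 2-nt residue is
#' dropped.
#'
#' @param seq Character scalar.
#' @param k Token width (default 3).
#' @param stride Step between token starts (default 3).
#' @return List with `tokens` (character), `ids` (integer, per
#'   [kmer_vocabulary()]), `k`, `stride`.
#' @examples
#' tokenize("AUGGCA")$tokens
#' @export
tokenize <- function(seq, k = 3L, stride = 3L) {
  stopifnot(k >= 1L, stride >= 1L)
  seq <- normalize_seq(seq)
  L <- nchar(seq)
  if (k > L) {
    return(list(tokens = character(0), ids = integer(0), k = k,
                stride = stride))
  }
  starts <- seq.int(1L, L - k + 1L, by = stride)
  tokens <- substring(seq, starts, starts + k - 1L)
  vocab <- kmer_vocabulary(k)
  list(tokens = tokens, ids = unname(vocab[tokens]), k = k, stride = stride)
}

# ids for a batch of equal-length sequences -> n x T integer matrix
tokenize_batch <- function(seqs, k = 3L, stride = 3L) {
  toks <- lapply(seqs, function(s) tokenize(s, k, stride)$ids)
  lens <- lengths(toks)
  if (length(unique(lens)) > 1L) stop("sequences tokenize to unequal lengths")
  matrix(unlist(toks), nrow = length(seqs), byrow = TRUE)
}

#' Untokenize non-overlapping tokens
#'
#' Concatenation; recovers the sequence up to the dropped tail when
#' stride = k.
#'
#' @param tokens Character vector of k-mers.
#' @return Character scalar.
#' @export
untokenize <- function(tokens) paste(tokens, collapse = "")

CGR_CORNERS <- matrix(c(-1, -1,   # A
                        -1,  1,   # C
                         1,  1,   # G
                         1, -1),  # U
                      nrow = 4, byrow = TRUE,
                      dimnames = list(RNA_ALPHABET, c("x", "y")))

#' Chaos-game representation of a sequence
#'
#' Iterated midpoint map starting at the origin: each base pulls the point
#' halfway toward its corner of the square, A = (-1,-1), C = (-1,1),
#' G = (1,1), U = (1,-1). Together with the length the final point encodes
#' the sequence losslessly.
#'
#' @param seq Character vector of sequences.
#' @return data.frame with columns `x`, `y`, both in \[-1, 1\].
#' @examples
#' cgr("A")  # (-0.5, -0.5)
#' @export
cgr <- function(seq) {
  seq <- normalize_seq(seq)
  pts <- t(vapply(seq, function(s) {
    if (nchar(s) == 0L) return(c(x = 0, y = 0))
    idx <- seq_to_ints(s)
    n <- length(idx)
    w <- 2^-(n:1)  # weight of base i in the final point is 2^-(n-i+1)
    c(x = sum(CGR_CORNERS[idx, "x"] * w),
      y = sum(CGR_CORNERS[idx, "y"] * w))
  }, c(x = 0, y = 0)))
  data.frame(x = pts[, "x"], y = pts[, "y"], row.names = NULL)
}

#' Background-normalized position weight logo
#'
#' Per-position log2 enrichment of each nucleotide over a background
#' distribution, the matrix behind a sequence logo. A pseudocount of 0.5 per
#' cell keeps empty cells finite.
#'
#' @param seqs Character vector of equal-length sequences.
#' @param background Length-4 positive vector of background base
#'   probabilities (A,C,G,U), normalized internally. Default uniform.
#' @param pseudocount Added to every (position, base) count (default 0.5).
#' @return length x 4 matrix of log2 enrichments, columns A,C,G,U, with the
#'   background stored in `attr(, "background")`.
#' @export
position_logo <- function(seqs, background = rep(0.25, 4),
                          pseudocount = 0.5) {
  seqs <- normalize_seq(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences must be of equal length")
  stopifnot(length(background) == 4L, all(background > 0))
  background <- background / sum(background)
  L <- lens[1]
  n <- length(seqs)
  counts <- matrix(pseudocount, nrow = L, ncol = 4L,
                   dimnames = list(NULL, RNA_ALPHABET))
  for (s in seqs) {
    idx <- seq_to_ints(s)
    counts[cbind(seq_len(L), idx)] <- counts[cbind(seq_len(L), idx)] + 1
  }
  freq <- counts / (n + 4 * pseudocount)
  w <- log2(sweep(freq, 2L, background, "/"))
  attr(w, "background") <- setNames(background, RNA_ALPHABET)
  w
}

#' Empirical base composition of a sequence set
#'
#' Convenience background for [position_logo()].
#'
#' @param seqs Character vector.
#' @return Length-4 probability vector (A,C,G,U).
#' @export
base_composition <- function(seqs) {
  seqs <- normalize_seq(seqs)
  all_letters <- unlist(strsplit(seqs, "", fixed = TRUE))
  tab <- table(factor(all_letters, levels = RNA_ALPHABET))
  setNames(as.numeric(tab) / length(all_letters), RNA_ALPHABET)
}
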