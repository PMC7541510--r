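#' Split values into top-q and bottom-(1-q) performance classes
#'
#' The class definition used throughout: the bottom bin holds the
#' `floor((1-q) * n)` smallest values (ties broken by stable input order),
#' everything else is "good". With q = 0.25 this reproduces the screening
#' dataset's printed partition (n = 91,534 -> 22,884 good / 68,650 bad).
#'
#' @param values Numeric vector (e.g. ON/OFF ratios).
#' @param q Top fraction labeled good (default 0.25).
#' @return List with `labels` (character, "good"/"bad" per input),
#'   `threshold` (smallest good value), `top_count`, `bottom_count`.
#' @export
quartile_labels <- function(values, q = 0.25) {
  n <- length(values)
  if (n < 1L) stop("quartile_labels needs at least one value")
  stopifnot(q > 0, q < 1)
  bottom_count <- as.integer(floor((1 - q) * n))
  top_count <- as.integer(n - bottom_count)
  ord <- order(values, seq_along(values))  # stable in input order on ties
  labels <- rep("good", n)
  labels[ord[seq_len(bottom_count)]] <- "bad"
  threshold <- if (top_count > 0) min(values[labels == "good"]) else NA_real_
  list(labels = labels, threshold = threshold,
       top_count = top_count, bottom_count = bottom_count, q = q)
}

#' GC content
#'
#' @param seq Character vector of non-empty sequences.
#' @return Numeric vector of (G + C) / length in \[0, 1\].
#' @export
gc_content <- function(seq) {
  seq <- normalize_seq(seq)
  if (any(nchar(seq) == 0L)) stop("gc_content of an empty sequence")
  vapply(seq, function(s) {
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    mean(x %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

# 1 if `seq` matches `motif` (N = wildcard) anchored at 1-based `at`
motif_match <- function(seq, motif, at) {
  w <- nchar(motif)
  if (at < 1L || at + w - 1L > nchar(seq))
    stop("motif anchor out of range", call. = FALSE)
  win <- strsplit(substr(seq, at, at + w - 1L), "")[[1]]
  pat <- strsplit(toupper(motif), "")[[1]]
  as.numeric(all(pat == "N" | pat == win))
}

#' Fraction of sequences carrying a motif at an anchored position
#'
#' `N` in the motif is a wildcard. Example: the NUA bulge motif at
#' position 22 of a 59-nt switch.
#'
#' @param seqs Character vector of sequences.
#' @param motif Motif letters over A/C/G/U/N.
#' @param at 1-based anchor position.
#' @return Fraction in \[0, 1\].
#' @export
motif_fraction <- function(seqs, motif, at) {
  seqs <- normalize_seq(seqs)
  mean(vapply(seqs, motif_match, numeric(1), motif = motif, at = at,
              USE.NAMES = FALSE))
}

STOP_CODONS_ALL <- c("UAA", "UAG", "UGA")

#' In-frame amino-acid profile of the coding triplets
#'
#' Translates the in-frame codons of the coding range (default 51-59, three
#' triplets at positions 51, 54, 57) with the standard genetic code and
#' flags stop codons. All three standard stops (UAA, UAG, UGA) are detected
#' by default; `stops` restricts the set.
#'
#' @param seqs Character vector of switches.
#' @param coding_range Integer pair, length divisible by 3 (default
#'   `c(51, 59)`).
#' @param stops Stop codons to flag.
#' @return List with `aa` (n x n_codons character matrix), `stop_flags`
#'   (n x n_codons logical), `aa_freq` (per-codon amino-acid frequency
#'   table, list of named numeric vectors).
#' @export
inframe_aa_profile <- function(seqs, coding_range = c(51L, 59L),
                               stops = STOP_CODONS_ALL) {
  seqs <- normalize_seq(seqs)
  w <- coding_range[2] - coding_range[1] + 1L
  if (w %% 3L != 0L) stop("coding range length must be divisible by 3")
  n_cod <- w %/% 3L
  starts <- coding_range[1] + 3L * (seq_len(n_cod) - 1L)
  code <- Biostrings::GENETIC_CODE  # DNA codon table
  aa <- matrix(NA_character_, nrow = length(seqs), ncol = n_cod)
  stop_flags <- matrix(FALSE, nrow = length(seqs), ncol = n_cod)
  for (i in seq_along(seqs)) {
    cods <- substring(seqs[i], starts, starts + 2L)
    aa[i, ] <- unname(code[chartr("U", "T", cods)])
    stop_flags[i, ] <- cods %in% stops
  }
  aa_freq <- lapply(seq_len(n_cod), function(j) {
    tab <- table(aa[, j])
    setNames(as.numeric(tab) / length(seqs), names(tab))
  })
  list(aa = aa, stop_flags = stop_flags, aa_freq = aa_freq)
}

#' Levenshtein edit distance
#'
#' Unit-cost insert/delete/substitute distance between two sequences.
#'
#' @param a,b Character scalars.
#' @return Integer distance.
#' @export
edit_distance <- function(a, b) {
  as.integer(adist(a, b))
}

#' Pairwise distance summary of a sequence set
#'
#' Distances over all unordered pairs, optionally restricted to a
#' positional region; reports the median (the distribution center), the
#' mode, and the histogram. Used to quantify corpus collinearity.
#'
#' Two metrics: `"mismatch"` (default) counts per-position differences
#' between the equal-length sequences — the convention under which random
#' 30-mers center near 22 and assembled 59-nt switches near 34, the known
#' collinearity figures for in-silico toehold corpora. `"levenshtein"` is
#' the unit-cost alignment distance of [edit_distance()]; it runs a few
#' units lower on the same sets because alignment can exploit shifts.
#'
#' @param seqs Character vector (equal lengths required for `"mismatch"`).
#' @param region Optional integer pair restricting the comparison to a
#'   1-based inclusive range.
#' @param method `"mismatch"` or `"levenshtein"`.
#' @return List with `median`, `mode`, `histogram` (named count table),
#'   `n_pairs`.
#' @export
pairwise_distance_summary <- function(seqs, region = NULL,
                                      method = c("mismatch",
                                                 "levenshtein")) {
  method <- match.arg(method)
  seqs <- normalize_seq(seqs)
  if (!is.null(region)) seqs <- substr(seqs, region[1], region[2])
  if (method == "levenshtein") {
    d <- adist(seqs)
    vals <- d[upper.tri(d)]
  } else {
    if (length(unique(nchar(seqs))) != 1L)
      stop("mismatch distance requires equal-length sequences")
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    n <- nrow(m)
    vals <- unlist(lapply(seq_len(n - 1L), function(i)
      colSums(t(m[(i + 1L):n, , drop = FALSE]) != m[i, ])))
  }
  tab <- table(vals)
  list(median = median(vals),
       mode = as.integer(names(tab)[which.max(tab)]),
       histogram = tab,
       n_pairs = length(vals))
}

#' Regression and classification metrics
#'
#' Standard definitions: `r2` is 1 - SS_res/SS_tot, `spearman` the rank
#' correlation, `mse` the mean squared error, and `mcc` the Matthews
#' correlation coefficient (0 for a degenerate single-class prediction).
#'
#' @param y_true Observed values (binary labels for `mcc`; "good" or 1 is
#'   the positive class).
#' @param y_pred Predicted values.
#' @param kind One of `"r2"`, `"spearman"`, `"mse"`, `"mcc"`.
#' @return Numeric scalar.
#' @export
metric <- function(y_true, y_pred, kind = c("r2", "spearman", "mse", "mcc")) {
  kind <- match.arg(kind)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ")
  switch(kind,
    r2 = 1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2),
    spearman = cor(y_true, y_pred, method = "spearman"),
    mse = mean((y_true - y_pred)^2),
    mcc = {
      to01 <- function(y) {
        if (is.character(y)) as.numeric(y == "good")
        else if (is.logical(y)) as.numeric(y)
        else as.numeric(y)
      }
      yt <- to01(y_true); yp <- to01(y_pred)
      if (!all(yt %in% c(0, 1)) || !all(yp %in% c(0, 1)))
        stop("mcc requires binary labels")
      tp <- sum(yt == 1 & yp == 1); tn <- sum(yt == 0 & yp == 0)
      fp <- sum(yt == 0 & yp == 1); fn <- sum(yt == 1 & yp == 0)
      denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      if (denom == 0) 0 else (tp * tn - fp * fn) / denom
    }
  )
}
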