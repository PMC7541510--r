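profile_table <- function(position, mean, dispersion, n, kind) {
  structure(data.frame(position = position, mean = mean,
                       dispersion = dispersion),
            n = n, kind = kind, class = c("profile_table", "data.frame"))
}

#' First-layer filter logos
#'
#' The learned weights of each first-layer convolutional filter, read
#' directly as a width x 4 position weight matrix (columns A,C,G,U): the
#' motifs the network matches against the raw sequence.
#'
#' @param model A `toehold_cnn`.
#' @return List of width x 4 matrices, one per filter.
#' @export
filter_logos <- function(model) {
  stopifnot(inherits(model, "toehold_cnn"))
  W <- model$params$W1
  width <- model$config$conv1_width
  lapply(seq_len(ncol(W)), function(f) {
    m <- matrix(W[, f], nrow = width, ncol = 4L, byrow = TRUE,
                dimnames = list(NULL, RNA_ALPHABET))
    m
  })
}

filter_consensus <- function(model) {
  vapply(filter_logos(model), function(m)
    paste(RNA_ALPHABET[max.col(m, ties.method = "first")], collapse = ""),
    character(1))
}

#' k-mer enrichment across an ensemble of trained filters
#'
#' With `method = "consensus"` (default), takes the per-column argmax
#' consensus string of every first-layer filter in every model, slides
#' windows of width `k` over each consensus, and compares observed k-mer
#' counts to the expectation under a uniform k-mer distribution
#' (total windows / 4^k). With `method = "threshold"`, a window's argmax
#' k-mer is counted only if the window's filter sub-score (the summed
#' per-column weights of that k-mer) exceeds `threshold` — a stricter
#' reading that ignores weakly specified filter regions.
#'
#' @param models List of `toehold_cnn` models (e.g. 20 independently
#'   seeded trainings).
#' @param k Window width (default 3).
#' @param method `"consensus"` or `"threshold"`.
#' @param threshold Minimum window sub-score under `method = "threshold"`
#'   (default 0).
#' @return data.frame with `kmer`, `observed`, `expected`, `ratio`,
#'   covering all 4^k k-mers.
#' @export
filter_kmer_enrichment <- function(models, k = 3L,
                                   method = c("consensus", "threshold"),
                                   threshold = 0) {
  method <- match.arg(method)
  stopifnot(length(models) >= 1L)
  vocab <- names(kmer_vocabulary(k))
  observed <- setNames(numeric(length(vocab)), vocab)
  total <- 0
  for (m in models) {
    for (lg in filter_logos(m)) {
      width <- nrow(lg)
      if (width < k) next
      for (start in 1:(width - k + 1L)) {
        win <- lg[start:(start + k - 1L), , drop = FALSE]
        letters_idx <- max.col(win, ties.method = "first")
        wkm <- paste(RNA_ALPHABET[letters_idx], collapse = "")
        score <- sum(win[cbind(seq_len(k), letters_idx)])
        if (method == "consensus" || score > threshold) {
          observed[wkm] <- observed[wkm] + 1
          total <- total + 1
        }
      }
    }
  }
  expected <- total / length(vocab)
  data.frame(kmer = vocab, observed = as.numeric(observed),
             expected = expected,
             ratio = if (expected > 0) as.numeric(observed) / expected
                     else rep(NA_real_, length(vocab)),
             row.names = NULL)
}

#' Gradient saliency profile of the CNN
#'
#' Absolute input gradients of one output head, summed per (position,
#' nucleotide) over the sequence set and normalized by how often that
#' nucleotide occurs at that position, then aggregated per position. High
#' values mark positions whose letters the model's prediction is most
#' sensitive to.
#'
#' @param model A `toehold_cnn`.
#' @param seqs Character vector of switches.
#' @param head `"on"` or `"off"`.
#' @return A `profile_table` (position, mean, dispersion).
#' @export
saliency <- function(model, seqs, head = c("on", "off")) {
  head <- match.arg(head)
  seqs <- normalize_seq(seqs)
  L <- model$geom$input_len
  X <- encode_batch(seqs, L)
  G <- abs(cnn_input_gradient(model, X, head = head))
  n <- length(seqs)
  # per-sequence, per-position: |grad| summed over the 4 channels
  g <- matrix(0, n, L)
  # occurrence-weighted accumulation: the score is attributed to the letter
  # the sequence carries at that position, then divided by how often that
  # letter occurs there, and the letter groups are averaged
  sal <- matrix(0, L, 4L)
  cnt <- matrix(0, L, 4L)
  for (p in seq_len(L)) {
    cols <- ((p - 1L) * 4L + 1L):(p * 4L)
    g[, p] <- rowSums(G[, cols, drop = FALSE])
    obs <- X[, cols, drop = FALSE]
    sal[p, ] <- colSums(obs * g[, p])
    cnt[p, ] <- colSums(obs)
  }
  norm <- sal / pmax(cnt, 1)
  per_pos <- rowSums(norm * (cnt > 0)) / pmax(rowSums(cnt > 0), 1)
  profile_table(seq_len(L), per_pos, apply(g, 2L, sd),
                n = n, kind = paste0("saliency_", head))
}

#' In-silico mutagenesis scan of the CNN
#'
#' At every position of every sequence, substitutes all four nucleotides
#' (the identity substitution included), predicts, and scores the position
#' by the standard deviation of the four predictions. Aggregated as
#' mean with a 95% confidence half-width across sequences.
#'
#' @param model A `toehold_cnn`.
#' @param seqs Character vector (the screening design samples 2500 per
#'   group; any number is accepted).
#' @param head `"on"` or `"off"`.
#' @return A `profile_table` with `mean` (average sd) and `dispersion`
#'   (95% CI half-width).
#' @export
mutagenesis_scan_cnn <- function(model, seqs, head = c("on", "off")) {
  head <- match.arg(head)
  seqs <- normalize_seq(seqs)
  L <- model$geom$input_len
  n <- length(seqs)
  sds <- matrix(0, n, L)
  for (p in seq_len(L)) {
    variants <- unlist(lapply(seqs, function(s) {
      vapply(RNA_ALPHABET, function(b) {
        substr(s, p, p) <- b; s
      }, character(1), USE.NAMES = FALSE)
    }))
    pr <- predict(model, variants)[[head]]
    sds[, p] <- apply(matrix(pr, nrow = 4L), 2L, sd)
  }
  profile_table(seq_len(L), colMeans(sds),
                1.96 * apply(sds, 2L, sd) / sqrt(n),
                n = n, kind = paste0("mutagenesis_", head))
}

#' In-silico mutagenesis scan of the LM classifier
#'
#' Serially mutates each position of each (good) sequence to one random
#' nucleotide (seeded; the identity draw is possible) and records the
#' averaged classification probability of the mutant.
#'
#' @param cls_forward,cls_backward The classifier pair.
#' @param seqs Character vector of good switches (the screening design
#'   samples 500).
#' @param seed Integer seed for the substitution draws.
#' @return A `profile_table` with the mean and sd of mutant `p_good` per
#'   position.
#' @export
mutagenesis_scan_lm <- function(cls_forward, cls_backward, seqs,
                                seed = NULL) {
  seqs <- normalize_seq(seqs)
  L <- nchar(seqs[1])
  n <- length(seqs)
  with_seed(seed, {
    pm <- matrix(0, n, L)
    for (p in seq_len(L)) {
      subs <- sample(RNA_ALPHABET, n, replace = TRUE)
      mutants <- seqs
      substr(mutants, p, p) <- subs
      pm[, p] <- classify_switches(cls_forward, cls_backward,
                                   mutants)$p_good
    }
    profile_table(seq_len(L), colMeans(pm), apply(pm, 2L, sd),
                  n = n, kind = "lm_prob_delta")
  })
}

# per-token |gradient of the predicted-class logit w.r.t. the embedded
# input|, normalized to sum 1 per sequence
lm_attention_matrix <- function(cls, seqs) {
  config <- cls$config
  ids <- lm_token_matrix(config, seqs)
  if (cls$direction == "backward")
    ids <- ids[, rev(seq_len(ncol(ids))), drop = FALSE]
  cf <- lm_cls_forward(cls$params, config, ids)
  n <- nrow(ids); T_ <- ncol(ids)
  cls_idx <- max.col(cf$p, ties.method = "first")
  dlog <- matrix(0, n, 2L)
  dlog[cbind(seq_len(n), cls_idx)] <- 1
  dhbar <- dlog %*% t(cls$params$Wc)
  dH <- dhbar[rep(seq_len(n), T_), , drop = FALSE] / T_
  bw <- qrnn_backward(cls$params, config, cf$fw, dH)
  att <- matrix(0, n, T_)
  for (t in seq_len(T_))
    att[, t] <- rowSums(abs(bw$dXin[((t - 1L) * n + 1L):(t * n), ,
                                    drop = FALSE]))
  if (cls$direction == "backward") att <- att[, rev(seq_len(T_)),
                                              drop = FALSE]
  att / rowSums(att)
}

#' Intrinsic attention profile of the LM classifier
#'
#' Gradient-based contribution of each k-mer token to the logit of the
#' class the model assigns the sequence, normalized to sum to one per
#' sequence (so rows are comparable across sequences), averaged over the
#' pair of directional models.
#'
#' @param cls_forward,cls_backward The classifier pair (pass the same model
#'   twice for a single-direction profile).
#' @param seqs Character vector of switches.
#' @return A `profile_table` over token positions with mean and sd; the
#'   raw per-sequence matrix is in `attr(, "matrix")`.
#' @export
attention_profile <- function(cls_forward, cls_backward, seqs) {
  seqs <- normalize_seq(seqs)
  att <- (lm_attention_matrix(cls_forward, seqs) +
            lm_attention_matrix(cls_backward, seqs)) / 2
  out <- profile_table(seq_len(ncol(att)), colMeans(att),
                       apply(att, 2L, sd),
                       n = length(seqs), kind = "attention")
  attr(out, "matrix") <- att
  out
}

#' Export a profile or logo as TSV
#'
#' @param x A `profile_table`, logo matrix, or enrichment data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
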