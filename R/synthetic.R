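# All randomness is drawn inside with_seed(): the global RNG stream of the
# caller is saved and restored, so seeded operations compose without leaking
# generator state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Sample random trigger sequences
#'
#' Draws each nucleotide i.i.d. uniformly over A/C/G/U at every position, the
#' recipe used to populate the random arm of the screening library and the
#' in-silico corpus.
#'
#' @param n Number of triggers.
#' @param seed Integer seed; the same seed reproduces the same list.
#' @param width Trigger width in nt (default 30).
#' @return Character vector of `n` triggers.
#' @export
sample_triggers <- function(n, seed = NULL, width = 30L) {
  stopifnot(n >= 0)
  if (n == 0) return(character(0))
  with_seed(seed, {
    letters4 <- sample(RNA_ALPHABET, n * width, replace = TRUE)
    m <- matrix(letters4, nrow = n, ncol = width)
    apply(m, 1L, paste, collapse = "")
  })
}

#' Generate an in-silico corpus of valid switches
#'
#' Random uniform triggers completed to full-length switches by the
#' structural rules; every member validates against the template.
#'
#' @param n Corpus size.
#' @param template A [toehold_template()].
#' @param seed Integer seed.
#' @return Character vector of `n` switch sequences.
#' @export
build_corpus <- function(n, template = toehold_template(), seed = NULL) {
  if (n == 0) return(character(0))
  triggers <- sample_triggers(n, seed = seed, width = trigger_length(template))
  assemble_switch(triggers, template)
}

#' Control sequences for ablation studies
#'
#' Three negative controls used to probe what a sequence model has learned:
#' `scrambled` permutes single letters (preserves nucleotide composition),
#' `shuffled` permutes k-mer tokens (preserves token composition but destroys
#' token order), and `random` draws a fresh uniform sequence of equal length.
#'
#' @param seq Character vector of sequences.
#' @param mode One of `"scrambled"`, `"shuffled"`, `"random"`.
#' @param k Token width for `shuffled` (default 3, stride = k).
#' @param seed Integer seed.
#' @return Character vector of control sequences.
#' @export
make_control <- function(seq, mode = c("scrambled", "shuffled", "random"),
                         k = 3L, seed = NULL) {
  mode <- match.arg(mode)
  seq <- normalize_seq(seq)
  with_seed(seed, {
    vapply(seq, function(s) {
      switch(mode,
        scrambled = paste(sample(strsplit(s, "")[[1]]), collapse = ""),
        shuffled = {
          toks <- tokenize(s, k = k, stride = k)$tokens
          tail_start <- length(toks) * k + 1L
          tail <- if (tail_start <= nchar(s)) substring(s, tail_start) else ""
          paste0(paste(sample(toks), collapse = ""), tail)
        },
        random = paste(sample(RNA_ALPHABET, nchar(s), replace = TRUE),
                       collapse = "")
      )
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Synthetic sequence-function oracle parameters
#'
#' Weights for the interpretable features that define the synthetic ground
#' truth used in benchmarks: GC fraction of the stem-proximal trigger region
#' (positions 13-30), U count in the last five switch-region positions
#' (26-30), an indicator for an in-frame stop codon in the coding triplets
#' (51-59), and optional per-position motif bonuses. ON and OFF each get a
#' linear score passed through a logistic link, plus Gaussian noise.
#'
#' The `"preset1"` constants are fixed so that benchmark results are
#' reproducible: the stop-codon penalty and U-richness bonus mirror the
#' over-representation patterns seen in experimentally screened switches,
#' and the noiseless signal is learnable but not linearly trivial.
#'
#' @param preset `"preset1"` or `"flat"` (all weights zero).
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   linear scale (default 0.05).
#' @return An object of class `oracle_params`.
#' @export
oracle_params <- function(preset = c("preset1", "flat"), noise_sd = 0.05) {
  preset <- match.arg(preset)
  p <- switch(preset,
    preset1 = list(
      on = list(gc_13_30 = -3.0, u_26_30 = 0.45, stop_51_59 = -2.0,
                intercept = 0.8,
                motifs = list(list(motif = "UA", at = 23L, bonus = 0.8))),
      off = list(gc_13_30 = -2.0, u_26_30 = 0.0, stop_51_59 = 0.0,
                 intercept = -0.5, motifs = list())
    ),
    flat = list(
      on = list(gc_13_30 = 0, u_26_30 = 0, stop_51_59 = 0, intercept = 0,
                motifs = list()),
      off = list(gc_13_30 = 0, u_26_30 = 0, stop_51_59 = 0, intercept = 0,
                 motifs = list())
    )
  )
  structure(c(p, list(noise_sd = noise_sd, link = "logistic",
                      preset = preset)),
            class = "oracle_params")
}

oracle_features <- function(switch) {
  gc <- vapply(switch, function(s)
    gc_content(substr(s, 13, 30)), numeric(1), USE.NAMES = FALSE)
  u5 <- vapply(switch, function(s) {
    sub <- strsplit(substr(s, 26, 30), "")[[1]]
    sum(sub == "U")
  }, numeric(1), USE.NAMES = FALSE)
  stop_codons <- c("UAA", "UAG", "UGA")
  stp <- vapply(switch, function(s) {
    cods <- substring(s, c(51, 54, 57), c(53, 56, 59))
    as.numeric(any(cods %in% stop_codons))
  }, numeric(1), USE.NAMES = FALSE)
  list(gc_13_30 = gc, u_26_30 = u5, stop_51_59 = stp)
}

oracle_channel <- function(switch, w, feats) {
  eta <- w$intercept +
    w$gc_13_30 * feats$gc_13_30 +
    w$u_26_30 * feats$u_26_30 +
    w$stop_51_59 * feats$stop_51_59
  for (m in w$motifs) {
    hit <- vapply(switch, function(s)
      motif_match(s, m$motif, m$at), numeric(1), USE.NAMES = FALSE)
    eta <- eta + m$bonus * hit
  }
  eta
}

#' Score switches with the synthetic oracle
#'
#' Deterministic given the seed; returns ON and OFF in (0, 1) under the
#' logistic link. Used as ground truth for every parameter-recovery and
#' model benchmark in the package.
#'
#' @param switch Character vector of valid switches.
#' @param params An [oracle_params()] object.
#' @param seed Integer seed for the noise draw.
#' @return data.frame with columns `on`, `off`.
#' @export
oracle_score <- function(switch, params = oracle_params(), seed = NULL) {
  switch <- normalize_seq(switch)
  feats <- oracle_features(switch)
  eta_on <- oracle_channel(switch, params$on, feats)
  eta_off <- oracle_channel(switch, params$off, feats)
  with_seed(seed, {
    if (params$noise_sd > 0) {
      eta_on <- eta_on + rnorm(length(switch), sd = params$noise_sd)
      eta_off <- eta_off + rnorm(length(switch), sd = params$noise_sd)
    }
    link <- if (identical(params$link, "logistic")) stats::plogis else identity
    data.frame(on = link(eta_on), off = link(eta_off))
  })
}

ONOFF_FLOOR <- 1e-6

#' Build an oracle-labeled dataset of toehold records
#'
#' Generates a corpus, scores it with the oracle, and attaches the combined
#' ON/OFF performance value (`on / max(off, floor)`).
#'
#' @param n Number of records.
#' @param params An [oracle_params()] object.
#' @param template A [toehold_template()].
#' @param seed Integer seed (drives both the corpus and the oracle noise).
#' @return data.frame with columns `switch_seq, trigger_seq, on, off, onoff,
#'   qc_pass, label, source`.
#' @export
build_labeled_dataset <- function(n, params = oracle_params(),
                                  template = toehold_template(),
                                  seed = NULL) {
  switches <- build_corpus(n, template, seed = seed)
  sc <- oracle_score(switches, params,
                     seed = if (is.null(seed)) NULL else seed + 1L)
  data.frame(
    switch_seq = switches,
    trigger_seq = switch_trigger(switches, template),
    on = sc$on, off = sc$off,
    onoff = sc$on / pmax(sc$off, ONOFF_FLOOR),
    qc_pass = TRUE,
    label = NA_character_,
    source = paste0("oracle:", params$preset),
    stringsAsFactors = FALSE
  )
}

#' Balance a dataset over its ON and OFF distributions
#'
#' The distribution-flattening filter applied before training: each channel
#' (ON, then OFF) is split into `n_bins` equal-width bins over its observed
#' range, every bin is down-sampled without replacement to the rounded mean
#' bin count, and the union of the two channels' survivors is carried
#' forward. Never duplicates a record; always a subset of the input.
#'
#' @param records data.frame with `on` and `off` columns.
#' @param n_bins Number of bins per channel (default 1000).
#' @param seed Integer seed for the down-sampling draws.
#' @return The surviving subset of `records`, in original order.
#' @export
balance_distribution <- function(records, n_bins = 1000L, seed = NULL) {
  if (nrow(records) == 0L) return(records)
  with_seed(seed, {
    survivors_channel <- function(values) {
      rng <- range(values)
      if (rng[1] == rng[2]) {
        bins <- rep(1L, length(values))
      } else {
        edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
        bins <- findInterval(values, edges, rightmost.closed = TRUE,
                             all.inside = TRUE)
      }
      counts <- tabulate(bins, nbins = n_bins)
      # mean count over occupied bins (a single occupied bin is left
      # unchanged; empty bins say nothing about the density to flatten to)
      target <- max(1L, round(mean(counts[counts > 0L])))
      keep <- integer(0)
      for (b in unique(bins)) {
        idx <- which(bins == b)
        if (length(idx) > target)
          idx <- sort(sample(idx, target))
        keep <- c(keep, idx)
      }
      keep
    }
    keep_on <- survivors_channel(records$on)
    keep_off <- survivors_channel(records$off)
    records[sort(union(keep_on, keep_off)), , drop = FALSE]
  })
}
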