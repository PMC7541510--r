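# Generic scoring seams: optimization routines accept either the package's
# trained models or any object wrapped with toehold_scorer(), so surrogate
# (e.g. oracle-backed) models plug into the same pipelines.

#' Wrap arbitrary scoring functions as model stand-ins
#'
#' `onoff_fun(seqs)` must return a data.frame with `on` and `off` (regressor
#' stand-in); `pgood_fun(seqs)` must return probabilities in \[0,1\]
#' (classifier stand-in).
#'
#' @param onoff_fun,pgood_fun Functions of a character vector of sequences.
#' @return An object of class `toehold_scorer`.
#' @export
toehold_scorer <- function(onoff_fun = NULL, pgood_fun = NULL) {
  structure(list(onoff_fun = onoff_fun, pgood_fun = pgood_fun),
            class = "toehold_scorer")
}

score_onoff <- function(model, seqs) {
  if (inherits(model, "toehold_scorer")) {
    pr <- model$onoff_fun(seqs)
  } else {
    pr <- predict(model, seqs)
  }
  if (!is.null(pr$onoff)) pr$onoff
  else pr$on / pmax(pr$off, ONOFF_FLOOR)
}

score_pgood <- function(classifiers, seqs) {
  if (inherits(classifiers, "toehold_scorer"))
    return(classifiers$pgood_fun(seqs))
  classify_switches(classifiers[[1]], classifiers[[2]], seqs)$p_good
}

#' Enumerate all stem variants of a parent switch
#'
#' Assigns every combination of A/C/G/U to the template's mutable stem
#' positions (default 22-30, so 4^9 = 262,144 variants) and repairs the
#' pairing dependencies with [fix_sequence()], preserving positions 1-21 and
#' hence complementarity to the intended target. Duplicate-free by
#' construction.
#'
#' @param parent A valid switch sequence.
#' @param template A [toehold_template()].
#' @return Character vector of 4^m variant switches (m = number of mutable
#'   positions), each passing validation.
#' @export
enumerate_variants <- function(parent, template = toehold_template()) {
  parent <- normalize_seq(parent)
  v <- validate_switch(parent, template)
  if (!v$pass) stop("parent switch does not validate: ",
                    paste(v$violations, collapse = "; "))
  mp <- template$mutable_positions
  positions <- range_seq(mp)
  m <- length(positions)
  n_var <- 4^m
  if (n_var > .Machine$integer.max) stop("mutable range too large")
  n_var <- as.integer(n_var)
  # base-4 digits of 0..4^m-1, one column per mutable position
  idx <- 0:(n_var - 1L)
  out <- rep(parent, n_var)
  for (j in seq_len(m)) {
    digit <- (idx %/% 4L^(m - j)) %% 4L + 1L
    substr(out, positions[j], positions[j]) <-
      RNA_ALPHABET[digit]
  }
  fix_sequence(out, template)
}

#' Rank stem variants by geometric-mean consensus (NuSpeak)
#'
#' Scores every variant with the classifier pair (probability of the good
#' class) and the regressor (predicted ON/OFF, min-max normalized within
#' the candidate set), and ranks by the geometric mean of the two scores.
#' Ties break lexicographically by sequence, so the ranking is
#' deterministic.
#'
#' @param parent A valid switch sequence.
#' @param classifiers List of two `toehold_lm_classifier`s (forward,
#'   backward) or a [toehold_scorer()].
#' @param regressor A `toehold_cnn` or a [toehold_scorer()].
#' @param template A [toehold_template()].
#' @param top_k Number of top variants to return (default 10; `Inf` for
#'   all).
#' @param batch_size Scoring batch size (default 4096).
#' @param mfe Optional function mapping sequences to precomputed minimum
#'   free energies; used only as a secondary sort (least negative first)
#'   among equal geometric means. MFE is never computed here — this is a
#'   hook for values produced by an external thermodynamic tool.
#' @return data.frame ranked by decreasing `geo_mean`: `sequence`,
#'   `p_good`, `onoff`, `score_norm`, `geo_mean` (plus `mfe` when
#'   supplied).
#' @export
nuspeak_rank <- function(parent, classifiers, regressor,
                         template = toehold_template(), top_k = 10L,
                         batch_size = 4096L, mfe = NULL) {
  variants <- enumerate_variants(parent, template)
  n <- length(variants)
  p_good <- numeric(n)
  onoff <- numeric(n)
  for (start in seq.int(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    p_good[idx] <- score_pgood(classifiers, variants[idx])
    onoff[idx] <- score_onoff(regressor, variants[idx])
  }
  rng <- range(onoff)
  score_norm <- if (rng[2] > rng[1]) (onoff - rng[1]) / (rng[2] - rng[1])
                else rep(1, n)
  geo_mean <- sqrt(p_good * score_norm)
  if (!is.null(mfe)) {
    mfe_vals <- mfe(variants)
    ord <- order(-geo_mean, -mfe_vals, variants)
  } else {
    ord <- order(-geo_mean, variants)
  }
  keep <- ord[seq_len(min(top_k, n))]
  out <- data.frame(sequence = variants[keep], p_good = p_good[keep],
                    onoff = onoff[keep], score_norm = score_norm[keep],
                    geo_mean = geo_mean[keep], row.names = NULL)
  if (!is.null(mfe)) out$mfe <- mfe_vals[keep]
  out
}

row_entropy <- function(P) {
  -rowSums(P * log(pmax(P, 1e-12)))
}

# reverse complement of a probability block: reverse rows, swap A<->U and
# C<->G columns; a linear involution, so it is its own adjoint
rc_prob <- function(B) B[rev(seq_len(nrow(B))), c(4L, 3L, 2L, 1L),
                         drop = FALSE]

# gradient of sum over dependency rules of ||P[target] - rc(P[source])||^2
pairing_penalty_grad <- function(P, template) {
  G <- P * 0
  for (rule in template$dependency_rules) {
    tgt <- range_seq(rule$target)
    src <- range_seq(rule$source)
    diffB <- P[tgt, , drop = FALSE] - rc_prob(P[src, , drop = FALSE])
    G[tgt, ] <- G[tgt, ] + 2 * diffB
    G[src, ] <- G[src, ] - 2 * rc_prob(diffB)
  }
  G
}

#' Gradient-ascent sequence redesign (STORM)
#'
#' Relaxes the switch to a 59 x 4 logit matrix, takes gradient steps that
#' move the regressor's predicted (ON, OFF) toward the targets (the whole
#' sequence varies freely; an entropy bonus, annealed to zero, keeps early
#' steps exploratory), and after each round discretizes the relaxed matrix
#' by row-wise argmax and repairs it with [fix_sequence()]. The best
#' repaired sequence across rounds (by predicted ON/OFF) is returned.
#'
#' @param seed_switch A full-length starting sequence (not necessarily
#'   valid; it is repaired on entry).
#' @param model A two-head `toehold_cnn`.
#' @param template A [toehold_template()].
#' @param target_on,target_off Per-head targets (defaults 1 and 0) under
#'   `target_mode = "per_head"`.
#' @param target_mode `"per_head"` (default) steers each head to its own
#'   target; `"ratio"` steers the predicted ON/OFF ratio itself toward
#'   `target_ratio`.
#' @param target_ratio Ratio target under `target_mode = "ratio"`
#'   (default 1).
#' @param rounds Optimization rounds (default 5).
#' @param steps_per_round Gradient steps per round (default 300).
#' @param step_size Logit step size (default 0.5).
#' @param entropy_weight Initial entropy bonus weight, annealed linearly
#'   to 0 (default 1e-3).
#' @param pairing_weight Weight of an optional base-pairing penalty added
#'   to the loss (sum of squared deviations between each dependency
#'   target's probability rows and the reverse complement of its
#'   source's). Default 0: repairing after free optimization avoids the
#'   local minima constrained ascent tends to settle into.
#' @param rng_seed Seed for the logit jitter between rounds.
#' @return An `optimization_trace`: list with `best` (sequence),
#'   `best_on`, `best_off`, `best_onoff`, and `trace` (per-round
#'   data.frame).
#' @export
storm_optimize <- function(seed_switch, model,
                           template = toehold_template(),
                           target_on = 1, target_off = 0,
                           target_mode = c("per_head", "ratio"),
                           target_ratio = 1, rounds = 5L,
                           steps_per_round = 300L, step_size = 0.5,
                           entropy_weight = 1e-3, pairing_weight = 0,
                           rng_seed = 1L) {
  target_mode <- match.arg(target_mode)
  stopifnot(inherits(model, "toehold_cnn"), model$heads == "on_off")
  L <- model$geom$input_len
  seed_switch <- fix_sequence(normalize_seq(seed_switch), template)
  with_seed(rng_seed, {
    eval_seq <- function(s) {
      pr <- predict(model, s)
      list(on = pr$on, off = pr$off,
           onoff = pr$on / max(pr$off, ONOFF_FLOOR))
    }
    current <- seed_switch
    sc <- eval_seq(current)
    best <- list(seq = current, on = sc$on, off = sc$off,
                 onoff = sc$onoff)
    trace <- data.frame(round = 0L, sequence = current, on = sc$on,
                        off = sc$off, onoff = sc$onoff)
    if (steps_per_round <= 0L) rounds <- 0L
    total_steps <- max(1L, rounds * steps_per_round)
    step_no <- 0L
    for (r in seq_len(rounds)) {
      logits <- 4 * one_hot(current) +
        matrix(rnorm(L * 4L, sd = 0.25), L, 4L)
      for (s in seq_len(steps_per_round)) {
        step_no <- step_no + 1L
        P <- softmax_rows(logits)
        X <- matrix(as.vector(t(P)), nrow = 1L)  # channel-major flat row
        fw <- cnn_forward(model$params, X, model$config, model$geom)
        if (target_mode == "per_head") {
          don <- 2 * (fw$yon - target_on)
          doff <- 2 * (fw$yoff - target_off)
        } else {
          off_fl <- max(fw$yoff, ONOFF_FLOOR)
          r <- fw$yon / off_fl
          don <- 2 * (r - target_ratio) / off_fl
          doff <- if (fw$yoff > ONOFF_FLOOR)
            -2 * (r - target_ratio) * fw$yon / off_fl^2 else 0
        }
        bw <- cnn_backward(model$params, fw, model$config, model$geom,
                           dyon = don, dyoff = doff)
        dP <- matrix(bw$dX, L, 4L, byrow = TRUE)
        # entropy bonus (negative mean row entropy in the loss), annealed
        w_ent <- entropy_weight * (1 - step_no / total_steps)
        if (w_ent > 0)
          dP <- dP + w_ent * (log(pmax(P, 1e-12)) + 1) / L
        if (pairing_weight > 0)
          dP <- dP + pairing_weight * pairing_penalty_grad(P, template)
        # softmax Jacobian, row-wise
        dLogit <- P * (dP - rowSums(dP * P))
        logits <- logits - step_size * dLogit
      }
      cand <- fix_sequence(one_hot_decode(logits), template)
      sc <- eval_seq(cand)
      trace <- rbind(trace,
                     data.frame(round = r, sequence = cand, on = sc$on,
                                off = sc$off, onoff = sc$onoff))
      if (sc$onoff > best$onoff) {
        best <- list(seq = cand, on = sc$on, off = sc$off,
                     onoff = sc$onoff)
      }
      current <- cand
    }
    structure(list(best = best$seq, best_on = best$on,
                   best_off = best$off,
                   best_onoff = best$onoff, trace = trace),
              class = "optimization_trace")
  })
}

#' @export
print.optimization_trace <- function(x, ...) {
  cat("STORM optimization trace (", nrow(x$trace) - 1L, " rounds)\n",
      sep = "")
  cat("  best predicted ON/OFF: ", signif(x$best_onoff, 4), "\n", sep = "")
  cat("  best sequence: ", x$best, "\n", sep = "")
  invisible(x)
}

#' Consensus selection of predicted-good and predicted-bad switches
#'
#' Ranks candidates by the geometric mean of classifier probability and
#' min-max-normalized predicted ON/OFF, then draws the requested numbers of
#' picks at random (seeded) from the top and bottom quarters of the
#' ranking. Pick sets are disjoint and every good pick outranks every bad
#' pick.
#'
#' @param candidates Character vector of switches.
#' @param classifiers Classifier pair (or [toehold_scorer()]).
#' @param regressor Regressor (or [toehold_scorer()]).
#' @param n_good,n_bad Numbers of picks (default 8 and 8).
#' @param rng_seed Seed for the random draws.
#' @return List with `good` and `bad` data.frames (sequence and scores).
#' @export
consensus_select <- function(candidates, classifiers, regressor,
                             n_good = 8L, n_bad = 8L, rng_seed = 1L) {
  n <- length(candidates)
  p_good <- score_pgood(classifiers, candidates)
  onoff <- score_onoff(regressor, candidates)
  rng <- range(onoff)
  score_norm <- if (rng[2] > rng[1]) (onoff - rng[1]) / (rng[2] - rng[1])
                else rep(1, n)
  geo_mean <- sqrt(p_good * score_norm)
  ord <- order(-geo_mean, candidates)
  stratum <- max(ceiling(n / 4), n_good, n_bad)
  if (n_good + n_bad > 0 && 2 * stratum > n)
    stop("too few candidates (", n, ") for ", n_good, "+", n_bad,
         " disjoint picks")
  df <- data.frame(sequence = candidates, p_good = p_good, onoff = onoff,
                   score_norm = score_norm, geo_mean = geo_mean)[ord, ]
  rownames(df) <- NULL
  with_seed(rng_seed, {
    good_idx <- if (n_good > 0) sort(sample(seq_len(stratum), n_good))
                else integer(0)
    bad_idx <- if (n_bad > 0)
      sort(sample(seq.int(n - stratum + 1L, n), n_bad)) else integer(0)
    list(good = df[good_idx, , drop = FALSE],
         bad = df[bad_idx, , drop = FALSE])
  })
}
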