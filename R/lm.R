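#' Configuration of the k-mer language model
#'
#' A stacked quasi-recurrent (QRNN) encoder over non-overlapping k-mer
#' tokens: an embedding layer (plus a learned positional embedding — the
#' toehold grammar is strongly positional), `n_layers` QRNN layers with
#' f-pooling (`h_t = f_t * h_(t-1) + (1 - f_t) * z_t`, gates computed per
#' token), and either a tied decoder (pre-training, next-token objective)
#' or a linear classifier head over the token-averaged final hidden state.
#' The final QRNN layer's width equals the embedding size so decoder
#' weights can be tied to the embedding.
#'
#' Two presets: `"paper"` is the full-scale architecture (4 layers, 1552
#' hidden activations, 400-dim embedding); `"desk"` is a reduced
#' architecture (2 layers, 256 hidden, 64-dim embedding) with the same
#' contracts, sized for interactive work and the test suite.
#'
#' @param preset `"desk"` (default) or `"paper"`.
#' @param n_layers,hidden_size,embedding_size Encoder architecture
#'   (overrides the preset).
#' @param k,stride Tokenizer settings (default 3/3; a 59-mer gives 19
#'   tokens).
#' @param dropout_output,dropout_hidden,dropout_input,dropout_embedding
#'   Dropout rates (defaults 0.15 / 0.20 / 0.30 / 0.05).
#' @param classifier_dropout Dropout on the pooled state in the classifier
#'   head (default 0.5).
#' @param label_smoothing Label-smoothing mass for the classifier loss
#'   (default 0.1).
#' @param weight_decay L2 weight decay added to the gradient before the
#'   Adam update (default 0: at desk scale any appreciable decay collapses
#'   the classifier toward the majority class; the knob is exposed for
#'   larger-scale training).
#' @param learning_rate Peak Adam learning rate under the cosine schedule.
#' @param batch_size Minibatch size (default 128).
#' @param epochs Training epochs (default 15).
#' @param bptt Maximum back-propagation-through-time span (default 60;
#'   toehold token streams are shorter, so truncation never triggers).
#' @param seed Integer seed.
#' @return An object of class `lm_config`.
#' @export
lm_config <- function(preset = c("desk", "paper"),
                      n_layers = NULL, hidden_size = NULL,
                      embedding_size = NULL,
                      k = 3L, stride = 3L,
                      dropout_output = 0.15, dropout_hidden = 0.20,
                      dropout_input = 0.30, dropout_embedding = 0.05,
                      classifier_dropout = 0.5, label_smoothing = 0.1,
                      weight_decay = 0, learning_rate = 0.005,
                      batch_size = 128L, epochs = 15L, bptt = 60L,
                      seed = 1L) {
  preset <- match.arg(preset)
  dims <- switch(preset,
    desk = list(n_layers = 2L, hidden_size = 256L, embedding_size = 64L),
    paper = list(n_layers = 4L, hidden_size = 1552L,
                 embedding_size = 400L))
  if (!is.null(n_layers)) dims$n_layers <- as.integer(n_layers)
  if (!is.null(hidden_size)) dims$hidden_size <- as.integer(hidden_size)
  if (!is.null(embedding_size))
    dims$embedding_size <- as.integer(embedding_size)
  structure(c(dims, list(
    preset = preset, k = as.integer(k), stride = as.integer(stride),
    dropout_output = dropout_output, dropout_hidden = dropout_hidden,
    dropout_input = dropout_input, dropout_embedding = dropout_embedding,
    classifier_dropout = classifier_dropout,
    label_smoothing = label_smoothing, weight_decay = weight_decay,
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), bptt = as.integer(bptt),
    seed = as.integer(seed))), class = "lm_config")
}

lm_vocab_size <- function(config) 4L^config$k

LM_BOS <- function(config) lm_vocab_size(config) + 1L

LM_MAX_POSITIONS <- 64L

lm_layer_dims <- function(config) {
  L <- config$n_layers
  lapply(seq_len(L), function(l) {
    d_in <- if (l == 1L) config$embedding_size else config$hidden_size
    d_out <- if (l == L) config$embedding_size else config$hidden_size
    c(d_in = d_in, d_out = d_out)
  })
}

lm_init_params <- function(config) {
  V <- lm_vocab_size(config)
  p <- list(E = matrix(rnorm((V + 1L) * config$embedding_size, sd = 0.1),
                       V + 1L, config$embedding_size),
            P = matrix(rnorm(LM_MAX_POSITIONS * config$embedding_size,
                             sd = 0.1),
                       LM_MAX_POSITIONS, config$embedding_size),
            bdec = numeric(V))
  for (l in seq_len(config$n_layers)) {
    d <- lm_layer_dims(config)[[l]]
    p[[paste0("Wz", l)]] <- glorot(d["d_in"], d["d_out"])
    p[[paste0("bz", l)]] <- numeric(d["d_out"])
    p[[paste0("Wf", l)]] <- glorot(d["d_in"], d["d_out"])
    # gate bias > 0 starts the layer close to a copy gate (stable memory)
    p[[paste0("bf", l)]] <- rep(1, d["d_out"])
  }
  p
}

# variational dropout: one mask per batch, shared across time steps
lm_make_masks <- function(n, config, classifier = FALSE) {
  dims <- lm_layer_dims(config)
  rate_in <- 1 - (1 - config$dropout_input) * (1 - config$dropout_embedding)
  list(input = dropout_mask(n, config$embedding_size, rate_in),
       hidden = lapply(seq_len(max(config$n_layers - 1L, 0L)), function(l)
         dropout_mask(n, dims[[l]]["d_out"], config$dropout_hidden)),
       output = dropout_mask(n, config$embedding_size,
                             if (classifier) config$classifier_dropout
                             else config$dropout_output))
}

# replicate a per-sample mask across T time steps (row order: sample
# fastest, then time — matching column-major flattening of [n, T])
rep_mask <- function(M, T_) {
  if (is.null(M)) return(NULL)
  M[rep(seq_len(nrow(M)), T_), , drop = FALSE]
}

# Encoder forward over an id matrix [n, T]. All gate projections are
# batched across time into single matmuls; only the f-pooling recurrence
# loops over T with elementwise ops. Row order of the flat (n*T) matrices:
# sample index fastest, then time (row (t-1)*n + i).
qrnn_forward <- function(params, config, ids, masks = NULL) {
  n <- nrow(ids); T_ <- ncol(ids)
  dims <- lm_layer_dims(config)
  emb <- config$embedding_size
  pos <- pmin(rep(seq_len(T_), each = n), LM_MAX_POSITIONS)
  X2 <- params$E[as.vector(ids), , drop = FALSE] +
    params$P[pos, , drop = FALSE]
  if (!is.null(masks)) X2 <- apply_mask(X2, rep_mask(masks$input, T_))
  store <- vector("list", config$n_layers)
  layer_in <- X2
  for (l in seq_len(config$n_layers)) {
    d_out <- dims[[l]]["d_out"]
    Z <- tanh(sweep(layer_in %*% params[[paste0("Wz", l)]], 2L,
                    params[[paste0("bz", l)]], "+"))
    Fg <- sigmoid(sweep(layer_in %*% params[[paste0("Wf", l)]], 2L,
                        params[[paste0("bf", l)]], "+"))
    H <- matrix(0, n * T_, d_out)
    h_prev <- matrix(0, n, d_out)
    for (t in seq_len(T_)) {
      rows <- ((t - 1L) * n + 1L):(t * n)
      ft <- Fg[rows, , drop = FALSE]
      h_prev <- ft * h_prev + (1 - ft) * Z[rows, , drop = FALSE]
      H[rows, ] <- h_prev
    }
    store[[l]] <- list(X = layer_in, Z = Z, Fg = Fg, H = H)
    out <- H
    if (l < config$n_layers && !is.null(masks) &&
        !is.null(masks$hidden[[l]]))
      out <- out * rep_mask(masks$hidden[[l]], T_)
    layer_in <- out
  }
  H_out <- layer_in
  if (!is.null(masks) && !is.null(masks$output))
    H_out <- H_out * rep_mask(masks$output, T_)
  list(store = store, H_out = H_out, ids = ids, n = n, T_ = T_,
       masks = masks)
}

# BPTT. dH_out: (n*T) x emb gradient on the (post-dropout) top states.
# Returns parameter grads (embedding grads only from the input path; the
# tied-decoder contribution is added by the caller) and the input-level
# gradient dXin ((n*T) x emb, post-positional-sum).
qrnn_backward <- function(params, config, fw, dH_out) {
  ids <- fw$ids; masks <- fw$masks
  n <- fw$n; T_ <- fw$T_
  dims <- lm_layer_dims(config)
  g <- list()
  if (!is.null(masks) && !is.null(masks$output))
    dH_out <- dH_out * rep_mask(masks$output, T_)
  dH_layer <- dH_out
  for (l in rev(seq_len(config$n_layers))) {
    st <- fw$store[[l]]
    d_out <- dims[[l]]["d_out"]
    dZpre <- matrix(0, n * T_, d_out)
    dFpre <- matrix(0, n * T_, d_out)
    dh_carry <- matrix(0, n, d_out)
    for (t in rev(seq_len(T_))) {
      rows <- ((t - 1L) * n + 1L):(t * n)
      dh <- dH_layer[rows, , drop = FALSE] + dh_carry
      zt <- st$Z[rows, , drop = FALSE]
      ft <- st$Fg[rows, , drop = FALSE]
      h_prev <- if (t > 1L)
        st$H[((t - 2L) * n + 1L):((t - 1L) * n), , drop = FALSE]
      else matrix(0, n, d_out)
      dZpre[rows, ] <- (dh * (1 - ft)) * (1 - zt^2)
      dFpre[rows, ] <- (dh * (h_prev - zt)) * ft * (1 - ft)
      dh_carry <- dh * ft
    }
    g[[paste0("Wz", l)]] <- crossprod(st$X, dZpre)
    g[[paste0("bz", l)]] <- colSums(dZpre)
    g[[paste0("Wf", l)]] <- crossprod(st$X, dFpre)
    g[[paste0("bf", l)]] <- colSums(dFpre)
    dX <- dZpre %*% t(params[[paste0("Wz", l)]]) +
      dFpre %*% t(params[[paste0("Wf", l)]])
    if (l > 1L && !is.null(masks) && !is.null(masks$hidden[[l - 1L]]))
      dX <- dX * rep_mask(masks$hidden[[l - 1L]], T_)
    dH_layer <- dX
  }
  dXin <- dH_layer
  dmasked <- if (!is.null(masks) && !is.null(masks$input))
    dXin * rep_mask(masks$input, T_) else dXin
  dE <- params$E * 0
  acc <- rowsum(dmasked, group = as.vector(ids))
  dE[as.integer(rownames(acc)), ] <- acc
  g$E <- dE
  pos <- pmin(rep(seq_len(T_), each = n), LM_MAX_POSITIONS)
  dP <- params$P * 0
  accp <- rowsum(dmasked, group = pos)
  dP[as.integer(rownames(accp)), ] <- accp
  g$P <- dP
  list(grads = g, dXin = dXin)
}

cosine_lr <- function(base, epoch, epochs) {
  0.5 * base * (1 + cos(pi * (epoch - 1) / max(1L, epochs)))
}

lm_token_matrix <- function(config, seqs) {
  tokenize_batch(normalize_seq(seqs), k = config$k, stride = config$stride)
}

# mean next-token cross-entropy of a batch; optionally returns gradients
lm_next_token_pass <- function(params, config, ids, masks = NULL,
                               want_grads = FALSE) {
  V <- lm_vocab_size(config)
  n <- nrow(ids); T_ <- ncol(ids)
  inputs <- cbind(rep(LM_BOS(config), n), ids[, -T_, drop = FALSE])
  fw <- qrnn_forward(params, config, inputs, masks)
  Edec <- params$E[seq_len(V), , drop = FALSE]
  total <- n * T_
  logits <- sweep(fw$H_out %*% t(Edec), 2L, params$bdec, "+")
  p <- softmax_rows(logits)
  tgt <- cbind(seq_len(n * T_), as.vector(ids))
  loss <- -sum(log(pmax(p[tgt], 1e-12))) / total
  if (!want_grads) return(list(loss = loss))
  dlog <- p
  dlog[tgt] <- dlog[tgt] - 1
  dlog <- dlog / total
  dH <- dlog %*% Edec
  bw <- qrnn_backward(params, config, fw, dH)
  bw$grads$E[seq_len(V), ] <- bw$grads$E[seq_len(V), , drop = FALSE] +
    crossprod(dlog, fw$H_out)
  bw$grads$bdec <- colSums(dlog)
  list(loss = loss, grads = bw$grads)
}

#' Pre-train the language model on a switch corpus
#'
#' Self-supervised next-token modelling over k-mer tokens with the decoder
#' weights tied to the embedding, Adam under a cosine learning-rate
#' schedule, and held-out perplexity reported in the manifest.
#'
#' @param corpus Character vector of switch sequences (e.g. from
#'   [build_corpus()]).
#' @param config An [lm_config()].
#' @param holdout_fraction Corpus fraction held out for perplexity
#'   (default 0.1).
#' @return A `toehold_lm` model handle (encoder + decoder).
#' @export
pretrain_lm <- function(corpus, config = lm_config(),
                        holdout_fraction = 0.1) {
  stopifnot(length(corpus) > 0)
  with_seed(config$seed, {
    ids <- lm_token_matrix(config, corpus)
    n_val <- max(1L, round(holdout_fraction * nrow(ids)))
    val_idx <- sample.int(nrow(ids), n_val)
    ids_tr <- ids[-val_idx, , drop = FALSE]
    ids_val <- ids[val_idx, , drop = FALSE]
    params <- lm_init_params(config)
    opt <- adam_new(params, lr = config$learning_rate,
                    weight_decay = config$weight_decay)
    n <- nrow(ids_tr)
    final_loss <- NA_real_
    for (epoch in seq_len(config$epochs)) {
      lr <- cosine_lr(config$learning_rate, epoch, config$epochs)
      ord <- sample.int(n)
      for (start in seq.int(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        masks <- lm_make_masks(length(idx), config)
        pass <- lm_next_token_pass(params, config,
                                   ids_tr[idx, , drop = FALSE],
                                   masks, want_grads = TRUE)
        st <- adam_step(opt, params, pass$grads, lr = lr)
        opt <- st$opt; params <- st$params
        final_loss <- pass$loss
      }
    }
    val_loss <- lm_next_token_pass(params, config, ids_val)$loss
    structure(list(kind = "lm", config = config, params = params,
                   vocab = kmer_vocabulary(config$k),
                   manifest = list(n_train = n, seed = config$seed,
                                   epochs = config$epochs,
                                   final_train_loss = final_loss,
                                   holdout_perplexity = exp(val_loss))),
              class = "toehold_lm")
  })
}

#' @export
print.toehold_lm <- function(x, ...) {
  cat("Toehold k-mer language model (", x$config$n_layers,
      " QRNN layers, ", x$config$hidden_size, " hidden, ",
      x$config$embedding_size, "-dim embedding, k=", x$config$k, ")\n",
      sep = "")
  if (!is.null(x$manifest$holdout_perplexity))
    cat("  held-out perplexity: ",
        signif(x$manifest$holdout_perplexity, 4), "\n", sep = "")
  invisible(x)
}

#' Held-out perplexity of a language model
#'
#' @param model A `toehold_lm`.
#' @param seqs Character vector of switch sequences.
#' @return exp(mean next-token cross-entropy).
#' @export
lm_perplexity <- function(model, seqs) {
  ids <- lm_token_matrix(model$config, seqs)
  exp(lm_next_token_pass(model$params, model$config, ids)$loss)
}

#' Sample sequences from the language model decoder
#'
#' Autoregressive sampling of token streams from the start-of-sequence
#' state; tokens are concatenated, so sampled sequences cover the
#' tokenized span (57 nt for the default 59-nt/k=3 setup).
#'
#' @param model A `toehold_lm`.
#' @param n Number of sequences.
#' @param n_tokens Tokens per sequence (default: full switch span).
#' @param temperature Softmax temperature (default 1).
#' @param seed Integer seed.
#' @return Character vector of sampled sequences.
#' @export
sample_lm <- function(model, n, n_tokens = 19L, temperature = 1,
                      seed = NULL) {
  config <- model$config
  V <- lm_vocab_size(config)
  kmers <- names(model$vocab)
  with_seed(seed, {
    dims <- lm_layer_dims(config)
    out <- character(n)
    Edec <- model$params$E[seq_len(V), , drop = FALSE]
    for (i in seq_len(n)) {
      h <- lapply(dims, function(d) numeric(d["d_out"]))
      tok <- LM_BOS(config)
      toks <- integer(n_tokens)
      for (t in seq_len(n_tokens)) {
        x <- model$params$E[tok, ] +
          model$params$P[min(t, LM_MAX_POSITIONS), ]
        for (l in seq_len(config$n_layers)) {
          z <- tanh(drop(x %*% model$params[[paste0("Wz", l)]]) +
                      model$params[[paste0("bz", l)]])
          f <- sigmoid(drop(x %*% model$params[[paste0("Wf", l)]]) +
                         model$params[[paste0("bf", l)]])
          h[[l]] <- f * h[[l]] + (1 - f) * z
          x <- h[[l]]
        }
        logits <- drop(Edec %*% x) + model$params$bdec
        p <- exp((logits - max(logits)) / temperature)
        tok <- sample.int(V, 1L, prob = p)
        toks[t] <- tok
      }
      out[i] <- paste(kmers[toks], collapse = "")
    }
    out
  })
}

#' Embed sequences with the language-model encoder
#'
#' The final-layer hidden state averaged across all tokens, the
#' representation used for manifold visualization and linear probes.
#'
#' @param model A `toehold_lm` or `toehold_lm_classifier`.
#' @param seqs Character vector of sequences.
#' @return n x embedding_size numeric matrix.
#' @export
lm_embed <- function(model, seqs) {
  config <- model$config
  ids <- lm_token_matrix(config, seqs)
  if (identical(model$direction, "backward"))
    ids <- ids[, rev(seq_len(ncol(ids))), drop = FALSE]
  fw <- qrnn_forward(model$params, config, ids)
  n <- fw$n; T_ <- fw$T_
  out <- matrix(0, n, config$embedding_size)
  for (t in seq_len(T_))
    out <- out + fw$H_out[((t - 1L) * n + 1L):(t * n), , drop = FALSE]
  out / T_
}

lm_frozen_param_names <- function(freeze_layers) {
  if (freeze_layers < 1L) return(character(0))
  unlist(lapply(seq_len(freeze_layers), function(l)
    paste0(c("Wz", "bz", "Wf", "bf"), l)))
}

# classifier forward: returns p_good and the pieces needed for backprop
lm_cls_forward <- function(params, config, ids, masks = NULL) {
  fw <- qrnn_forward(params, config, ids, masks)
  n <- fw$n; T_ <- fw$T_
  hbar <- matrix(0, n, config$embedding_size)
  for (t in seq_len(T_))
    hbar <- hbar + fw$H_out[((t - 1L) * n + 1L):(t * n), , drop = FALSE]
  hbar <- hbar / T_
  logits <- sweep(hbar %*% params$Wc, 2L, params$bc, "+")
  p <- softmax_rows(logits)
  list(fw = fw, hbar = hbar, logits = logits, p = p)
}

#' Train a good/bad classifier on the language-model encoder
#'
#' Attaches a linear classification head to the (pre-trained or fresh)
#' encoder and fine-tunes with label-smoothing cross-entropy. Labels come
#' from the `label` column when present, otherwise from the top-`q` ON/OFF
#' split. The first `freeze_layers` QRNN layers are frozen bit-for-bit.
#'
#' @param encoder A pre-trained `toehold_lm`, or `NULL` for a naive
#'   (randomly initialized) encoder.
#' @param data data.frame with `switch_seq` and either `label`
#'   ("good"/"bad") or `onoff`.
#' @param config An [lm_config()]; defaults to the encoder's.
#' @param freeze_layers How many bottom QRNN layers to freeze (default 0).
#' @param direction `"forward"` or `"backward"` (backward consumes
#'   reversed token streams).
#' @param q Top fraction defining "good" when labels are derived
#'   (default 0.25).
#' @param epochs Fine-tuning epochs (default: `config$epochs`).
#' @return A `toehold_lm_classifier` handle.
#' @export
train_classifier <- function(encoder, data, config = NULL,
                             freeze_layers = 0L,
                             direction = c("forward", "backward"),
                             q = 0.25, epochs = NULL) {
  direction <- match.arg(direction)
  if (is.null(config)) {
    if (is.null(encoder)) stop("config required for a naive classifier")
    config <- encoder$config
  }
  if (is.null(epochs)) epochs <- config$epochs
  labels <- if (!is.null(data$label) && !anyNA(data$label)) data$label
            else quartile_labels(data$onoff, q)$labels
  if (length(unique(labels)) < 2L)
    stop("training data contains a single class")
  y <- as.integer(labels == "good") + 1L  # class 2 = good
  with_seed(config$seed, {
    ids <- lm_token_matrix(config, data$switch_seq)
    if (direction == "backward")
      ids <- ids[, rev(seq_len(ncol(ids))), drop = FALSE]
    params <- if (is.null(encoder)) lm_init_params(config)
              else encoder$params
    params$Wc <- glorot(config$embedding_size, 2L)
    params$bc <- numeric(2L)
    frozen <- lm_frozen_param_names(freeze_layers)
    opt <- adam_new(params, lr = config$learning_rate,
                    weight_decay = config$weight_decay)
    n <- nrow(ids)
    T_ <- ncol(ids)
    eps <- config$label_smoothing
    for (epoch in seq_len(epochs)) {
      lr <- cosine_lr(config$learning_rate, epoch, epochs)
      ord <- sample.int(n)
      for (start in seq.int(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        nb <- length(idx)
        masks <- lm_make_masks(nb, config, classifier = TRUE)
        cf <- lm_cls_forward(params, config, ids[idx, , drop = FALSE],
                             masks)
        q_tgt <- matrix(eps / 2, nb, 2L)
        q_tgt[cbind(seq_len(nb), y[idx])] <- 1 - eps / 2
        dlog <- (cf$p - q_tgt) / nb
        dhbar <- dlog %*% t(params$Wc)
        dH <- dhbar[rep(seq_len(nb), T_), , drop = FALSE] / T_
        bw <- qrnn_backward(params, config, cf$fw, dH)
        bw$grads$Wc <- crossprod(cf$hbar, dlog)
        bw$grads$bc <- colSums(dlog)
        st <- adam_step(opt, params, bw$grads, skip = frozen, lr = lr)
        opt <- st$opt; params <- st$params
      }
    }
    structure(list(kind = "lm_classifier", config = config,
                   params = params, vocab = kmer_vocabulary(config$k),
                   direction = direction,
                   threshold_spec = list(q = q, on = "onoff"),
                   frozen_layers = freeze_layers,
                   manifest = list(n_train = n, seed = config$seed,
                                   epochs = epochs,
                                   pretrained = !is.null(encoder))),
              class = "toehold_lm_classifier")
  })
}

#' @export
print.toehold_lm_classifier <- function(x, ...) {
  cat("Toehold LM classifier (", x$direction, ", top ",
      100 * x$threshold_spec$q, "% = good, ",
      if (x$manifest$pretrained) "pre-trained" else "naive",
      " encoder)\n", sep = "")
  invisible(x)
}

# directional probability of the "good" class
lm_cls_pgood <- function(cls, seqs) {
  ids <- lm_token_matrix(cls$config, seqs)
  if (cls$direction == "backward")
    ids <- ids[, rev(seq_len(ncol(ids))), drop = FALSE]
  lm_cls_forward(cls$params, cls$config, ids)$p[, 2L]
}

#' Classify switches with a forward/backward model pair
#'
#' Direction-agnostic prediction: the good-class probabilities of the
#' forward model and of the backward model (which consumes reversed token
#' streams) are arithmetically averaged.
#'
#' @param cls_forward,cls_backward `toehold_lm_classifier` handles trained
#'   with the same tokenizer and threshold specification. Passing the same
#'   model twice makes the averaging a no-op.
#' @param seqs Character vector of switches.
#' @param threshold Decision threshold on the averaged probability
#'   (default 0.5).
#' @return data.frame with `p_good` and `label`.
#' @export
classify_switches <- function(cls_forward, cls_backward, seqs,
                              threshold = 0.5) {
  if (!identical(cls_forward$threshold_spec, cls_backward$threshold_spec))
    stop("classifier pair was trained with different threshold specs")
  if (cls_forward$config$k != cls_backward$config$k ||
      cls_forward$config$stride != cls_backward$config$stride)
    stop("classifier pair uses different tokenizers")
  p <- (lm_cls_pgood(cls_forward, seqs) +
          lm_cls_pgood(cls_backward, seqs)) / 2
  data.frame(p_good = p,
             label = ifelse(p >= threshold, "good", "bad"))
}
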