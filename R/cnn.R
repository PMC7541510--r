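#' Configuration of the convolutional ON/OFF regressor
#'
#' The two-head sequence regressor: two "valid" 1-D convolutional layers
#' over the one-hot sequence (10 filters of width 5, then 5 filters of
#' width 3), a flatten, three fully connected ReLU layers (150, 60, 15),
#' and two independent linear output heads for ON and OFF. Dropout follows
#' every hidden layer and an L2 penalty is placed on layer activations
#' (not weights). Trained with Adam on mean-squared error, both heads
#' jointly, with early stopping on a held-out split.
#'
#' @param conv1_filters,conv1_width First convolutional layer (default 10 x 5).
#' @param conv2_filters,conv2_width Second convolutional layer (default 5 x 3).
#' @param dense_sizes Hidden fully-connected sizes (default `c(150, 60, 15)`).
#' @param dropout Dropout rate after each hidden layer (default 0.3).
#' @param activity_l2 L2 coefficient on hidden activations (default 0.001).
#' @param learning_rate Adam learning rate (default 0.005).
#' @param batch_size Minibatch size (default 128).
#' @param epochs Maximum training epochs (default 200).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout; training is fully reproducible given the seed.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(conv1_filters = 10L, conv1_width = 5L,
                       conv2_filters = 5L, conv2_width = 3L,
                       dense_sizes = c(150L, 60L, 15L),
                       dropout = 0.3, activity_l2 = 0.001,
                       learning_rate = 0.005, batch_size = 128L,
                       epochs = 200L, patience = 10L, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, all(dense_sizes > 0))
  structure(list(conv1_filters = as.integer(conv1_filters),
                 conv1_width = as.integer(conv1_width),
                 conv2_filters = as.integer(conv2_filters),
                 conv2_width = as.integer(conv2_width),
                 dense_sizes = as.integer(dense_sizes),
                 dropout = dropout, activity_l2 = activity_l2,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

cnn_geometry <- function(config, input_len = 59L) {
  g1 <- conv_geom(input_len, 4L, config$conv1_width)
  g2 <- conv_geom(g1$L_out, config$conv1_filters, config$conv2_width)
  list(input_len = input_len, g1 = g1, g2 = g2,
       flat = g2$L_out * config$conv2_filters)
}

cnn_init_params <- function(config, geom, heads = 2L) {
  ds <- config$dense_sizes
  p <- list(
    W1 = glorot(config$conv1_width * 4L, config$conv1_filters),
    b1 = numeric(config$conv1_filters),
    W2 = glorot(config$conv2_width * config$conv1_filters,
                config$conv2_filters),
    b2 = numeric(config$conv2_filters),
    Wd1 = glorot(geom$flat, ds[1]), bd1 = numeric(ds[1]),
    Wd2 = glorot(ds[1], ds[2]), bd2 = numeric(ds[2]),
    Wd3 = glorot(ds[2], ds[3]), bd3 = numeric(ds[3])
  )
  if (heads == 2L) {
    p$Won <- glorot(ds[3], 1L); p$bon <- 0
    p$Woff <- glorot(ds[3], 1L); p$boff <- 0
  } else {
    p$Wout <- glorot(ds[3], 1L); p$bout <- 0
  }
  p
}

CNN_CONV_PARAMS <- c("W1", "b1", "W2", "b2")

# Forward pass. `masks` non-NULL during training (inverted dropout).
cnn_forward <- function(params, X, config, geom, masks = NULL,
                        single_head = FALSE) {
  mk <- function(i) if (is.null(masks)) NULL else masks[[i]]
  Z1 <- conv_forward(X, params$W1, params$b1, geom$g1)
  A1 <- relu(Z1); A1d <- apply_mask(A1, mk(1))
  Z2 <- conv_forward(A1d, params$W2, params$b2, geom$g2)
  A2 <- relu(Z2); A2d <- apply_mask(A2, mk(2))
  Z3 <- sweep(A2d %*% params$Wd1, 2L, params$bd1, "+")
  A3 <- relu(Z3); A3d <- apply_mask(A3, mk(3))
  Z4 <- sweep(A3d %*% params$Wd2, 2L, params$bd2, "+")
  A4 <- relu(Z4); A4d <- apply_mask(A4, mk(4))
  Z5 <- sweep(A4d %*% params$Wd3, 2L, params$bd3, "+")
  A5 <- relu(Z5); A5d <- apply_mask(A5, mk(5))
  out <- if (single_head) {
    list(yout = drop(A5d %*% params$Wout) + params$bout)
  } else {
    list(yon = drop(A5d %*% params$Won) + params$bon,
         yoff = drop(A5d %*% params$Woff) + params$boff)
  }
  c(out, list(X = X, Z1 = Z1, A1 = A1, A1d = A1d, Z2 = Z2, A2 = A2,
              A2d = A2d, Z3 = Z3, A3d = A3d, Z4 = Z4, A4d = A4d,
              Z5 = Z5, A5d = A5d, masks = masks))
}

# Backward pass from per-head output gradients; returns parameter grads and
# the input gradient. `act_l2_n` > 0 adds the activity-penalty gradient for
# a batch of that size.
cnn_backward <- function(params, fw, config, geom, dyon = NULL, dyoff = NULL,
                         dyout = NULL, act_l2_n = 0) {
  mk <- function(i) if (is.null(fw$masks)) NULL else fw$masks[[i]]
  g <- list()
  if (!is.null(dyout)) {
    dyout <- matrix(dyout, ncol = 1L)
    g$Wout <- crossprod(fw$A5d, dyout); g$bout <- sum(dyout)
    dA5 <- dyout %*% t(params$Wout)
  } else {
    dyon <- matrix(dyon, ncol = 1L); dyoff <- matrix(dyoff, ncol = 1L)
    g$Won <- crossprod(fw$A5d, dyon); g$bon <- sum(dyon)
    g$Woff <- crossprod(fw$A5d, dyoff); g$boff <- sum(dyoff)
    dA5 <- dyon %*% t(params$Won) + dyoff %*% t(params$Woff)
  }
  lam <- config$activity_l2
  addl2 <- function(dA, A) if (act_l2_n > 0 && lam > 0)
    dA + 2 * lam * A / act_l2_n else dA
  dA5 <- apply_mask(dA5, mk(5))
  dA5 <- addl2(dA5, relu(fw$Z5))
  dZ5 <- dA5 * (fw$Z5 > 0)
  g$Wd3 <- crossprod(fw$A4d, dZ5); g$bd3 <- colSums(dZ5)
  dA4 <- apply_mask(dZ5 %*% t(params$Wd3), mk(4))
  dA4 <- addl2(dA4, relu(fw$Z4))
  dZ4 <- dA4 * (fw$Z4 > 0)
  g$Wd2 <- crossprod(fw$A3d, dZ4); g$bd2 <- colSums(dZ4)
  dA3 <- apply_mask(dZ4 %*% t(params$Wd2), mk(3))
  dA3 <- addl2(dA3, relu(fw$Z3))
  dZ3 <- dA3 * (fw$Z3 > 0)
  g$Wd1 <- crossprod(fw$A2d, dZ3); g$bd1 <- colSums(dZ3)
  dA2 <- apply_mask(dZ3 %*% t(params$Wd1), mk(2))
  dA2 <- addl2(dA2, fw$A2)
  dZ2 <- dA2 * (fw$Z2 > 0)
  cb2 <- conv_backward(fw$A1d, params$W2, dZ2, geom$g2)
  g$W2 <- cb2$dW; g$b2 <- cb2$db
  dA1 <- apply_mask(cb2$dX, mk(1))
  dA1 <- addl2(dA1, fw$A1)
  dZ1 <- dA1 * (fw$Z1 > 0)
  cb1 <- conv_backward(fw$X, params$W1, dZ1, geom$g1)
  g$W1 <- cb1$dW; g$b1 <- cb1$db
  list(grads = g, dX = cb1$dX)
}

cnn_make_masks <- function(n, config, geom) {
  if (config$dropout <= 0) return(NULL)
  ds <- config$dense_sizes
  sizes <- c(geom$g1$L_out * config$conv1_filters, geom$flat,
             ds[1], ds[2], ds[3])
  lapply(sizes, function(m) dropout_mask(n, m, config$dropout))
}

cnn_val_loss <- function(params, X, Yon, Yoff, config, geom,
                         single_head = FALSE, Yout = NULL) {
  fw <- cnn_forward(params, X, config, geom, single_head = single_head)
  if (single_head) mean((fw$yout - Yout)^2)
  else mean((fw$yon - Yon)^2 + (fw$yoff - Yoff)^2)
}

# shared training loop for the 2-head regressor and the 1-head transfer model
cnn_fit <- function(params, Xtr, Ytr, Xval, Yval, config, geom,
                    frozen = character(0), single_head = FALSE) {
  opt <- adam_new(params, lr = config$learning_rate)
  n <- nrow(Xtr)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (start in seq.int(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      nb <- length(idx)
      masks <- cnn_make_masks(nb, config, geom)
      fw <- cnn_forward(params, Xtr[idx, , drop = FALSE], config, geom,
                        masks = masks, single_head = single_head)
      if (single_head) {
        dyout <- 2 * (fw$yout - Ytr$out[idx]) / nb
        bw <- cnn_backward(params, fw, config, geom, dyout = dyout,
                           act_l2_n = nb)
      } else {
        dyon <- 2 * (fw$yon - Ytr$on[idx]) / nb
        dyoff <- 2 * (fw$yoff - Ytr$off[idx]) / nb
        bw <- cnn_backward(params, fw, config, geom, dyon = dyon,
                           dyoff = dyoff, act_l2_n = nb)
      }
      st <- adam_step(opt, params, bw$grads, skip = frozen)
      opt <- st$opt; params <- st$params
    }
    vl <- if (single_head)
      cnn_val_loss(params, Xval, NULL, NULL, config, geom,
                   single_head = TRUE, Yout = Yval$out)
    else cnn_val_loss(params, Xval, Yval$on, Yval$off, config, geom)
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(params = best$params, val_loss = best$loss, epochs_run = epoch,
       best_epoch = best$epoch)
}

#' Train the convolutional ON/OFF regressor
#'
#' Trains both heads jointly on mean-squared error with Adam, holding out a
#' fraction of the data for early stopping. Fully deterministic given
#' `config$seed`.
#'
#' @param data data.frame with `switch_seq`, `on`, `off` columns (e.g. from
#'   [build_labeled_dataset()] or [read_dataset()]).
#' @param config A [cnn_config()].
#' @param holdout_fraction Fraction held out for early stopping
#'   (default 0.15).
#' @param val_data Optional explicit validation data.frame (overrides the
#'   internal split; used by [cross_validate()]).
#' @return A `toehold_cnn` model handle.
#' @export
train_cnn <- function(data, config = cnn_config(), holdout_fraction = 0.15,
                      val_data = NULL) {
  if (nrow(data) < 2L) stop("need at least 2 training records")
  if (anyNA(data$on) || anyNA(data$off)) stop("on/off values missing")
  with_seed(config$seed, {
    seqs <- normalize_seq(data$switch_seq)
    len <- nchar(seqs[1])
    geom <- cnn_geometry(config, len)
    X <- encode_batch(seqs, len)
    if (is.null(val_data)) {
      n_val <- max(1L, round(holdout_fraction * nrow(X)))
      val_idx <- sample.int(nrow(X), n_val)
      Xval <- X[val_idx, , drop = FALSE]
      Yval <- list(on = data$on[val_idx], off = data$off[val_idx])
      Xtr <- X[-val_idx, , drop = FALSE]
      Ytr <- list(on = data$on[-val_idx], off = data$off[-val_idx])
    } else {
      vseqs <- normalize_seq(val_data$switch_seq)
      Xval <- encode_batch(vseqs, len)
      Yval <- list(on = val_data$on, off = val_data$off)
      Xtr <- X; Ytr <- list(on = data$on, off = data$off)
    }
    params <- cnn_init_params(config, geom)
    fit <- cnn_fit(params, Xtr, Ytr, Xval, Yval, config, geom)
    structure(list(kind = "cnn", heads = "on_off", config = config,
                   geom = geom, params = fit$params,
                   alphabet = RNA_ALPHABET,
                   manifest = list(n_train = nrow(Xtr), seed = config$seed,
                                   epochs_run = fit$epochs_run,
                                   best_epoch = fit$best_epoch,
                                   val_loss = fit$val_loss)),
              class = "toehold_cnn")
  })
}

#' @export
print.toehold_cnn <- function(x, ...) {
  cat("Toehold CNN regressor (", x$heads, " head), input ",
      x$geom$input_len, " nt\n", sep = "")
  cat("  conv ", x$config$conv1_filters, "x", x$config$conv1_width, " -> ",
      x$config$conv2_filters, "x", x$config$conv2_width, ", dense ",
      paste(x$config$dense_sizes, collapse = "/"), "\n", sep = "")
  cat("  trained ", x$manifest$epochs_run, " epochs (best ",
      x$manifest$best_epoch, "), val loss ",
      signif(x$manifest$val_loss, 4), "\n", sep = "")
  invisible(x)
}

# forward on a pre-encoded matrix (also accepts relaxed/soft rows)
cnn_predict_matrix <- function(model, X) {
  fw <- cnn_forward(model$params, X, model$config, model$geom,
                    single_head = model$heads == "single")
  if (model$heads == "single") data.frame(onoff = fw$yout)
  else data.frame(on = fw$yon, off = fw$yoff)
}

#' Predict ON/OFF values for switch sequences
#'
#' Deterministic (dropout off) and order-preserving; results are independent
#' of how the input is batched.
#'
#' @param object A `toehold_cnn` model.
#' @param seqs Character vector of full-length switch sequences.
#' @param ... Unused.
#' @return data.frame with `on` and `off` columns (or `onoff` for a
#'   single-head transfer model).
#' @export
predict.toehold_cnn <- function(object, seqs, ...) {
  X <- encode_batch(normalize_seq(seqs), object$geom$input_len)
  cnn_predict_matrix(object, X)
}

# gradient of one head's output w.r.t. the one-hot input
# head: "on", "off", or "both" (summed with weights)
cnn_input_gradient <- function(model, X, head = c("on", "off"),
                               w_on = 1, w_off = 0) {
  single <- model$heads == "single"
  fw <- cnn_forward(model$params, X, model$config, model$geom,
                    single_head = single)
  n <- nrow(X)
  if (single) {
    bw <- cnn_backward(model$params, fw, model$config, model$geom,
                       dyout = rep(w_on, n))
  } else {
    head <- if (is.character(head)) match.arg(head) else head
    if (identical(head, "on")) { w_on <- 1; w_off <- 0 }
    else if (identical(head, "off")) { w_on <- 0; w_off <- 1 }
    bw <- cnn_backward(model$params, fw, model$config, model$geom,
                       dyon = rep(w_on, n), dyoff = rep(w_off, n))
  }
  bw$dX
}

stratified_folds <- function(labels, n_folds, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      if (length(idx) < n_folds)
        stop("class '", cl, "' has fewer members than folds")
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Stratified k-fold cross-validation of the CNN
#'
#' Folds are stratified on the top-quartile ON/OFF class so the class
#' imbalance is preserved in every fold. Within each fold, half of the test
#' fold drives early stopping and the other half is scored, so reported
#' metrics never touch sequences the stopping rule saw.
#'
#' @param data Labeled data.frame (`switch_seq`, `on`, `off`, `onoff`).
#' @param config A [cnn_config()].
#' @param n_folds Number of folds (>= 2).
#' @param q Top fraction defining the stratification class (default 0.25).
#' @return data.frame with one row per fold: `fold`, `r2_on`, `r2_off`,
#'   `spearman_on`, `spearman_off`, `mse_on`, `mse_off`.
#' @export
cross_validate <- function(data, config = cnn_config(), n_folds = 10L,
                           q = 0.25) {
  stopifnot(n_folds >= 2L)
  labels <- quartile_labels(data$onoff, q)$labels
  fold <- stratified_folds(labels, n_folds, seed = config$seed)
  res <- lapply(seq_len(n_folds), function(f) {
    test_idx <- which(fold == f)
    half <- with_seed(config$seed + f,
                      sample(test_idx, length(test_idx) %/% 2L))
    score_idx <- setdiff(test_idx, half)
    m <- train_cnn(data[fold != f, , drop = FALSE], config,
                   val_data = data[half, , drop = FALSE])
    pr <- predict(m, data$switch_seq[score_idx])
    data.frame(fold = f,
               r2_on = metric(data$on[score_idx], pr$on, "r2"),
               r2_off = metric(data$off[score_idx], pr$off, "r2"),
               spearman_on = metric(data$on[score_idx], pr$on, "spearman"),
               spearman_off = metric(data$off[score_idx], pr$off, "spearman"),
               mse_on = metric(data$on[score_idx], pr$on, "mse"),
               mse_off = metric(data$off[score_idx], pr$off, "mse"))
  })
  do.call(rbind, res)
}

#' Random hyperparameter search
#'
#' Samples architectures uniformly from a value grid (random search, not a
#' combinatorial sweep), cross-validates each draw, and ranks by the mean of
#' ON and OFF R-squared.
#'
#' @param data Labeled data.frame.
#' @param grid Named list of candidate values; names must be [cnn_config()]
#'   arguments (e.g. `list(conv1_filters = c(5, 10, 15), conv1_width =
#'   c(3, 5, 7))`).
#' @param n_draws Number of random configurations.
#' @param seed Integer seed for both the draws and each training run.
#' @param n_folds Folds per draw (default 5).
#' @return data.frame ranked by decreasing `mean_r2`, one row per draw, with
#'   the sampled values and the score; the full configs are in
#'   `attr(, "configs")`.
#' @export
random_search <- function(data, grid, n_draws = 10L, seed = 1L,
                          n_folds = 5L) {
  stopifnot(length(grid) > 0)
  draws <- with_seed(seed, {
    lapply(seq_len(n_draws), function(i)
      lapply(grid, function(v) sample(v, 1L)))
  })
  configs <- lapply(draws, function(d)
    do.call(cnn_config, c(d, list(seed = seed))))
  scores <- vapply(configs, function(cf) {
    cv <- cross_validate(data, cf, n_folds = n_folds)
    mean(c(cv$r2_on, cv$r2_off))
  }, numeric(1))
  tab <- cbind(do.call(rbind, lapply(draws, as.data.frame)),
               mean_r2 = scores)
  ord <- order(-scores)
  out <- tab[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "configs") <- configs[ord]
  out
}

#' Transfer the CNN to a single-target dataset with frozen convolutions
#'
#' Freezes both convolutional layers bit-for-bit, replaces the two output
#' heads with a single linear head, and fine-tunes the dense stack on a
#' small dataset carrying one combined ON/OFF target.
#'
#' @param model A trained two-head `toehold_cnn`.
#' @param small_data data.frame with `switch_seq` and `onoff` columns.
#' @param config Optional [cnn_config()] for fine-tuning (architecture
#'   fields must match the base model; defaults to the base model's config).
#' @param holdout_fraction Early-stopping fraction (default 0.15).
#' @return A single-head `toehold_cnn`; its conv parameters are identical
#'   to the base model's.
#' @export
transfer_cnn <- function(model, small_data, config = NULL,
                         holdout_fraction = 0.15) {
  stopifnot(inherits(model, "toehold_cnn"), model$heads == "on_off")
  if (is.null(config)) config <- model$config
  with_seed(config$seed, {
    seqs <- normalize_seq(small_data$switch_seq)
    geom <- model$geom
    X <- encode_batch(seqs, geom$input_len)
    params <- model$params
    params$Won <- NULL; params$bon <- NULL
    params$Woff <- NULL; params$boff <- NULL
    ds <- config$dense_sizes
    params$Wout <- glorot(ds[3], 1L); params$bout <- 0
    n_val <- max(1L, round(holdout_fraction * nrow(X)))
    val_idx <- sample.int(nrow(X), n_val)
    fit <- cnn_fit(params,
                   X[-val_idx, , drop = FALSE],
                   list(out = small_data$onoff[-val_idx]),
                   X[val_idx, , drop = FALSE],
                   list(out = small_data$onoff[val_idx]),
                   config, geom, frozen = CNN_CONV_PARAMS,
                   single_head = TRUE)
    structure(list(kind = "cnn", heads = "single", config = config,
                   geom = geom, params = fit$params,
                   alphabet = RNA_ALPHABET,
                   manifest = list(n_train = nrow(X) - n_val,
                                   seed = config$seed,
                                   epochs_run = fit$epochs_run,
                                   best_epoch = fit$best_epoch,
                                   val_loss = fit$val_loss,
                                   transfer_from = model$manifest)),
              class = "toehold_cnn")
  })
}
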