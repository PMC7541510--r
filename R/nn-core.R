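# Minimal neural-network primitives shared by the CNN regressor and the
# language model: Adam state, ReLU, softmax, and a 1-D "valid" convolution
# over flat channel-major batches (row = sample, column = (pos-1)*C + chan).
# Everything is plain matrix algebra so gradients w.r.t. inputs are exact,
# which saliency and gradient-ascent design rely on.

relu <- function(x) (x > 0) * x

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# Adam with one state entry per parameter matrix
adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       weight_decay = weight_decay,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads, skip = character(0), lr = NULL) {
  opt$t <- opt$t + 1
  lr <- if (is.null(lr)) opt$lr else lr
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    if (nm %in% skip) next
    g <- grads[[nm]]
    if (is.null(g)) next
    if (opt$weight_decay > 0) g <- g + opt$weight_decay * params[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(opt = opt, params = params)
}

# column indices of the input slice feeding output position j
conv_geom <- function(L_in, C_in, width) {
  L_out <- L_in - width + 1L
  cols <- lapply(seq_len(L_out), function(j)
    ((j - 1L) * C_in + 1L):((j + width - 1L) * C_in))
  list(L_out = L_out, C_in = C_in, width = width, cols = cols)
}

# X [n, L_in*C_in] -> Z [n, L_out*F], channel-major
conv_forward <- function(X, W, b, geom) {
  n <- nrow(X)
  F_ <- ncol(W)
  Z <- matrix(0, n, geom$L_out * F_)
  for (j in seq_len(geom$L_out)) {
    Z[, ((j - 1L) * F_ + 1L):(j * F_)] <-
      X[, geom$cols[[j]], drop = FALSE] %*% W
  }
  sweep(Z, 2L, rep(b, geom$L_out), "+")
}

# returns dX, dW, db given upstream dZ
conv_backward <- function(X, W, dZ, geom) {
  n <- nrow(X)
  F_ <- ncol(W)
  dX <- matrix(0, n, ncol(X))
  dW <- W * 0
  db <- numeric(F_)
  for (j in seq_len(geom$L_out)) {
    dZj <- dZ[, ((j - 1L) * F_ + 1L):(j * F_), drop = FALSE]
    Xj <- X[, geom$cols[[j]], drop = FALSE]
    dW <- dW + crossprod(Xj, dZj)
    db <- db + colSums(dZj)
    dX[, geom$cols[[j]]] <- dX[, geom$cols[[j]], drop = FALSE] +
      dZj %*% t(W)
  }
  list(dX = dX, dW = dW, db = db)
}

glorot <- function(nin, nout) {
  matrix(runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

dropout_mask <- function(n, m, rate) {
  if (rate <= 0) return(NULL)
  matrix(rbinom(n * m, 1L, 1 - rate), n, m) / (1 - rate)
}

apply_mask <- function(A, M) if (is.null(M)) A else A * M
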