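test_that("a degenerate constant-target fit predicts the constant", {
  sw <- build_corpus(300, seed = 61)
  d <- data.frame(switch_seq = sw, on = 0.4, off = 0.4)
  m <- train_cnn(d, cnn_config(epochs = 70, seed = 2))
  pr <- predict(m, build_corpus(50, seed = 62))
  expect_true(all(abs(pr$on - 0.4) < 0.05))
  expect_true(all(abs(pr$off - 0.4) < 0.05))
})

test_that("training is reproducible and prediction is pure", {
  d <- build_labeled_dataset(400, seed = 63)
  cfg <- cnn_config(epochs = 5, seed = 9)
  m1 <- train_cnn(d, cfg)
  m2 <- train_cnn(d, cfg)
  expect_identical(m1$params, m2$params)
  probe <- build_corpus(20, seed = 64)
  p1 <- predict(m1, probe)
  expect_identical(p1, predict(m1, probe))
  # batch composition does not change predictions
  expect_equal(rbind(predict(m1, probe[1:7]), predict(m1, probe[8:20])),
               p1, tolerance = 1e-12)
  # single-sequence predicts concatenate to the batch predict
  singles <- do.call(rbind, lapply(probe[1:5], function(s)
    predict(m1, s)))
  expect_equal(singles, p1[1:5, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # outputs finite for all four homopolymers
  homo <- vapply(c("A", "C", "G", "U"), function(b) strrep(b, 59), "")
  expect_true(all(is.finite(unlist(predict(m1, homo)))))
  expect_error(predict(m1, "ACGU"), "length")
})

test_that("the CNN learns the oracle signal and not permuted labels", {
  d <- fixture_dataset()
  m <- fixture_cnn()
  holdout <- d[5001:5500, ]
  pr <- predict(m, holdout$switch_seq)
  r2_on <- metric(holdout$on, pr$on, "r2")
  expect_gte(r2_on, 0.5)
  # sanity floor: beat the train-mean predictor on held-out MSE
  expect_lt(metric(holdout$on, pr$on, "mse"),
            metric(holdout$on, rep(mean(d$on[1:5000]), 500), "mse"))
  # permuted labels destroy the signal
  dp <- d[1:2000, ]
  perm <- with_seed(65, sample.int(nrow(dp)))
  dp$on <- dp$on[perm]; dp$off <- dp$off[perm]
  mp <- train_cnn(dp, cnn_config(epochs = 30, seed = 7))
  prp <- predict(mp, holdout$switch_seq)
  expect_lte(metric(holdout$on, prp$on, "r2"), 0.05)
})

test_that("input gradients match finite differences", {
  d <- build_labeled_dataset(300, seed = 66)
  m <- train_cnn(d, cnn_config(epochs = 4, seed = 4))
  s <- build_corpus(1, seed = 67)
  X <- toeholdr:::encode_batch(s, 59)
  g <- toeholdr:::cnn_input_gradient(m, X, head = "on")
  eps <- 1e-5
  for (j in c(1, 40, 118, 236)) {
    Xp <- X; Xp[1, j] <- Xp[1, j] + eps
    Xm <- X; Xm[1, j] <- Xm[1, j] - eps
    fd <- (toeholdr:::cnn_predict_matrix(m, Xp)$on -
             toeholdr:::cnn_predict_matrix(m, Xm)$on) / (2 * eps)
    expect_equal(g[1, j], fd, tolerance = 1e-5)
  }
})

test_that("stratified cross-validation preserves fold structure", {
  d <- build_labeled_dataset(400, seed = 68)
  labels <- quartile_labels(d$onoff)$labels
  folds <- toeholdr:::stratified_folds(labels, 4L, seed = 1)
  expect_true(all(tabulate(folds) > 0))
  expect_equal(sort(unique(folds)), 1:4)
  # class ratio per fold within 1 item of the global split
  for (f in 1:4) {
    n_good <- sum(labels[folds == f] == "good")
    expect_lte(abs(n_good - sum(labels == "good") / 4), 1)
  }
  cv <- cross_validate(d, cnn_config(epochs = 3, seed = 3), n_folds = 3)
  expect_equal(nrow(cv), 3L)
  expect_true(all(is.finite(unlist(cv))))
  expect_true(all(cv$r2_on <= 1))
})

test_that("random search draws from the grid and ranks by combined R2", {
  d <- build_labeled_dataset(300, seed = 69)
  grid <- list(conv1_filters = c(5L, 10L), dropout = c(0.1, 0.3),
               epochs = 2L)
  rs <- random_search(d, grid, n_draws = 3, seed = 5, n_folds = 2)
  expect_equal(nrow(rs), 3L)
  expect_true(all(rs$conv1_filters %in% grid$conv1_filters))
  expect_true(all(rs$dropout %in% grid$dropout))
  expect_true(all(diff(rs$mean_r2) <= 1e-12))
  rs2 <- random_search(d, grid, n_draws = 3, seed = 5, n_folds = 2)
  expect_equal(rs, rs2, ignore_attr = TRUE)
})

test_that("transfer freezes convolutions bitwise and emits one value", {
  base <- fixture_cnn()
  shift <- oracle_params()
  # domain shift: flip the U-richness bonus and strengthen the GC penalty
  shift$on$u_26_30 <- -0.45
  shift$on$gc_13_30 <- -4
  small <- build_labeled_dataset(168, shift, seed = 70)
  tr <- transfer_cnn(base, small, cnn_config(epochs = 40, seed = 8))
  for (nm in c("W1", "b1", "W2", "b2"))
    expect_identical(tr$params[[nm]], base$params[[nm]])
  pr <- predict(tr, build_corpus(5, seed = 71))
  expect_equal(ncol(pr), 1L)
  expect_named(pr, "onoff")
})

test_that("frozen transfer beats from-scratch at small n on a shifted task", {
  base <- fixture_cnn()
  shift <- oracle_params()
  shift$on$u_26_30 <- -0.45
  shift$on$gc_13_30 <- -4
  small <- build_labeled_dataset(168, shift, seed = 72)
  test_set <- build_labeled_dataset(400, shift, seed = 73)
  tr <- transfer_cnn(base, small, cnn_config(epochs = 40, seed = 8))
  rho_tr <- metric(test_set$onoff,
                   predict(tr, test_set$switch_seq)$onoff, "spearman")
  scratch <- train_cnn(small, cnn_config(epochs = 40, seed = 8))
  pr_sc <- predict(scratch, test_set$switch_seq)
  rho_sc <- metric(test_set$onoff,
                   pr_sc$on / pmax(pr_sc$off, 1e-6), "spearman")
  expect_gt(rho_tr, rho_sc)
})
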