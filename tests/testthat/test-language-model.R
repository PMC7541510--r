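test_that("pre-training lowers held-out perplexity below the untrained model", {
  heldout <- build_corpus(200, seed = 81)
  cfg <- fixture_lm_config()
  untrained <- structure(list(config = cfg,
                              params = with_seed(1, toeholdr:::lm_init_params(cfg)),
                              vocab = kmer_vocabulary(3)),
                         class = "toehold_lm")
  m <- fixture_lm()
  expect_lt(lm_perplexity(m, heldout), lm_perplexity(untrained, heldout))
  # a corpus of valid switches is far more predictable than uniform tokens
  expect_lt(lm_perplexity(m, heldout), 40)
})

test_that("seeded retraining reproduces the final loss exactly", {
  corpus <- build_corpus(200, seed = 82)
  cfg <- lm_config(seed = 3, epochs = 2)
  m1 <- pretrain_lm(corpus, cfg)
  m2 <- pretrain_lm(corpus, cfg)
  expect_identical(m1$manifest$final_train_loss,
                   m2$manifest$final_train_loss)
  expect_identical(m1$params, m2$params)
})

test_that("decoder samples reproduce the conserved grammar positions", {
  m <- fixture_lm()
  s <- sample_lm(m, 60, seed = 83)
  expect_true(all(nchar(s) == 57L))
  conserved_match <- vapply(s, function(x)
    mean(c(strsplit(substr(x, 31, 41), "")[[1]] ==
             strsplit("AACAGAGGAGA", "")[[1]],
           strsplit(substr(x, 48, 50), "")[[1]] == c("A", "U", "G"))),
    numeric(1))
  expect_gt(mean(conserved_match), 0.9)
})

test_that("embeddings are deterministic, sized, and separate real from scrambled", {
  m <- fixture_lm()
  sw <- build_corpus(120, seed = 84)
  e1 <- lm_embed(m, sw)
  expect_identical(e1, lm_embed(m, sw))
  expect_equal(dim(e1), c(120L, 64L))
  expect_true(all(is.finite(e1)))
  # linear probe separates real switches from scrambled controls
  scr <- make_control(sw, "scrambled", seed = 85)
  e0 <- lm_embed(m, scr)
  y <- c(rep(1, 120), rep(0, 120))
  X <- rbind(e1, e0)
  tr <- with_seed(86, sample.int(240, 170))
  fit <- suppressWarnings(
    glm.fit(cbind(1, X[tr, ]), y[tr], family = binomial()))
  p <- 1 / (1 + exp(-(cbind(1, X[-tr, ]) %*% fit$coefficients)))
  acc <- mean((p > 0.5) == y[-tr])
  expect_gte(acc, 0.9)
})

test_that("the classifier learns the oracle task (held-out MCC >= 0.3)", {
  pair <- fixture_classifier_pair()
  holdout <- fixture_holdout()
  truth <- fixture_holdout_labels()
  res <- classify_switches(pair$fwd, pair$bwd, holdout$switch_seq)
  expect_true(all(res$p_good >= 0 & res$p_good <= 1))
  mcc <- metric(truth, res$label, "mcc")
  expect_gte(mcc, 0.3)
})

test_that("classification beats shuffled and scrambled training controls", {
  # ablation design: same architecture and budget, training sequences
  # replaced by token-shuffled / letter-scrambled versions
  d <- fixture_dataset()[1:736, ]
  enc <- fixture_lm()
  holdout <- fixture_holdout()
  truth <- fixture_holdout_labels()
  mcc_for <- function(train_seqs) {
    dd <- d; dd$switch_seq <- train_seqs
    cls <- train_classifier(enc, dd, epochs = 8)
    p <- toeholdr:::lm_cls_pgood(cls, holdout$switch_seq)
    metric(truth, ifelse(p >= 0.5, "good", "bad"), "mcc")
  }
  mcc_real <- mcc_for(d$switch_seq)
  mcc_shuf <- mcc_for(make_control(d$switch_seq, "shuffled", seed = 87))
  mcc_scr <- mcc_for(make_control(d$switch_seq, "scrambled", seed = 88))
  expect_gt(mcc_real, mcc_shuf)
  expect_gt(mcc_real, mcc_scr)
})

test_that("freezing leaves the frozen QRNN layers bitwise unchanged", {
  d <- fixture_dataset()[1:400, ]
  enc <- fixture_lm()
  cls <- train_classifier(enc, d, freeze_layers = 1L, epochs = 2)
  for (nm in c("Wz1", "bz1", "Wf1", "bf1"))
    expect_identical(cls$params[[nm]], enc$params[[nm]])
  # the unfrozen top layer did move
  expect_false(identical(cls$params$Wz2, enc$params$Wz2))
  one_class <- d
  one_class$label <- "good"
  expect_error(train_classifier(enc, one_class, epochs = 1),
               "single class")
})

test_that("pre-training helps the classifier in the low-data regime", {
  # with 1000 labeled examples and a short budget, the pre-trained
  # encoder reaches a useful MCC while the naive one stays near chance;
  # the gap closes as labels grow, which is the expected transfer pattern
  d <- fixture_dataset()[1:1000, ]
  enc <- fixture_lm()
  holdout <- fixture_holdout()
  truth <- fixture_holdout_labels()
  mcc_of <- function(encoder) {
    cls <- train_classifier(encoder, d, config = fixture_lm_config(),
                            epochs = 10)
    p <- toeholdr:::lm_cls_pgood(cls, holdout$switch_seq)
    metric(truth, ifelse(p >= 0.5, "good", "bad"), "mcc")
  }
  expect_gt(mcc_of(enc), mcc_of(NULL))
})

test_that("directional averaging is the arithmetic mean of probabilities", {
  pair <- fixture_classifier_pair()
  sw <- build_corpus(25, seed = 89)
  p_f <- toeholdr:::lm_cls_pgood(pair$fwd, sw)
  p_b <- toeholdr:::lm_cls_pgood(pair$bwd, sw)
  res <- classify_switches(pair$fwd, pair$bwd, sw)
  expect_equal(res$p_good, (p_f + p_b) / 2, tolerance = 1e-12)
  # same model twice: averaging is a no-op
  solo <- classify_switches(pair$fwd, pair$fwd, sw)
  expect_equal(solo$p_good, p_f, tolerance = 1e-12)
  expect_true(all(res$p_good >= 0 & res$p_good <= 1))
  # mismatched threshold specs are rejected
  other <- pair$fwd
  other$threshold_spec <- list(q = 0.5, on = "onoff")
  expect_error(classify_switches(other, pair$bwd, sw), "threshold")
})
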