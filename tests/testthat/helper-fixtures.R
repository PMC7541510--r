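# Shared fixtures: tiny oracle-labeled datasets and cached trained models.
# Models are trained once per test run (lazily) and reused across test
# files; everything is seeded, so the cache never changes results.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

fixture_dataset <- function() {
  fixture("dataset5k", function()
    build_labeled_dataset(5500, oracle_params(), seed = 42))
}

# two-head CNN trained on the first 5000 oracle records
fixture_cnn <- function() {
  fixture("cnn", function() {
    d <- fixture_dataset()
    train_cnn(d[1:5000, ], cnn_config(epochs = 80, seed = 7))
  })
}

fixture_lm_config <- function() lm_config(seed = 11, epochs = 15,
                                          learning_rate = 0.005)

fixture_lm <- function() {
  fixture("lm", function()
    pretrain_lm(build_corpus(3000, seed = 5), fixture_lm_config()))
}

fixture_classifier_pair <- function() {
  fixture("cls_pair", function() {
    d <- fixture_dataset()[1:5000, ]
    enc <- fixture_lm()
    list(fwd = train_classifier(enc, d, direction = "forward",
                                epochs = 8),
         bwd = train_classifier(enc, d, direction = "backward",
                                epochs = 8))
  })
}

# held-out oracle records never seen by any fixture model
fixture_holdout <- function() fixture_dataset()[5001:5500, ]

# good/bad truth for the holdout at the training split's threshold
fixture_holdout_labels <- function() {
  d <- fixture_dataset()
  thr <- quartile_labels(d$onoff[1:5000])$threshold
  ifelse(fixture_holdout()$onoff >= thr, "good", "bad")
}

# brute-force recursive Levenshtein, the independent oracle for adist
lev_oracle <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(lev_oracle(substr(a, 2, nchar(a)), b) + 1L,
      lev_oracle(a, substr(b, 2, nchar(b))) + 1L,
      lev_oracle(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))) + cost)
}

random_rna <- function(n, len, seed = NULL) {
  sample_triggers(n, seed = seed, width = len)
}
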