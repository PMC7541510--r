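# oracle-backed surrogate models used to exercise the optimizers without
# the cost of full neural scoring
oracle_regressor <- function(params = oracle_params(noise_sd = 0)) {
  toehold_scorer(onoff_fun = function(seqs) oracle_score(seqs, params))
}

oracle_classifier <- function(params = oracle_params(noise_sd = 0),
                              pivot = 2) {
  toehold_scorer(pgood_fun = function(seqs) {
    sc <- oracle_score(seqs, params)
    1 / (1 + exp(-(sc$on / pmax(sc$off, 1e-6) - pivot)))
  })
}

test_that("variant enumeration is complete, duplicate-free and anchored", {
  parent <- assemble_switch(sample_triggers(1, seed = 101))
  # small templates: exhaustive duplicate check
  for (m in c(1L, 3L, 6L)) {
    tmpl <- toehold_template(mutable_positions = c(30L - m + 1L, 30L))
    vars <- enumerate_variants(parent, tmpl)
    expect_length(vars, 4^m)
    expect_equal(anyDuplicated(vars), 0L)
    expect_true(parent %in% vars)
    expect_true(all(substr(vars, 1, 30 - m) == substr(parent, 1, 30 - m)))
    expect_true(all(vapply(vars[seq(1, length(vars), length.out = 16)],
                           function(v) validate_switch(v, tmpl)$pass,
                           TRUE)))
  }
  # degenerate template with a zero-width mutable range is rejected by
  # construction; a one-position range gives 4 variants incl. the parent
  tmpl1 <- toehold_template(mutable_positions = c(30L, 30L))
  expect_length(enumerate_variants(parent, tmpl1), 4L)
})

test_that("the default stem enumerates all 262,144 variants", {
  parent <- assemble_switch(sample_triggers(1, seed = 102))
  vars <- enumerate_variants(parent)
  expect_length(vars, 262144L)
  # duplicate-free by counting distinct mutable substrings
  stems <- substr(vars, 22, 30)
  expect_equal(length(unique(stems)), 262144L)
  expect_true(all(substr(vars, 1, 21) == substr(parent, 1, 21)))
  expect_true(validate_switch(vars[77777])$pass)
})

test_that("geometric-mean consensus ranking is deterministic and dominant-consistent", {
  parent <- assemble_switch(sample_triggers(1, seed = 103))
  tmpl <- toehold_template(mutable_positions = c(27L, 30L))
  rk <- nuspeak_rank(parent, oracle_classifier(), oracle_regressor(),
                     tmpl, top_k = Inf)
  expect_equal(nrow(rk), 256L)
  expect_true(all(diff(rk$geo_mean) <= 1e-12))
  expect_equal(rk$geo_mean, sqrt(rk$p_good * rk$score_norm),
               tolerance = 1e-12)
  expect_true(all(rk$score_norm >= 0 & rk$score_norm <= 1))
  # dominance: if A beats B on both components, A ranks first
  for (i in c(5, 50, 150)) {
    dominated <- rk$p_good < rk$p_good[i] & rk$score_norm < rk$score_norm[i]
    expect_true(all(which(dominated) > i))
  }
  rk2 <- nuspeak_rank(parent, oracle_classifier(), oracle_regressor(),
                      tmpl, top_k = Inf)
  expect_identical(rk, rk2)
  expect_equal(sqrt(0.9 * 0.4), 0.6)
})

test_that("consensus-ranked top variants improve the oracle objective", {
  # improvement property over 50 seeded trials on a reduced stem
  tmpl <- toehold_template(mutable_positions = c(27L, 30L))
  reg <- oracle_regressor()
  cls <- oracle_classifier()
  wins <- 0L
  for (trial in 1:50) {
    parent <- assemble_switch(sample_triggers(1, seed = 200 + trial))
    parent_score <- oracle_score(parent, oracle_params(noise_sd = 0))
    parent_onoff <- parent_score$on / max(parent_score$off, 1e-6)
    top <- nuspeak_rank(parent, cls, reg, tmpl, top_k = 1L)
    top_score <- oracle_score(top$sequence, oracle_params(noise_sd = 0))
    top_onoff <- top_score$on / max(top_score$off, 1e-6)
    if (top_onoff >= parent_onoff) wins <- wins + 1L
  }
  expect_gte(wins, 45L)  # >= 90% of trials
})

test_that("STORM returns a valid best switch and a monotone objective", {
  m <- fixture_cnn()
  seedsw <- assemble_switch(sample_triggers(1, seed = 104))
  # no-op contract: zero steps returns the repaired seed and its scores
  tr0 <- storm_optimize(seedsw, m, steps_per_round = 0L)
  expect_identical(tr0$best, fix_sequence(seedsw))
  pr <- predict(m, fix_sequence(seedsw))
  expect_equal(tr0$best_on, pr$on, tolerance = 1e-12)
  expect_equal(tr0$best_off, pr$off, tolerance = 1e-12)
  # a short run: best validates, objective never below the seed's
  tr <- storm_optimize(seedsw, m, rounds = 2L, steps_per_round = 40L,
                       rng_seed = 5)
  expect_true(validate_switch(tr$best)$pass)
  expect_gte(tr$best_onoff, tr$trace$onoff[1])
  expect_equal(nrow(tr$trace), 3L)
  # deterministic given the seed
  tr2 <- storm_optimize(seedsw, m, rounds = 2L, steps_per_round = 40L,
                        rng_seed = 5)
  expect_identical(tr$best, tr2$best)
})

test_that("STORM improves the predicted objective for the worst switches", {
  m <- fixture_cnn()
  d <- fixture_dataset()
  pr <- predict(m, d$switch_seq)
  pred_onoff <- pr$on / pmax(pr$off, 1e-6)
  worst <- d$switch_seq[order(pred_onoff)][1:20]
  improved <- 0L
  for (i in seq_along(worst)) {
    tr <- storm_optimize(worst[i], m, rounds = 3L, steps_per_round = 60L,
                         rng_seed = 300 + i)
    if (tr$best_onoff >= tr$trace$onoff[1]) improved <- improved + 1L
  }
  expect_gte(improved, 18L)
})

test_that("STORM alternative modes stay valid and honor their knobs", {
  m <- fixture_cnn()
  seedsw <- assemble_switch(sample_triggers(1, seed = 106))
  # ratio-target mode
  tr <- storm_optimize(seedsw, m, target_mode = "ratio",
                       target_ratio = 2, rounds = 1L,
                       steps_per_round = 25L, rng_seed = 7)
  expect_true(validate_switch(tr$best)$pass)
  expect_true(is.finite(tr$best_onoff))
  # constrained mode: pairing penalty pulls dependency targets toward the
  # reverse complement of their sources in the relaxed matrix
  P <- matrix(0.25, 59, 4)
  G <- toeholdr:::pairing_penalty_grad(P, toehold_template())
  expect_true(all(G == 0))  # uniform rows already satisfy the constraint
  P2 <- P; P2[42, ] <- c(1, 0, 0, 0)  # target row off-constraint
  G2 <- toeholdr:::pairing_penalty_grad(P2, toehold_template())
  expect_gt(G2[42, 1], 0)  # pushed back down toward uniform
  tr2 <- storm_optimize(seedsw, m, rounds = 1L, steps_per_round = 25L,
                        pairing_weight = 0.1, rng_seed = 7)
  expect_true(validate_switch(tr2$best)$pass)
})

test_that("the MFE hook only breaks geometric-mean ties", {
  parent <- assemble_switch(sample_triggers(1, seed = 107))
  tmpl <- toehold_template(mutable_positions = c(29L, 30L))
  # constant scorers make every variant tie on geo_mean
  cls <- toehold_scorer(pgood_fun = function(s) rep(0.8, length(s)))
  reg <- toehold_scorer(onoff_fun = function(s)
    data.frame(on = rep(0.5, length(s)), off = rep(0.5, length(s))))
  fake_mfe <- function(s) -nchar(gsub("[^GC]", "", substr(s, 22, 30)))
  rk <- nuspeak_rank(parent, cls, reg, tmpl, top_k = Inf, mfe = fake_mfe)
  expect_true(all(diff(rk$mfe) <= 0))  # least negative first
  expect_named(rk, c("sequence", "p_good", "onoff", "score_norm",
                     "geo_mean", "mfe"))
})

test_that("consensus selection draws disjoint, ordered, seeded picks", {
  cands <- build_corpus(200, seed = 105)
  cls <- oracle_classifier()
  reg <- oracle_regressor()
  picks <- consensus_select(cands, cls, reg, n_good = 8, n_bad = 8,
                            rng_seed = 6)
  expect_equal(nrow(picks$good), 8L)
  expect_equal(nrow(picks$bad), 8L)
  expect_length(intersect(picks$good$sequence, picks$bad$sequence), 0L)
  expect_gt(min(picks$good$geo_mean), max(picks$bad$geo_mean))
  picks2 <- consensus_select(cands, cls, reg, n_good = 8, n_bad = 8,
                             rng_seed = 6)
  expect_identical(picks, picks2)
  empty <- consensus_select(cands, cls, reg, n_good = 0, n_bad = 0)
  expect_equal(nrow(empty$good), 0L)
  expect_equal(nrow(empty$bad), 0L)
  expect_error(consensus_select(cands[1:10], cls, reg, n_good = 8,
                                n_bad = 8), "too few")
})
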