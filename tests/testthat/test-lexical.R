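# Lexical-decision modelling: edit distance, features, nearest-word
# distances, RT regressions, model comparison and category summaries.

test_that("orthographic Levenshtein distance matches hand cases", {
  expect_equal(old_distance("FORGET", "FORGET"), 0)
  expect_equal(old_distance("FORGET", "FOGRET"), 2)
  expect_equal(old_distance("AB", ""), 2)
  expect_equal(old_distance("", ""), 0)
  expect_equal(old_distance("CAT", "BAT"), 2)       # one substitution
  expect_equal(old_distance("CAT", "BAT", sub_cost = 1), 1)
  expect_error(old_distance("A", "B", sub_cost = -1), "nonnegative")
})

test_that("with substitution cost 2 the distance equals |s|+|t|-2*LCS", {
  withr::with_seed(31, {
    for (i in 1:500) {
      s <- random_string(sample(0:8, 1))
      t <- random_string(sample(0:8, 1))
      expect_equal(old_distance(s, t),
                   nchar(s) + nchar(t) - 2 * lcs_length(s, t))
    }
  })
})

test_that("default-cost distance satisfies the metric axioms", {
  withr::with_seed(32, {
    strs <- vapply(1:30, function(i) random_string(sample(1:6, 1)),
                   character(1))
    for (i in 1:150) {
      abc <- sample(strs, 3, replace = TRUE)
      dab <- old_distance(abc[1], abc[2])
      expect_equal(dab, old_distance(abc[2], abc[1]))          # symmetry
      expect_equal(old_distance(abc[1], abc[1]), 0)            # identity
      if (abc[1] != abc[2]) expect_gt(dab, 0)
      expect_lte(old_distance(abc[1], abc[3]),
                 dab + old_distance(abc[2], abc[3]))           # triangle
    }
  })
})

test_that("orthographic neighborhood is substitution-only and excludes self", {
  lex <- c("CAT", "BAT", "CAR", "DOG")
  expect_equal(orthographic_neighbors("CAT", lex), 2)
  expect_equal(orthographic_neighbors("CAT", c(lex, "CAT")), 2)
  expect_equal(orthographic_neighbors("HOUSE", lex), 0)
  expect_equal(orthographic_neighbors("CAT", character(0)), 0)
  # OLD-radius alternative counts the same neighbors at radius 2
  expect_equal(orthographic_neighbors("CAT", lex, method = "old_radius"), 2)
})

test_that("lexical features match hand arithmetic on a tiny norms table", {
  norms <- lexical_norms(
    word_freq = c(CAT = 100, DOG = 10, RAT = 1),
    bigram_freq = c(CA = 4, AT = 8, DO = 2, OG = 2, RA = 4),
    letter_freq = c(C = 10, A = 20, T = 30, D = 5, O = 5, G = 5, R = 10))
  f <- lexical_features(c("CAT", "BAT", "A"), norms)
  expect_equal(f$is_word, c(1L, 0L, 0L))
  expect_equal(f$log_word_freq[1], log(100))
  expect_true(is.na(f$log_word_freq[2]))
  expect_equal(f$mean_log_bigram_freq[1], mean(log(c(4, 8))))
  # unseen bigram BA floored at half the minimum positive frequency (1)
  expect_equal(f$mean_log_bigram_freq[2], mean(log(c(1, 8))))
  expect_equal(f$mean_log_letter_freq[1], mean(log(c(10, 20, 30))))
  expect_equal(f$n_neighbors, c(1L, 2L, 0L))  # CAT-RAT; BAT-{CAT,RAT}
  # single-letter string: bigram feature is missing, not zero
  expect_true(is.na(f$mean_log_bigram_freq[3]))
  # uniform norms give equal-length strings identical features
  un <- lexical_norms(c(CAT = 1, DOG = 1),
                      c(PQ = 1, QR = 1, XY = 1, YZ = 1),
                      c(P = 1, Q = 1, R = 1, X = 1, Y = 1, Z = 1),
                      lexicon = character(0))
  fu <- lexical_features(c("PQR", "XYZ"), un)
  expect_equal(fu$mean_log_bigram_freq[1], fu$mean_log_bigram_freq[2])
  expect_equal(fu$mean_log_letter_freq[1], fu$mean_log_letter_freq[2])
  expect_error(lexical_features("", norms), "empty")
})

test_that("nearest-word distance reflects the compositional geometry", {
  code <- make_letter_code(6, LETTERS[1:12], seed = 41)
  # positions 5-6 summed symmetrically, positions 1-2 asymmetrically:
  # a late swap moves the response nowhere, an edge swap far
  prof <- c(1.0, 0.55, 0.4, 0.55, 0.7, 0.7)
  w6 <- spatial_weights(matrix(rep(prof, each = 6), 6, 6))
  lex <- c("ABCDEF")
  d_mid <- nonword_distance("ABCDFE", lex, code, w6)  # swap 5-6
  d_edge <- nonword_distance("BACDEF", lex, code, w6) # swap 1-2
  expect_equal(d_mid$nearest_word, "ABCDEF")
  expect_lt(d_mid$d, d_edge$d)
  # a mislabeled nonword that is itself a word sits at distance 0
  expect_equal(nonword_distance("ABCDEF", lex, code, w6)$d, 0)
  expect_error(nonword_distance("AB", lex, code, w6), "no length-2")
})

test_that("linear RT models recover their generating parameters", {
  f <- (1:50)^-1
  df <- data.frame(rt = 0.9 - 0.05 * log(f), log_word_freq = log(f))
  fit <- fit_rt_model(df, "log_word_freq")
  expect_equal(unname(fit$coefficients), c(0.9, -0.05), tolerance = 1e-8)
  expect_gt(fit$r, 1 - 1e-10)
  # nonword form RT = 1/(alpha d + beta) is linear on the reciprocal scale
  d <- seq(0.1, 2, length.out = 40)
  dn <- data.frame(rt = 1 / (1.3 * d + 0.4), model_distance = d)
  fn <- fit_rt_model(dn, "model_distance", target = "reciprocal_rt")
  expect_equal(unname(fn$coefficients), c(0.4, 1.3), tolerance = 1e-8)
  expect_gt(fn$r, 0.99)
  # intercept-only model has r = 0 by definition
  expect_equal(fit_rt_model(df, character(0))$r, 0)
  expect_error(fit_rt_model(df, "missing_col"), "missing from data")
  df$dup <- df$log_word_freq
  expect_error(fit_rt_model(df, c("log_word_freq", "dup")), "singular")
})

test_that("cross-validated comparison is calibrated and detects the truth", {
  study <- edge_weighted_study(n_per_category = 8, n_subjects = 12,
                               noise_sd = 0.05)
  nw_trials <- study$trials[study$trials$is_word == 0, ]
  strings <- unique(nw_trials$string)
  d <- vapply(strings, function(s)
    nonword_distance(s, study$lexicon$words, study$code, study$weights)$d,
    numeric(1))
  feats <- data.frame(string = strings, model_distance = d,
                      noise_pred = withr::with_seed(42, rnorm(length(d))))
  res <- crossval_compare(
    list(neural = list(predictors = "model_distance",
                       target = "reciprocal_rt"),
         neural_twin = list(predictors = "model_distance",
                            target = "reciprocal_rt"),
         noise = list(predictors = "noise_pred", target = "reciprocal_rt")),
    nw_trials, feats, n_boot = 200, seed = 7)
  # identical specs tie on every split: calibrated exceedance 0.5
  expect_equal(res$exceedance["neural", "neural_twin"], 0.5)
  # the generating model beats an uninformative predictor
  expect_lt(res$exceedance["neural", "noise"], 0.05)
  # determinism by seed
  res2 <- crossval_compare(
    list(a = list(predictors = "model_distance", target = "reciprocal_rt")),
    nw_trials, feats, n_boot = 50, seed = 9)
  res3 <- crossval_compare(
    list(a = list(predictors = "model_distance", target = "reciprocal_rt")),
    nw_trials, feats, n_boot = 50, seed = 9)
  expect_identical(res2$r_matrix, res3$r_matrix)
  expect_error(crossval_compare(list(a = list(predictors = "model_distance")),
                                nw_trials[nw_trials$subject_id < 4, ],
                                feats, 10, 1), ">= 4 subjects")
})

test_that("percent-change summaries follow the category structure", {
  categories <- data.frame(nonword = c("NW1", "NW2", "NW3", "NW4"),
                           source = c("W1", "W2", "W1", "W2"),
                           category = c("t", "t", "s", "s"))
  wrt <- c(W1 = 0.6, W2 = 0.8)
  # equal RTs: all percent changes zero
  zero <- transposition_substitution_summary(
    wrt, c(NW1 = 0.6, NW2 = 0.8, NW3 = 0.6, NW4 = 0.8), categories)
  expect_equal(zero$by_category$mean_pct, c(0, 0))
  expect_equal(nrow(zero$by_category), 2)
  # hand case: +10% and -25%
  mix <- transposition_substitution_summary(
    wrt, c(NW1 = 0.66, NW2 = 0.88, NW3 = 0.45, NW4 = 0.6), categories)
  expect_equal(mix$by_category$mean_pct[mix$by_category$category == "t"], 10)
  expect_equal(mix$by_category$mean_pct[mix$by_category$category == "s"], -25)
  expect_equal(nrow(mix$pairwise), 1)
  # singleton categories are excluded with a warning
  expect_warning(
    transposition_substitution_summary(
      wrt, c(NW1 = 0.66, NW2 = 0.88, NW3 = 0.45, NW4 = 0.6),
      transform(categories, category = c("t", "t", "t", "lone"))),
    "lone")
})

test_that("low-accuracy strings are excluded before modelling", {
  tr <- data.frame(subject_id = rep(1:5, times = 3),
                   string = rep(c("GOODW", "HARDW", "BADW"), each = 5),
                   is_word = 0L,
                   rt_s = 0.6,
                   correct = c(rep(1, 5), c(1, 0, 0, 0, 0), rep(0, 5)))
  kept <- exclude_low_accuracy(tr, threshold = 0.2)
  expect_setequal(unique(kept$string), c("GOODW", "HARDW"))
  expect_equal(attr(kept, "excluded_strings"), "BADW")
  # everything retained at threshold 0
  expect_equal(nrow(exclude_low_accuracy(tr, 0)), nrow(tr))
})
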